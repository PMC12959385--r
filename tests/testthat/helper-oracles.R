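# Shared fixtures and independent brute-force oracles.

# A short reference pair (200 nt) keeps the fraction of window-covering
# fragments high enough for fast end-to-end tests.
shortRefs <- function(seed = 11L) {
  makeReferencePair(seed, diagnosticPos = 100L, window = c(80L, 126L),
                    refLength = 200L)
}

# Brute-force classifier: scan every offset of the read against both
# 47-nt windows by plain substring comparison. Independent of the
# Biostrings matching used by classifyReads().
bruteClassify <- function(read, refs) {
  contains <- function(r, w) {
    n <- nchar(r); wl <- nchar(w)
    if (n < wl) return(FALSE)
    for (i in seq_len(n - wl + 1L))
      if (substr(r, i, i + wl - 1L) == w) return(TRUE)
    FALSE
  }
  if (contains(read, diagnosticWindow(refs, "A"))) "A"
  else if (contains(read, diagnosticWindow(refs, "G"))) "G"
  else "unclassified"
}

# Exact-arithmetic dominance oracle: frac_A > 0.95 iff 20 n_A > 19 total,
# i.e. n_A > 19 n_G, entirely in integers.
bruteDominanceCall <- function(nA, nG) {
  if (20 * nA > 19 * (nA + nG)) "A-dominant"
  else if (20 * nG > 19 * (nA + nG)) "G-dominant"
  else "mixed"
}

# Connected components of a labelled spot set under 4-connectivity.
countComponents <- function(x, y, lab) {
  n <- length(x)
  key <- paste(x, y, sep = ",")
  idx <- stats::setNames(seq_len(n), key)
  seen <- logical(n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- c(paste(x[i] + 1L, y[i], sep = ","),
              paste(x[i] - 1L, y[i], sep = ","),
              paste(x[i], y[i] + 1L, sep = ","),
              paste(x[i], y[i] - 1L, sep = ","))
      j <- idx[nb]
      j <- j[!is.na(j)]
      j <- j[!seen[j] & lab[j] == lab[i]]
      seen[j] <- TRUE
      queue <- c(queue, j)
    }
  }
  comps
}

# Minimal single-reference SAM writer for alignment-mode fixtures.
# records: data.frame with qname, flag, pos, mapq, cigar, seq, nh, nm.
writeSamFixture <- function(records, path, refName = "phylotypeA",
                            refLen = 1500L) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", refName, refLen))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    paste(r$qname, r$flag, refName, r$pos, r$mapq, r$cigar, "*", 0, 0,
          r$seq, strrep("I", nchar(r$seq)),
          sprintf("NH:i:%d", r$nh), sprintf("NM:i:%d", r$nm),
          sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

# R-squared by direct evaluation of the definition (no cor()).
bruteR2 <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))
  (num / sqrt(sum((x - mx)^2) * sum((y - my)^2)))^2
}
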