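#' Simulate spatially barcoded paired reads over a planted field
#'
#' Emulates a Stereo-seq-style FFPE 16S capture library: read 1 carries a
#' 25-nt coordinate barcode (CID) identifying the spot, followed by a 10-nt
#' molecular barcode (MID); read 2 is a 75-nt fragment of one of the two
#' phylotype references. Per-spot read totals are Poisson; each read's
#' phylotype is Bernoulli in the spot's true phylotype-A fraction; fragment
#' start positions are uniform over all valid starts on the reference, so
#' most fragments do not cover the 47-nt diagnostic window and must be
#' rejected downstream, as in real capture data. Sequencing errors are
#' i.i.d. substitutions at `errorRate` per base on read 2 (barcodes are
#' emitted error-free).
#'
#' @param truth Truth table from [simulateField()] (columns `x`, `y`,
#'   `fracA`).
#' @param refs A [ReferencePair-class].
#' @param meanReadsPerSpot Poisson mean of per-spot read totals.
#' @param read2Length Read 2 length in nt (default 75); must be at least 47
#'   and no longer than the reference.
#' @param errorRate Per-base substitution probability on read 2, in \[0, 1).
#' @param cidLength,midLength Barcode lengths (defaults 25 and 10).
#' @param seed Integer seed; output is a deterministic function of it.
#' @return A list with elements
#' \describe{
#'   \item{read1}{character vector, CID+MID sequences;}
#'   \item{read2}{character vector, 16S fragments;}
#'   \item{mask}{data.frame `cid`, `x`, `y` mapping every emitted CID to
#'     its spot;}
#'   \item{labels}{data.frame with per-read provenance: `x`, `y`, `mid`,
#'     `phylotype` (planted \code{"A"}/\code{"G"}), `start` (1-based
#'     fragment start) and `coversWindow` (whether the fragment spans the
#'     full diagnostic window);}
#'   \item{readsPerSpot}{integer vector of per-spot totals, aligned with
#'     rows of `truth`.}
#' }
#' @export
simulateReads <- function(truth, refs, meanReadsPerSpot = 50,
                          read2Length = 75L, errorRate = 0.001,
                          cidLength = 25L, midLength = 10L, seed = 1L) {
  stopifnot(is(refs, "ReferencePair"))
  refLen <- length(refs@seqA)
  read2Length <- as.integer(read2Length)
  if (read2Length < 47L)
    stop("'read2Length' must be at least the 47-nt window length")
  if (read2Length > refLen)
    stop("'read2Length' exceeds the reference length")
  if (errorRate < 0 || errorRate >= 1)
    stop("'errorRate' must lie in [0, 1)")

  set.seed(seed)
  nSpot <- nrow(truth)
  cids <- .randomBarcodes(nSpot, cidLength)
  mask <- data.frame(cid = cids, x = truth$x, y = truth$y,
                     stringsAsFactors = FALSE)

  counts <- stats::rpois(nSpot, meanReadsPerSpot)
  n <- sum(counts)
  spotIdx <- rep.int(seq_len(nSpot), counts)
  isA <- stats::rbinom(n, 1L, truth$fracA[spotIdx]) == 1L
  starts <- sample.int(refLen - read2Length + 1L, n, replace = TRUE)
  ends <- starts + read2Length - 1L

  seqA <- as.character(refs@seqA)
  seqG <- as.character(refs@seqG)
  read2 <- ifelse(isA,
                  substring(seqA, starts, ends),
                  substring(seqG, starts, ends))
  if (errorRate > 0 && n > 0)
    read2 <- .substitutionErrors(read2, read2Length, errorRate)

  mids <- .randomBarcodes(n, midLength, unique = FALSE)
  read1 <- paste0(cids[spotIdx], mids)

  w <- refs@window
  labels <- data.frame(
    x = truth$x[spotIdx], y = truth$y[spotIdx], mid = mids,
    phylotype = ifelse(isA, "A", "G"), start = starts,
    coversWindow = starts <= w[1] & ends >= w[2],
    stringsAsFactors = FALSE)

  list(read1 = read1, read2 = read2, mask = mask, labels = labels,
       readsPerSpot = counts)
}

.randomBarcodes <- function(n, width, unique = TRUE) {
  if (n == 0L) return(character(0))
  draw <- function(m) {
    chars <- sample(c("A", "C", "G", "T"), m * width, replace = TRUE)
    apply(matrix(chars, nrow = m), 1L, paste, collapse = "")
  }
  bc <- draw(n)
  while (unique && anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
  }
  bc
}

# i.i.d. substitutions: per-read error counts are Binomial(width, rate);
# only reads with at least one error are touched.
.substitutionErrors <- function(reads, width, rate) {
  nerr <- stats::rbinom(length(reads), width, rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    s <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(width, nerr[i])
    for (p in pos) s[p] <- sample(bases[bases != s[p]], 1L)
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Write simulated reads and mask to FASTQ/TSV
#'
#' @param sim Output of [simulateReads()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Named character vector of the written file paths (`r1`, `r2`,
#'   `mask`), invisibly.
#' @export
writeSimulatedReads <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  r1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
  r2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
  mk <- file.path(dir, paste0(prefix, "_mask.tsv"))
  ids <- sprintf("read%06d", seq_along(sim$read1))
  .writeFastq(sim$read1, ids, r1)
  .writeFastq(sim$read2, ids, r2)
  writeMask(sim$mask, mk)
  invisible(c(r1 = r1, r2 = r2, mask = mk))
}

.writeFastq <- function(seqs, ids, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  quals <- Biostrings::BStringSet(
    vapply(nchar(seqs), function(w) strrep("I", w), character(1)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = quals)
}

#' Read a FASTQ file as plain sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning bare
#' character sequences for the demultiplexing and classification steps.
#'
#' @param path FASTQ file path.
#' @return Character vector of read sequences.
#' @export
readFastqSequences <- function(path) {
  unname(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
}
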