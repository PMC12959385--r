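#' Classify reads to phylotype by exact diagnostic-window match
#'
#' Sequence-mode emulation of the mapping-based extraction filter used for
#' single-base phylotype discrimination: a read is called phylotype A if
#' and only if it contains the full 47-nt diagnostic window of the
#' phylotype A reference with zero mismatches, phylotype G likewise for the
#' G window, and `unclassified` otherwise — including reads that cover only
#' part of the window or carry a sequencing error anywhere inside it. The
#' two windows differ at the diagnostic base, so no read can match both.
#'
#' @param read2 Character vector (or [Biostrings::DNAStringSet]) of read 2
#'   sequences.
#' @param refs A [ReferencePair-class].
#' @return Character vector of calls in `{"A", "G", "unclassified"}`,
#'   one per read.
#' @examples
#' refs <- makeReferencePair(seed = 1, refLength = 200,
#'                           diagnosticPos = 100, window = c(80, 126))
#' frag <- substr(as.character(refSeqG(refs)), 60, 134)
#' classifyReads(frag, refs)
#' @export
classifyReads <- function(read2, refs) {
  stopifnot(is(refs, "ReferencePair"))
  if (!is(read2, "DNAStringSet"))
    read2 <- Biostrings::DNAStringSet(as.character(read2))
  winA <- diagnosticWindow(refs, "A")
  winG <- diagnosticWindow(refs, "G")
  hitA <- Biostrings::vcountPattern(winA, read2, max.mismatch = 0) > 0L
  hitG <- Biostrings::vcountPattern(winG, read2, max.mismatch = 0) > 0L
  ifelse(hitA, "A", ifelse(hitG, "G", "unclassified"))
}

#' Tally classified reads into per-spot phylotype counts
#'
#' @param classified Data.frame with columns `x`, `y`, `mid`, `call`
#'   (values `"A"`, `"G"` or `"unclassified"`), one row per demultiplexed
#'   read.
#' @param dedupMid When `TRUE`, collapse molecular-barcode duplicates: at
#'   most one count per (spot, MID, call). Off by default, matching a plain
#'   mapped-read count.
#' @return Spot-count table: data.frame `x`, `y`, `n_A`, `n_G`,
#'   `n_unclassified`, one row per spot seen in the input.
#' @export
accumulateCounts <- function(classified, dedupMid = FALSE) {
  df <- classified[c("x", "y", "mid", "call")]
  if (dedupMid)
    df <- df[!duplicated(df[c("x", "y", "mid", "call")]), , drop = FALSE]
  if (nrow(df) == 0L)
    return(data.frame(x = integer(0), y = integer(0), n_A = integer(0),
                      n_G = integer(0), n_unclassified = integer(0)))
  key <- paste(df$x, df$y, sep = ",")
  tab <- table(key, factor(df$call, levels = c("A", "G", "unclassified")))
  xy <- do.call(rbind, strsplit(rownames(tab), ",", fixed = TRUE))
  out <- data.frame(
    x = as.integer(xy[, 1]), y = as.integer(xy[, 2]),
    n_A = as.integer(tab[, "A"]), n_G = as.integer(tab[, "G"]),
    n_unclassified = as.integer(tab[, "unclassified"]))
  out[order(out$y, out$x), , drop = FALSE]
}

#' Overall phylotype frequency among classified reads
#'
#' The sample-level analogue of the metagenomic G-allele read percentage
#' at the diagnostic 16S position: the fraction of phylotype G (and A)
#' among all classified reads of a sample.
#'
#' @param nA,nG Classified read counts for phylotypes A and G; their sum
#'   must be positive.
#' @param sample Optional sample id.
#' @return One-row data.frame `sample`, `n_A`, `n_G`, `frac_G`, `frac_A`.
#' @export
sampleFrequency <- function(nA, nG, sample = NA_character_) {
  if (nA + nG <= 0) stop("no classified reads: n_A + n_G must be positive")
  data.frame(sample = sample, n_A = nA, n_G = nG,
             frac_G = nG / (nA + nG), frac_A = nA / (nA + nG),
             stringsAsFactors = FALSE)
}

#' Concordance between two frequency estimators
#'
#' Squared Pearson correlation of paired phylotype-frequency estimates,
#' e.g. a strain-decomposition estimate against the diagnostic-base read
#' frequency for the same samples.
#'
#' @param est1,est2 Numeric vectors of paired estimates, length at least 3
#'   and neither constant.
#' @return The coefficient of determination (squared Pearson correlation).
#' @export
concordanceR2 <- function(est1, est2) {
  if (length(est1) != length(est2)) stop("estimates must be paired")
  if (length(est1) < 3L) stop("need at least 3 pairs")
  if (stats::sd(est1) == 0 || stats::sd(est2) == 0)
    stop("correlation undefined for a constant estimator")
  stats::cor(est1, est2)^2
}
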