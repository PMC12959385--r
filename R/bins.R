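#' Aggregate spot counts into square bins
#'
#' Spots are aggregated into `binSize` x `binSize` blocks (default 20 x 20
#' DNA nanoballs, about 10 um, approximating one cell). Bin indices come
#' from floor division of the 0-based spot coordinates, and a bin is valid
#' only if its classified-read total reaches `minReads`.
#'
#' @param spots Spot-count table from [accumulateCounts()] (columns `x`,
#'   `y`, `n_A`, `n_G`).
#' @param binSize Bin edge length in spots; at least 1.
#' @param minReads Validity threshold on `n_A + n_G` (default 180).
#' @return Bin table: data.frame `bx`, `by`, `n_A`, `n_G`, `total`,
#'   `frac_A` (`NaN` for empty bins), `ratio_AG` (`Inf` when `n_G` is 0),
#'   `valid`.
#' @export
binAggregate <- function(spots, binSize = 20L, minReads = 180L) {
  binSize <- as.integer(binSize)
  if (binSize < 1L) stop("'binSize' must be at least 1")
  bx <- spots$x %/% binSize
  by <- spots$y %/% binSize
  key <- paste(bx, by, sep = ",")
  agg <- rowsum(cbind(spots$n_A, spots$n_G), key)
  nA <- as.integer(agg[, 1])
  nG <- as.integer(agg[, 2])
  xy <- do.call(rbind, strsplit(rownames(agg), ",", fixed = TRUE))
  out <- data.frame(
    bx = as.integer(xy[, 1]), by = as.integer(xy[, 2]),
    n_A = nA, n_G = nG, total = nA + nG)
  out$frac_A <- out$n_A / out$total
  out$ratio_AG <- out$n_A / out$n_G
  out$valid <- out$total >= minReads
  out <- out[order(out$by, out$bx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call the dominant phylotype per bin
#'
#' A valid bin is called for a phylotype when that phylotype's read
#' fraction strictly exceeds the `dominance` threshold; at the default
#' 0.95 this is equivalent to a count ratio above 19 (A-dominant iff
#' n_A > 19 n_G). Valid bins exceeding neither threshold are `mixed`;
#' invalid bins are `invalid`.
#'
#' @param bins Bin table from [binAggregate()].
#' @param dominance Dominance threshold, strictly between 0.5 and 1.
#' @return The bin table with a `call` column in
#'   `{"A-dominant", "G-dominant", "mixed", "invalid"}`.
#' @export
callBins <- function(bins, dominance = 0.95) {
  if (dominance <= 0.5 || dominance >= 1)
    stop("'dominance' must lie in (0.5, 1)")
  fracA <- bins$n_A / bins$total
  fracG <- bins$n_G / bins$total
  call <- rep("mixed", nrow(bins))
  call[which(fracA > dominance)] <- "A-dominant"
  call[which(fracG > dominance)] <- "G-dominant"
  call[!bins$valid] <- "invalid"
  bins$call <- call
  bins
}

#' Spatial heterogeneity summary of a called bin table
#'
#' Summaries over valid bins only: the share of single-phylotype bins in
#' the strict sense (minor phylotype count exactly 0) and in the dominance
#' sense (call not `mixed`); a 20-interval frequency histogram of the
#' phylotype A fraction in steps of 5% (intervals \[0,0.05), ...,
#' \[0.95,1\], the last closed); the extreme-bin share (fraction of valid
#' bins with `frac_A` at or below 0.05 or at or above 0.95); and the
#' neighbour discordance, the fraction of 4-adjacent pairs of
#' dominant-called bins whose calls differ (`NaN` when no such pair
#' exists).
#'
#' @param bins Called bin table from [callBins()].
#' @return A list with elements `nValidBins`, `singlePhylotypeStrict`,
#'   `singlePhylotypeDominance`, `histogram` (named 20-vector of counts),
#'   `extremeFraction` and `neighborDiscordance`.
#' @export
summarizeBins <- function(bins) {
  v <- bins[bins$valid, , drop = FALSE]
  if (nrow(v) == 0L) stop("no valid bins to summarize")
  frac <- v$n_A / v$total
  nValid <- nrow(v)

  idx <- pmin(floor(frac / 0.05) + 1L, 20L)  # last interval closed at 1
  hist <- tabulate(idx, nbins = 20L)
  lo <- seq(0, 0.95, by = 0.05)
  names(hist) <- sprintf("[%.2f,%.2f%s", lo, lo + 0.05,
                         c(rep(")", 19), "]"))

  dom <- v$call %in% c("A-dominant", "G-dominant")
  discord <- .neighborDiscordance(v[dom, , drop = FALSE])

  list(
    nValidBins = nValid,
    singlePhylotypeStrict = mean(pmin(v$n_A, v$n_G) == 0L),
    singlePhylotypeDominance = mean(dom),
    histogram = hist,
    extremeFraction = mean(frac <= 0.05 | frac >= 0.95),
    neighborDiscordance = discord)
}

# fraction of 4-adjacent dominant-called bin pairs with different calls
.neighborDiscordance <- function(domBins) {
  if (nrow(domBins) < 2L) return(NaN)
  key <- paste(domBins$bx, domBins$by, sep = ",")
  callOf <- stats::setNames(domBins$call, key)
  same <- 0L; diff <- 0L
  for (shift in list(c(1L, 0L), c(0L, 1L))) {
    nb <- paste(domBins$bx + shift[1], domBins$by + shift[2], sep = ",")
    hit <- nb %in% key
    if (!any(hit)) next
    agree <- domBins$call[hit] == callOf[nb[hit]]
    same <- same + sum(agree)
    diff <- diff + sum(!agree)
  }
  if (same + diff == 0L) return(NaN)
  diff / (same + diff)
}

#' Write spot and bin tables as TSV
#'
#' @param spots Spot-count table ([accumulateCounts()]).
#' @param bins Called bin table ([callBins()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeSpotTable <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpotTable
#' @export
writeBinTable <- function(bins, path) {
  utils::write.table(bins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
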