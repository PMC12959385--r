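#' Read and write a coordinate-barcode mask
#'
#' The mask maps each 25-nt coordinate barcode (CID) to its spot position
#' on the chip lattice. Coordinates are 0-based non-negative integers with
#' the spot (one DNA-nanoball pitch) as the unit.
#'
#' @param path Tab-delimited file with header columns `cid`, `x`, `y`.
#' @return `loadMask()` returns a data.frame with character `cid` and
#'   integer `x`, `y`; duplicate CIDs or malformed coordinates are errors.
#' @export
loadMask <- function(path) {
  m <- utils::read.delim(path, colClasses = c(cid = "character"),
                         stringsAsFactors = FALSE)
  req <- c("cid", "x", "y")
  if (!all(req %in% names(m)))
    stop("mask must have columns 'cid', 'x', 'y'")
  m <- m[req]
  if (anyDuplicated(m$cid))
    stop("duplicate CID in mask: ", m$cid[duplicated(m$cid)][1])
  x <- suppressWarnings(as.integer(m$x))
  y <- suppressWarnings(as.integer(m$y))
  if (anyNA(x) || anyNA(y))
    stop("malformed coordinate in mask")
  if (any(x < 0L) || any(y < 0L))
    stop("mask coordinates must be non-negative")
  data.frame(cid = m$cid, x = x, y = y, stringsAsFactors = FALSE)
}

#' @rdname loadMask
#' @param mask Data.frame with columns `cid`, `x`, `y`.
#' @export
writeMask <- function(mask, path) {
  utils::write.table(mask[c("cid", "x", "y")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Demultiplex read 1 barcodes against a mask
#'
#' Splits each read 1 into its coordinate barcode (bases 1-25) and
#' molecular barcode (bases 26-35, both 1-based inclusive) and looks the
#' CID up in the mask. Reads whose CID is absent from the mask are dropped
#' and counted; reads shorter than `cidLength + midLength` are an error.
#'
#' @param read1 Character vector of read 1 sequences.
#' @param mask Mask data.frame from [loadMask()].
#' @param cidLength,midLength Barcode lengths (defaults 25 and 10).
#' @return A list with `assigned` (data.frame `read` \[index into `read1`\],
#'   `x`, `y`, `mid`) and `dropped` (count of unknown-CID reads).
#' @export
demuxReads <- function(read1, mask, cidLength = 25L, midLength = 10L) {
  minLen <- cidLength + midLength
  if (length(read1) && any(nchar(read1) < minLen))
    stop("read 1 shorter than ", minLen, " bases")
  cid <- substr(read1, 1L, cidLength)
  mid <- substr(read1, cidLength + 1L, minLen)
  hit <- match(cid, mask$cid)
  keep <- !is.na(hit)
  list(
    assigned = data.frame(read = which(keep), x = mask$x[hit[keep]],
                          y = mask$y[hit[keep]], mid = mid[keep],
                          stringsAsFactors = FALSE),
    dropped = sum(!keep))
}
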