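#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet subseq
NULL

#' ReferencePair: two 16S references differing at one diagnostic base
#'
#' An S4 container for the pair of mock full-length 16S rRNA reference
#' sequences that define the two symbiont phylotypes. The two sequences are
#' identical except at a single diagnostic position, where phylotype A
#' carries an \code{A} and phylotype G carries a \code{G}. A 47-nt window
#' containing the diagnostic base is the region used for read
#' classification: a read is assigned to a phylotype only if it contains
#' that phylotype's full window with zero mismatches.
#'
#' @slot seqA A [Biostrings::DNAString] for phylotype A.
#' @slot seqG A [Biostrings::DNAString] for phylotype G.
#' @slot diagnosticPos Integer, 1-based position of the discriminating base.
#' @slot window Integer vector of length 2, the 1-based inclusive bounds of
#'   the 47-nt classification window; must contain \code{diagnosticPos}.
#'
#' @seealso [makeReferencePair()], [classifyReads()]
#' @exportClass ReferencePair
setClass("ReferencePair",
  representation(
    seqA = "DNAString",
    seqG = "DNAString",
    diagnosticPos = "integer",
    window = "integer"
  )
)

setValidity("ReferencePair", function(object) {
  msg <- character(0)
  a <- as.character(object@seqA)
  g <- as.character(object@seqG)
  if (nchar(a) != nchar(g)) {
    msg <- c(msg, "seqA and seqG must have equal length")
  } else {
    diff <- which(strsplit(a, "")[[1]] != strsplit(g, "")[[1]])
    if (length(diff) != 1L) {
      msg <- c(msg, "seqA and seqG must differ at exactly one position")
    } else {
      if (diff != object@diagnosticPos)
        msg <- c(msg, "the single difference must lie at diagnosticPos")
      if (substr(a, diff, diff) != "A" || substr(g, diff, diff) != "G")
        msg <- c(msg, "seqA must carry A and seqG must carry G at diagnosticPos")
    }
  }
  w <- object@window
  if (length(w) != 2L || w[2] - w[1] + 1L != 47L)
    msg <- c(msg, "window must be a length-2 interval spanning 47 bases")
  else {
    if (object@diagnosticPos < w[1] || object@diagnosticPos > w[2])
      msg <- c(msg, "diagnosticPos must lie inside the window")
    if (w[1] < 1L || w[2] > nchar(a))
      msg <- c(msg, "window must lie within the reference")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferencePair", function(object) {
  cat("ReferencePair of", length(object@seqA), "nt references\n")
  cat("  diagnostic position:", object@diagnosticPos,
      "(A-allele vs G-allele)\n")
  cat("  classification window: [", object@window[1], ", ",
      object@window[2], "] (47 nt)\n", sep = "")
})

#' Accessors for ReferencePair objects
#'
#' @param x A [ReferencePair-class] object.
#' @param phylotype Which phylotype's window to extract, `"A"` or `"G"`.
#' @return `refSeqA()` and `refSeqG()` return the reference
#'   [Biostrings::DNAString]s; `diagnosticPos()` the 1-based diagnostic
#'   position; `diagnosticWindow()` the 47-nt window of the requested
#'   phylotype as a character string.
#' @name ReferencePair-accessors
NULL

#' @rdname ReferencePair-accessors
#' @export
refSeqA <- function(x) x@seqA

#' @rdname ReferencePair-accessors
#' @export
refSeqG <- function(x) x@seqG

#' @rdname ReferencePair-accessors
#' @export
diagnosticPos <- function(x) x@diagnosticPos

#' @rdname ReferencePair-accessors
#' @export
diagnosticWindow <- function(x, phylotype = c("A", "G")) {
  phylotype <- match.arg(phylotype)
  s <- if (phylotype == "A") x@seqA else x@seqG
  as.character(subseq(s, x@window[1], x@window[2]))
}

#' Generate a random reference pair with one diagnostic base
#'
#' Draws a random nucleotide sequence of length `refLength`, places an
#' \code{A} at `diagnosticPos` to form the phylotype A reference, and
#' substitutes it with \code{G} to form the phylotype G reference. All other
#' positions are identical, so the Hamming distance between the two
#' references is exactly 1 by construction.
#'
#' @param seed Integer seed; the pair is a deterministic function of it.
#' @param diagnosticPos 1-based position of the discriminating base.
#' @param window Length-2 integer vector, 1-based inclusive bounds of the
#'   47-nt classification window; must contain `diagnosticPos`.
#' @param refLength Total reference length in nt (default 1500, full-16S
#'   scale).
#' @return A [ReferencePair-class] object.
#' @examples
#' refs <- makeReferencePair(seed = 1)
#' refs
#' @export
makeReferencePair <- function(seed, diagnosticPos = 930L,
                              window = c(907L, 953L), refLength = 1500L) {
  window <- as.integer(window)
  diagnosticPos <- as.integer(diagnosticPos)
  if (length(window) != 2L || window[2] - window[1] + 1L != 47L)
    stop("'window' must be a 1-based inclusive interval of length 47")
  if (diagnosticPos < window[1] || diagnosticPos > window[2])
    stop("'diagnosticPos' must lie inside 'window'")
  if (window[1] < 1L || window[2] > refLength)
    stop("'window' must lie within the reference (refLength = ",
         refLength, ")")
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), refLength, replace = TRUE)
  base[diagnosticPos] <- "A"
  a <- paste(base, collapse = "")
  base[diagnosticPos] <- "G"
  g <- paste(base, collapse = "")
  new("ReferencePair", seqA = DNAString(a), seqG = DNAString(g),
      diagnosticPos = diagnosticPos, window = window)
}

#' Write and read a reference pair as FASTA
#'
#' The diagnostic position and window are encoded in the FASTA description
#' lines so that a pair written with `writeReferencePair()` round-trips
#' through `readReferencePair()`.
#'
#' @param refs A [ReferencePair-class] object.
#' @param path FASTA file path.
#' @return `writeReferencePair()` returns `path` invisibly;
#'   `readReferencePair()` returns a [ReferencePair-class].
#' @export
writeReferencePair <- function(refs, path) {
  ss <- DNAStringSet(c(as.character(refs@seqA), as.character(refs@seqG)))
  names(ss) <- sprintf(
    "phylotype%s diag=%d window=%d-%d",
    c("A", "G"), refs@diagnosticPos, refs@window[1], refs@window[2])
  writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname writeReferencePair
#' @export
readReferencePair <- function(path) {
  ss <- readDNAStringSet(path)
  if (length(ss) != 2L)
    stop("reference FASTA must contain exactly two sequences")
  nm <- names(ss)
  ia <- grep("^phylotypeA\\b", nm)
  ig <- grep("^phylotypeG\\b", nm)
  if (length(ia) != 1L || length(ig) != 1L)
    stop("reference FASTA must name its records 'phylotypeA' and 'phylotypeG'")
  diag <- as.integer(sub(".*\\bdiag=(\\d+).*", "\\1", nm[ia]))
  w1 <- as.integer(sub(".*\\bwindow=(\\d+)-(\\d+).*", "\\1", nm[ia]))
  w2 <- as.integer(sub(".*\\bwindow=(\\d+)-(\\d+).*", "\\2", nm[ia]))
  if (anyNA(c(diag, w1, w2)))
    stop("reference FASTA headers must carry 'diag=' and 'window=' fields")
  new("ReferencePair",
      seqA = DNAString(as.character(ss[[ia]])),
      seqG = DNAString(as.character(ss[[ig]])),
      diagnosticPos = diag, window = c(w1, w2))
}
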