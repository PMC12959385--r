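#' Alignment-ingestion filter for phylotype extraction
#'
#' The conjunctive filter applied to pre-aligned records before a
#' phylotype call is attempted: the read must be uniquely mapped (NH tag),
#' carry the aligner's required mapping quality, and align as one
#' contiguous match-only block of the diagnostic-window length (no indels,
#' no clipping). Defaults mirror the extraction tuple NH:i:1, MAPQ 255,
#' CIGAR 47M.
#'
#' @param requireUnique Require NH == 1.
#' @param requiredMapq Required mapping quality (default 255, the value
#'   STAR assigns to uniquely mapped reads).
#' @param requiredCigar Required CIGAR string (default `"47M"`).
#' @return A list of class `alignmentFilter`.
#' @export
alignmentFilter <- function(requireUnique = TRUE, requiredMapq = 255L,
                            requiredCigar = "47M") {
  structure(list(requireUnique = requireUnique,
                 requiredMapq = as.integer(requiredMapq),
                 requiredCigar = requiredCigar),
            class = "alignmentFilter")
}

#' Read alignment records from a SAM/BAM file
#'
#' Loads the fields the phylotype filter needs (position, MAPQ, CIGAR,
#' sequence, and the NH and NM tags) via Rsamtools. Plain-text SAM input is
#' converted with [Rsamtools::asBam()] first.
#'
#' @param path SAM or BAM file path (SAM files must carry a header).
#' @return Data.frame with columns `qname`, `pos`, `mapq`, `cigar`, `seq`,
#'   `nh`, `nm` (tags `NA` when absent).
#' @export
readSamRecords <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "pos", "mapq", "cigar", "seq"),
    tag = c("NH", "NM"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(r$qname)
  grab <- function(tag) {
    v <- r$tag[[tag]]
    if (is.null(v)) rep(NA_integer_, n) else as.integer(v)
  }
  data.frame(qname = r$qname, pos = r$pos, mapq = r$mapq,
             cigar = r$cigar, seq = as.character(r$seq),
             nh = grab("NH"), nm = grab("NM"),
             stringsAsFactors = FALSE)
}

#' Classify pre-aligned reads by the base over the diagnostic position
#'
#' Alignment-mode counterpart of [classifyReads()]: a record passes the
#' [alignmentFilter()] (uniquely mapped, required MAPQ, contiguous
#' match-only block) and is then called by the read base aligned over the
#' diagnostic reference position — A-allele gives phylotype A, G-allele
#' phylotype G, any other base (or a record not covering the position) is
#' `unclassified`. When the NM tag is present, mismatches at non-diagnostic
#' positions disqualify the record: records are assumed aligned to the
#' phylotype A reference, so a perfect phylotype G read carries NM = 1
#' (the diagnostic base) and a perfect A read NM = 0; anything beyond that
#' breaks the complete-match requirement. On indel-free reads this path
#' agrees with the sequence-mode classifier.
#'
#' @param records Data.frame of alignment records as returned by
#'   [readSamRecords()]; `pos`, `mapq`, `cigar` and `seq` are required.
#' @param refs A [ReferencePair-class] (supplies the diagnostic position).
#' @param filter An [alignmentFilter()].
#' @return Character vector of calls in `{"A", "G", "unclassified"}`.
#' @export
classifyAlignments <- function(records, refs, filter = alignmentFilter()) {
  stopifnot(is(refs, "ReferencePair"))
  req <- c("pos", "mapq", "cigar", "seq")
  if (!all(req %in% names(records)))
    stop("records must carry columns: ", paste(req, collapse = ", "))
  n <- nrow(records)
  if (n == 0L) return(character(0))
  nh <- if ("nh" %in% names(records)) records$nh else rep(NA_integer_, n)
  nm <- if ("nm" %in% names(records)) records$nm else rep(NA_integer_, n)

  pass <- records$mapq == filter$requiredMapq &
    records$cigar == filter$requiredCigar
  if (filter$requireUnique) pass <- pass & !is.na(nh) & nh == 1L
  pass[is.na(pass)] <- FALSE

  matchLen <- .cigarMatchLength(filter$requiredCigar)
  diag <- refs@diagnosticPos
  off <- diag - records$pos + 1L          # read offset over the diagnostic base
  covers <- !is.na(records$pos) & off >= 1L & off <= matchLen
  base <- rep(NA_character_, n)
  ok <- pass & covers
  base[ok] <- substr(records$seq[ok], off[ok], off[ok])

  call <- rep("unclassified", n)
  call[ok & base == "A"] <- "A"
  call[ok & base == "G"] <- "G"

  # complete-match requirement via NM, relative to the A reference
  hasNM <- !is.na(nm)
  expNM <- ifelse(call == "G", 1L, 0L)
  bad <- hasNM & call != "unclassified" & nm != expNM
  call[bad] <- "unclassified"
  call
}

# total M length of a match-only CIGAR; anything else (indels, clips) is 0
.cigarMatchLength <- function(cigar) {
  if (grepl("^\\d+M$", cigar)) as.integer(sub("M$", "", cigar)) else 0L
}
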