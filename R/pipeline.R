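#' @importFrom jsonlite write_json read_json
NULL

.writeManifest <- function(dir, step, parameters, files, counters = list()) {
  manifest <- list(
    step = step,
    package = "symbiospot",
    version = as.character(utils::packageVersion("symbiospot")),
    parameters = parameters,
    files = as.list(files),
    counters = counters,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, paste0(step, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a complete synthetic data set on disk
#'
#' Runs the synthetic-data generators end to end and writes every input
#' the downstream stages need: paired FASTQ reads, the CID-to-spot barcode
#' mask, the reference pair FASTA, the planted truth table, and a table of
#' simulated radiotracer incubations, plus a JSON manifest recording
#' parameters, seed and emitted files. Reruns with the same seed reproduce
#' byte-identical TSV/FASTA/FASTQ content.
#'
#' @param outDir Output directory (created if missing).
#' @param seed Integer seed driving every generator.
#' @param gridWidth,gridHeight,fieldModel,nDomains,mixingBeta Field
#'   parameters, see [simulateField()].
#' @param meanReadsPerSpot,errorRate Read-simulation parameters, see
#'   [simulateReads()].
#' @param refLength,diagnosticPosition,window Reference parameters, see
#'   [makeReferencePair()].
#' @param incubation Named list of arguments forwarded to
#'   [simulateIncubations()] (e.g. `trueK`, `nReplicates`, `tDays`);
#'   `NULL` skips the incubation table.
#' @return Named character vector of written file paths, invisibly.
#' @export
runSimulate <- function(outDir, seed = 1L,
                        gridWidth = 40L, gridHeight = 40L,
                        fieldModel = "domain-mosaic", nDomains = 4L,
                        mixingBeta = 1, meanReadsPerSpot = 50,
                        errorRate = 0.001, refLength = 1500L,
                        diagnosticPosition = 930L, window = c(907L, 953L),
                        incubation = list(trueK = 7.4e-4, nReplicates = 6L,
                                          tDays = 1.94)) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  refs <- makeReferencePair(seed = seed, diagnosticPos = diagnosticPosition,
                            window = window, refLength = refLength)
  truth <- simulateField(gridWidth, gridHeight, fieldModel,
                         nDomains = nDomains, mixingBeta = mixingBeta,
                         seed = seed + 1L)
  sim <- simulateReads(truth, refs, meanReadsPerSpot = meanReadsPerSpot,
                       errorRate = errorRate, seed = seed + 2L)

  files <- writeSimulatedReads(sim, outDir)
  refPath <- file.path(outDir, "references.fasta")
  writeReferencePair(refs, refPath)
  truthPath <- file.path(outDir, "truth.tsv")
  utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, refs = refPath, truth = truthPath)

  if (!is.null(incubation)) {
    inc <- do.call(simulateIncubations,
                   c(incubation, list(seed = seed + 3L)))
    incPath <- file.path(outDir, "incubations.tsv")
    writeIncubations(inc, incPath)
    files <- c(files, incubations = incPath)
  }
  .writeManifest(outDir, "simulate",
                 parameters = list(
                   seed = seed, gridWidth = gridWidth,
                   gridHeight = gridHeight, fieldModel = fieldModel,
                   nDomains = nDomains, mixingBeta = mixingBeta,
                   meanReadsPerSpot = meanReadsPerSpot,
                   errorRate = errorRate, refLength = refLength,
                   diagnosticPosition = diagnosticPosition,
                   window = window, incubation = incubation),
                 files = files,
                 counters = list(nSpots = nrow(truth),
                                 nReads = length(sim$read1)))
  invisible(files)
}

#' Run the spatial phylotyping pipeline on files
#'
#' Wires the phylotyping stages in order — demultiplex read 1 against the
#' barcode mask, classify read 2 by exact diagnostic-window match (or, when
#' `sam` is given, classify pre-aligned records through the alignment
#' filter), accumulate per-spot counts, aggregate into bins, call dominant
#' phylotypes and summarize spatial heterogeneity — and writes the spot
#' table, bin table, JSON summary and a manifest with full stage counters.
#'
#' @param r1,r2 FASTQ paths for read 1 and read 2.
#' @param mask TSV barcode-mask path.
#' @param refs Reference-pair FASTA path (see [writeReferencePair()]).
#' @param outDir Output directory (created if missing).
#' @param sam Optional SAM/BAM path; when given, calls come from
#'   [classifyAlignments()] on these records (matched to reads by name
#'   order) instead of sequence-mode classification.
#' @param binSize,minReads,dominance Binning and calling parameters.
#' @param dedupMid Collapse molecular-barcode duplicates?
#' @return Invisibly, a list with `spots`, `bins`, `summary`, `counters`
#'   and the written `files`.
#' @export
runPhylotype <- function(r1, r2, mask, refs, outDir, sam = NULL,
                         binSize = 20L, minReads = 180L, dominance = 0.95,
                         dedupMid = FALSE) {
  for (p in c(r1, r2, mask, refs))
    if (!file.exists(p)) stop("input not found: ", p)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  maskDf <- loadMask(mask)
  refPair <- readReferencePair(refs)
  r1set <- Biostrings::readDNAStringSet(r1, format = "fastq")
  read1 <- as.character(r1set)
  readIds <- sub("\\s.*$", "", names(r1set))
  read2 <- readFastqSequences(r2)
  if (length(read1) != length(read2))
    stop("read 1 and read 2 files differ in read count")

  counters <- list(readsIn = length(read1))
  empty <- length(read1) == 0L
  if (empty) {
    dmx <- list(assigned = data.frame(read = integer(0), x = integer(0),
                                      y = integer(0), mid = character(0)),
                dropped = 0L)
    calls <- character(0)
  } else {
    dmx <- demuxReads(read1, maskDf)
    calls <- if (is.null(sam)) {
      classifyReads(read2[dmx$assigned$read], refPair)
    } else {
      rec <- readSamRecords(sam)
      allCalls <- classifyAlignments(rec, refPair)
      idx <- match(readIds[dmx$assigned$read], rec$qname)
      out <- rep("unclassified", nrow(dmx$assigned))
      out[!is.na(idx)] <- allCalls[idx[!is.na(idx)]]
      out
    }
  }
  counters$demuxDropped <- dmx$dropped
  counters$classifiedA <- sum(calls == "A")
  counters$classifiedG <- sum(calls == "G")
  counters$unclassified <- sum(calls == "unclassified")

  classified <- cbind(dmx$assigned[c("x", "y", "mid")], call = calls)
  spots <- accumulateCounts(classified, dedupMid = dedupMid)
  spotPath <- file.path(outDir, "spots.tsv")
  writeSpotTable(spots, spotPath)

  bins <- callBins(binAggregate(spots, binSize = binSize,
                                minReads = minReads),
                   dominance = dominance)
  binPath <- file.path(outDir, "bins.tsv")
  writeBinTable(bins, binPath)
  counters$validBins <- sum(bins$valid)

  summaryPath <- file.path(outDir, "summary.json")
  summary <- if (counters$validBins > 0L) summarizeBins(bins) else NULL
  jsonlite::write_json(
    c(summary, list(counters = counters)), summaryPath,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  files <- c(spots = spotPath, bins = binPath, summary = summaryPath)
  .writeManifest(outDir, "phylotype",
                 parameters = list(r1 = r1, r2 = r2, mask = mask,
                                   refs = refs, sam = sam,
                                   binSize = binSize, minReads = minReads,
                                   dominance = dominance,
                                   dedupMid = dedupMid),
                 files = files, counters = counters)
  invisible(list(spots = spots, bins = bins, summary = summary,
                 counters = counters, files = files))
}

#' Load incubation records from TSV
#'
#' @param path Tab-delimited file with header columns `label`, `dpm_poc`,
#'   `dpm_dic`, `t_days`, `dic_mmol_per_l`, `volume_l`, `norm_factor` and
#'   optionally `control_dpm`, `temperature_c`, `is_control`.
#' @return Data.frame of incubation records.
#' @export
loadIncubations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("label", "dpm_poc", "dpm_dic", "t_days", "dic_mmol_per_l",
           "volume_l", "norm_factor")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("incubation table lacks columns: ", paste(miss, collapse = ", "))
  if (!"control_dpm" %in% names(df)) df$control_dpm <- 0
  if (!"temperature_c" %in% names(df)) df$temperature_c <- NA_real_
  if (!"is_control" %in% names(df)) df$is_control <- FALSE
  df
}

#' Run the radiotracer rate pipeline on an incubation table
#'
#' Computes the turnover rate constant and DIC assimilation rate for every
#' experimental row of an incubation TSV, isolating row-level failures
#' (e.g. filter activity at or above the total tracer activity, for which
#' the logarithm is undefined): bad rows get `NA` results and an error
#' message naming their line, while the remaining rows are processed.
#' When the table carries at least four distinct temperatures, the
#' temperature response is fitted at `fitDegree` (and at degree 2 for
#' comparison) and the cubic's interior peak temperature is reported.
#'
#' @param incubations Path to an incubation TSV (see [loadIncubations()]).
#' @param outDir Output directory (created if missing).
#' @param subtractControl Subtract killed-control blanks before computing
#'   k (off by default)?
#' @param fitDegree Polynomial degree for the temperature fit (2 or 3).
#' @return Invisibly, a list with `rates` (per-row data.frame), `fit`
#'   (a `tempFit` or `NULL`), `peak` (degrees C or `NA`), `errors`
#'   (row-level messages) and `files`.
#' @export
runRates <- function(incubations, outDir, subtractControl = FALSE,
                     fitDegree = 3L) {
  if (!file.exists(incubations)) stop("input not found: ", incubations)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  df <- loadIncubations(incubations)
  exper <- !df$is_control

  k <- rep(NA_real_, nrow(df))
  errors <- character(0)
  for (i in which(exper)) {
    res <- tryCatch(
      turnoverK(df$dpm_poc[i], df$dpm_dic[i], df$t_days[i],
                control_dpm = df$control_dpm[i],
                subtractControl = subtractControl),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("row %d (%s): %s", i + 1L, df$label[i],
                                  conditionMessage(res)))
    } else k[i] <- res
  }
  rate <- ifelse(is.na(k), NA_real_,
                 assimRate(k, df$dic_mmol_per_l, df$volume_l,
                           df$norm_factor))
  out <- cbind(df, k_per_day = k, assim_nmol_per_day = rate)
  ratePath <- file.path(outDir, "rates.tsv")
  utils::write.table(out, ratePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  fit <- NULL; peak <- NA_real_; fitQuad <- NULL
  ok <- exper & !is.na(k) & !is.na(df$temperature_c)
  if (length(unique(df$temperature_c[ok])) > fitDegree) {
    fit <- fitTemperatureResponse(df$temperature_c[ok], k[ok], fitDegree)
    if (length(unique(df$temperature_c[ok])) > 2L)
      fitQuad <- fitTemperatureResponse(df$temperature_c[ok], k[ok], 2L)
    if (fit$degree == 3L)
      peak <- tryCatch(peakTemperature(fit), error = function(e) NA_real_)
  }
  fitPath <- file.path(outDir, "fit.json")
  jsonlite::write_json(list(
    fit = if (is.null(fit)) NULL else fit[c("degree", "coefficients",
                                            "r2", "adjusted_r2", "aicc")],
    quadratic = if (is.null(fitQuad)) NULL else
      fitQuad[c("degree", "coefficients", "r2", "adjusted_r2", "aicc")],
    peak_temperature_c = peak,
    errors = errors),
    fitPath, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  files <- c(rates = ratePath, fit = fitPath)
  .writeManifest(outDir, "rates",
                 parameters = list(incubations = incubations,
                                   subtractControl = subtractControl,
                                   fitDegree = fitDegree),
                 files = files,
                 counters = list(rowsIn = nrow(df),
                                 rowsComputed = sum(!is.na(k)),
                                 rowsFailed = length(errors)))
  invisible(list(rates = out, fit = fit, peak = peak, errors = errors,
                 files = files))
}
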