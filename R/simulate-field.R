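#' Simulate a planted two-phylotype spatial field
#'
#' Generates the per-spot true fraction of phylotype A over a rectangular
#' spot lattice, emulating the two spatial regimes seen in chemosymbiotic
#' gill sections: a mosaic of spatially segregated single-phylotype domains,
#' or a well-mixed field where both phylotypes co-occur in every spot.
#'
#' For `fieldModel = "domain-mosaic"` the grid is partitioned into
#' `nDomains` contiguous domains by seeded multi-source random region
#' growth (each domain grows from a random seed spot by uniform frontier
#' expansion, so contiguity holds by construction), and every spot in a
#' domain gets the domain's pure fraction, 0 or 1. Domain alleles are drawn
#' Bernoulli(0.5), except that with a single domain the whole field is one
#' pure phylotype.
#'
#' For `fieldModel = "well-mixed"` each spot's fraction is drawn
#' independently from Beta(`mixingBeta`, `mixingBeta`); large `mixingBeta`
#' concentrates fractions near 0.5.
#'
#' @param gridWidth,gridHeight Spot-lattice dimensions (spots are the unit
#'   lattice, one DNA-nanoball pitch); both must be at least 20.
#' @param fieldModel `"domain-mosaic"` or `"well-mixed"`.
#' @param nDomains Number of contiguous domains (domain-mosaic model).
#' @param mixingBeta Positive dispersion parameter of the symmetric Beta
#'   distribution (well-mixed model).
#' @param tissueMask Optional data.frame with integer columns `x`, `y`
#'   (0-based) restricting the field to covered spots; default is the full
#'   grid. Must be non-empty.
#' @param seed Integer seed; the field is a deterministic function of it.
#' @return A truth table: data.frame with columns `x`, `y` (0-based spot
#'   coordinates), `fracA` (true phylotype-A fraction in \[0,1\]) and, for
#'   the mosaic model, `domain` (1-based domain label).
#' @examples
#' truth <- simulateField(20, 20, "domain-mosaic", nDomains = 2, seed = 1)
#' table(truth$fracA)
#' @export
simulateField <- function(gridWidth, gridHeight,
                          fieldModel = c("domain-mosaic", "well-mixed"),
                          nDomains = 4L, mixingBeta = 1,
                          tissueMask = NULL, seed = 1L) {
  fieldModel <- match.arg(fieldModel)
  gridWidth <- as.integer(gridWidth)
  gridHeight <- as.integer(gridHeight)
  if (gridWidth < 20L || gridHeight < 20L)
    stop("grid dimensions must be at least 20 spots")
  if (mixingBeta <= 0) stop("'mixingBeta' must be positive")
  if (is.null(tissueMask)) {
    tissueMask <- expand.grid(x = seq_len(gridWidth) - 1L,
                              y = seq_len(gridHeight) - 1L)
  }
  if (nrow(tissueMask) == 0L) stop("'tissueMask' must cover at least one spot")
  if (any(tissueMask$x < 0L | tissueMask$x >= gridWidth |
          tissueMask$y < 0L | tissueMask$y >= gridHeight))
    stop("'tissueMask' spots must lie inside the grid")

  set.seed(seed)
  out <- data.frame(x = as.integer(tissueMask$x),
                    y = as.integer(tissueMask$y))
  if (fieldModel == "well-mixed") {
    out$fracA <- stats::rbeta(nrow(out), mixingBeta, mixingBeta)
    return(out)
  }
  nDomains <- as.integer(nDomains)
  if (nDomains < 1L) stop("'nDomains' must be at least 1")
  if (nDomains > nrow(out)) stop("'nDomains' exceeds the number of spots")
  out$domain <- .growDomains(out$x, out$y, gridWidth, gridHeight, nDomains)
  allele <- if (nDomains == 1L) sample(c(0, 1), 1L) else
    stats::rbinom(nDomains, 1L, 0.5)
  out$fracA <- allele[out$domain]
  out
}

# Multi-source random region growth over the masked lattice. Spots are
# addressed by linear index y*gridWidth + x + 1; growth picks a uniformly
# random (assigned spot -> unassigned 4-neighbour) frontier edge each step,
# so every domain is 4-connected by construction.
.growDomains <- function(x, y, gridWidth, gridHeight, nDomains) {
  n <- length(x)
  lin <- y * gridWidth + x + 1L
  inMask <- integer(gridWidth * gridHeight)  # 0 = outside mask
  inMask[lin] <- seq_len(n)                  # mask row index
  assign <- integer(n)                       # 0 = unassigned

  neighbours <- function(l) {
    xx <- (l - 1L) %% gridWidth
    yy <- (l - 1L) %/% gridWidth
    out <- integer(0)
    if (xx > 0L) out <- c(out, l - 1L)
    if (xx < gridWidth - 1L) out <- c(out, l + 1L)
    if (yy > 0L) out <- c(out, l - gridWidth)
    if (yy < gridHeight - 1L) out <- c(out, l + gridWidth)
    out[inMask[out] > 0L]
  }

  seeds <- sample.int(n, nDomains)
  assign[seeds] <- seq_len(nDomains)
  # frontier edges as (target mask-index, domain) pairs
  ft <- integer(0); fd <- integer(0)
  for (d in seq_len(nDomains)) {
    nb <- inMask[neighbours(lin[seeds[d]])]
    ft <- c(ft, nb); fd <- c(fd, rep.int(d, length(nb)))
  }
  while (length(ft)) {
    i <- sample.int(length(ft), 1L)
    tgt <- ft[i]; dom <- fd[i]
    if (assign[tgt] == 0L) {
      assign[tgt] <- dom
      nb <- inMask[neighbours(lin[tgt])]
      nb <- nb[assign[nb] == 0L]
      ft <- c(ft, nb); fd <- c(fd, rep.int(dom, length(nb)))
    }
    keep <- assign[ft] == 0L
    ft <- ft[keep]; fd <- fd[keep]
  }
  # disconnected mask components with no seed stay 0; assign them to domain 1
  assign[assign == 0L] <- 1L
  assign
}
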