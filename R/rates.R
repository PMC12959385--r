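#' Turnover rate constant of the DIC pool from a radiotracer incubation
#'
#' First-order turnover of the dissolved-inorganic-carbon pool: if a
#' fraction \eqn{f = DPM_{POC} / DPM_{DIC}} of the added 14C tracer is
#' recovered in particulate organic carbon after \eqn{t} days, the per-day
#' turnover rate constant is
#' \deqn{k = -\ln(1 - f) / t.}
#' With `subtractControl = TRUE`, the killed-control filter activity is
#' subtracted from `dpm_poc` first (floored at 0), removing abiotic tracer
#' adsorption.
#'
#' All arguments are vectorized over records.
#'
#' @param dpm_poc Filter activity, DPM (the 14C recovered in POC).
#' @param dpm_dic Total activity of the added DIC tracer, DPM; positive.
#' @param t_days Incubation duration, days; positive.
#' @param control_dpm Killed-control filter activity, DPM (used only when
#'   `subtractControl` is on; default 0).
#' @param subtractControl Subtract the control blank from `dpm_poc`?
#' @return Turnover rate constant(s), per day.
#' @examples
#' turnoverK(dpm_poc = 13.69, dpm_dic = 3.7e4, t_days = 0.5)
#' @export
turnoverK <- function(dpm_poc, dpm_dic, t_days, control_dpm = 0,
                      subtractControl = FALSE) {
  if (any(dpm_dic <= 0)) stop("'dpm_dic' must be positive")
  if (any(t_days <= 0)) stop("'t_days' must be positive")
  if (any(dpm_poc < 0)) stop("'dpm_poc' must be non-negative")
  eff <- dpm_poc
  if (subtractControl) {
    ctl <- ifelse(is.na(control_dpm), 0, control_dpm)
    eff <- pmax(dpm_poc - ctl, 0)
  }
  bad <- eff >= dpm_dic
  if (any(bad))
    stop("filter activity reaches total tracer activity (record ",
         paste(which(bad), collapse = ", "),
         "): turnover is undefined")
  -log1p(-eff / dpm_dic) / t_days
}

#' DIC assimilation rate from a turnover rate constant
#'
#' Converts a turnover rate constant into an absolute carbon assimilation
#' rate for the incubated unit:
#' \deqn{Assim = k \times [DIC] \times c \times V \times norm}
#' with \eqn{k} in day^-1, \eqn{[DIC]} the seawater DIC concentration in
#' mmol/L, \eqn{V} the incubation volume in litres (0.015 for a live clam,
#' 0.010 for a gill-homogenate vial), \eqn{norm} the per-clam normalization
#' (1 for a live clam; 4 for a gill vial holding a quarter of one clam's
#' symbionts) and \eqn{c} the mmol-to-nmol conversion, `nmolPerMmol =`
#' 1e6. The result is in nmol C per clam per day.
#'
#' @param k Turnover rate constant, day^-1 (vectorized).
#' @param dic_mmol_per_l DIC concentration, mmol/L.
#' @param volume_l Incubation volume, litres.
#' @param norm_factor Per-clam normalization factor.
#' @param nmolPerMmol Unit conversion constant (nmol per mmol; default 1e6).
#' @return Assimilation rate(s), nmol C clam^-1 day^-1.
#' @examples
#' assimRate(k = 7.4e-4, dic_mmol_per_l = 2.64)            # live clam
#' assimRate(k = 1.593e-3, dic_mmol_per_l = 3.07,
#'           volume_l = 0.010, norm_factor = 4)            # gill vial
#' @export
assimRate <- function(k, dic_mmol_per_l, volume_l = 0.015,
                      norm_factor = 1, nmolPerMmol = 1e6) {
  if (any(is.na(dic_mmol_per_l)))
    stop("missing DIC concentration")
  k * dic_mmol_per_l * nmolPerMmol * volume_l * norm_factor
}

#' Seawater DIC assimilation rate per 100 ml
#'
#' Microbial DIC assimilation of an organism-free seawater incubation,
#' normalized to 100 ml of incubation water:
#' \eqn{rate = k \times [DIC] \times 10^6 \times 0.1\,L}.
#'
#' @inheritParams assimRate
#' @param per_ml Normalization volume in ml (default 100).
#' @return Rate(s) in nmol C per `per_ml` ml per day.
#' @examples
#' seawaterRate(k = 3.5e-5, dic_mmol_per_l = 2.41)
#' @export
seawaterRate <- function(k, dic_mmol_per_l, per_ml = 100,
                         nmolPerMmol = 1e6) {
  assimRate(k, dic_mmol_per_l, volume_l = per_ml / 1000,
            norm_factor = 1, nmolPerMmol = nmolPerMmol)
}

#' Seawater-equivalence volume of a holobiont's carbon fixation
#'
#' The volume of surrounding seawater whose microbial DIC assimilation
#' matches one holobiont: `100 * clamRate / seawaterRate` ml.
#'
#' @param clamRate Holobiont rate, nmol C clam^-1 day^-1.
#' @param swRate Seawater rate, nmol C (100 ml)^-1 day^-1; positive.
#' @return Equivalent seawater volume in ml.
#' @examples
#' equivalenceVolume(29.3, 8.43)
#' @export
equivalenceVolume <- function(clamRate, swRate) {
  if (any(swRate <= 0)) stop("seawater rate must be positive")
  100 * clamRate / swRate
}

#' Each temperature's mean rate constant as a percentage of the maximum
#'
#' @param temperature_c Temperatures, degrees C (length at least 2).
#' @param k Mean rate constants per temperature; not all zero.
#' @return Integer percentages of the maximum, named by temperature.
#' @examples
#' ratioToMax(c(5, 12, 20, 28), c(2.15e-3, 5.09e-3, 4.79e-3, 3.51e-3))
#' @export
ratioToMax <- function(temperature_c, k) {
  if (length(k) < 2L) stop("need at least 2 temperatures")
  if (all(k == 0)) stop("all rate constants are zero")
  stats::setNames(as.integer(round(100 * k / max(k))),
                  as.character(temperature_c))
}
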