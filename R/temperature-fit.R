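#' Polynomial temperature-response fit of the rate constant
#'
#' Ordinary least-squares fit of a quadratic or cubic polynomial to
#' (temperature, rate constant) observations, replicate-level or
#' mean-level. With exactly `degree + 1` distinct temperatures the fit
#' interpolates the per-temperature means. Model comparison between the
#' two degrees uses adjusted R-squared as the primary criterion, with the
#' small-sample-corrected Akaike information criterion (AICc) reported
#' alongside (AICc is infinite when the residual degrees of freedom are
#' too few to correct, as for a cubic through four points).
#'
#' @param temperature_c Temperatures, degrees C.
#' @param k Rate constants, day^-1, paired with `temperature_c`.
#' @param degree Polynomial degree, 2 or 3; must be smaller than the
#'   number of distinct temperatures.
#' @return An object of class `tempFit`: list with `degree`,
#'   `coefficients` (ascending powers, intercept first), `r2`,
#'   `adjusted_r2`, `aicc`, `residuals`, `fitted` and the input `data`.
#' @examples
#' fit <- fitTemperatureResponse(c(5, 12, 20, 28),
#'                               c(2.15e-3, 5.09e-3, 4.79e-3, 3.51e-3), 3)
#' fit$coefficients
#' @export
fitTemperatureResponse <- function(temperature_c, k, degree = 3L) {
  degree <- as.integer(degree)
  if (!degree %in% c(2L, 3L)) stop("'degree' must be 2 or 3")
  nDistinct <- length(unique(temperature_c))
  if (nDistinct <= degree)
    stop("need more than ", degree, " distinct temperatures for a degree-",
         degree, " fit")
  fit <- stats::lm(k ~ stats::poly(temperature_c, degree, raw = TRUE))
  # interpolation through degree+1 means is a legitimate use; mute lm's
  # perfect-fit caveat for that case
  s <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  n <- length(k)
  p <- degree + 2L  # polynomial coefficients + residual variance
  rss <- sum(stats::residuals(fit)^2)
  aicc <- if (n - p - 1L > 0L && rss > 0) {
    n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1L)
  } else Inf
  structure(list(
    degree = degree,
    coefficients = stats::setNames(as.numeric(stats::coef(fit)),
                                   paste0("T^", 0:degree)),
    r2 = s$r.squared,
    adjusted_r2 = s$adj.r.squared,
    aicc = aicc,
    residuals = as.numeric(stats::residuals(fit)),
    fitted = as.numeric(stats::fitted(fit)),
    data = data.frame(temperature_c = temperature_c, k = k)),
    class = "tempFit")
}

#' @export
print.tempFit <- function(x, ...) {
  cat("Temperature-response polynomial fit (degree ", x$degree, ")\n",
      sep = "")
  cat("  coefficients (ascending):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  cat("  R2 =", signif(x$r2, 4), " adjusted R2 =",
      signif(x$adjusted_r2, 4), "\n")
  invisible(x)
}

#' Predict from a temperature-response fit
#'
#' @param object A `tempFit`.
#' @param newdata Numeric vector of temperatures.
#' @param ... Unused.
#' @return Predicted rate constants.
#' @export
predict.tempFit <- function(object, newdata, ...) {
  cf <- object$coefficients
  vapply(newdata, function(t) sum(cf * t^(0:object$degree)), numeric(1))
}

#' Temperature of the interior stationary maximum of a cubic fit
#'
#' For a cubic fit \eqn{k(T) = c_0 + c_1 T + c_2 T^2 + c_3 T^3} the
#' stationary points solve the derivative quadratic
#' \eqn{c_1 + 2 c_2 T + 3 c_3 T^2 = 0} in closed form; the one with
#' negative second derivative that lies strictly inside `range` is the
#' predicted thermal optimum. With `method = "grid"` the optimum is
#' instead located by exhaustive evaluation on a fixed-step temperature
#' grid, which serves as an independent numerical cross-check of the
#' closed form.
#'
#' @param fit A degree-3 `tempFit`.
#' @param range Length-2 numeric, temperature interval to search (default
#'   the fitted data range).
#' @param method `"closed-form"` (default) or `"grid"`.
#' @param gridStep Grid spacing in degrees C for `method = "grid"`
#'   (default 0.001).
#' @return The peak temperature in degrees C.
#' @examples
#' fit <- fitTemperatureResponse(c(5, 12, 20, 28),
#'                               c(2.15e-3, 5.09e-3, 4.79e-3, 3.51e-3), 3)
#' peakTemperature(fit)
#' @export
peakTemperature <- function(fit, range = NULL,
                            method = c("closed-form", "grid"),
                            gridStep = 0.001) {
  method <- match.arg(method)
  if (!inherits(fit, "tempFit") || fit$degree != 3L)
    stop("'fit' must be a degree-3 temperature-response fit")
  if (is.null(range)) range <- range(fit$data$temperature_c)
  cf <- fit$coefficients
  if (method == "grid") {
    grid <- seq(range[1], range[2], by = gridStep)
    best <- grid[which.max(predict(fit, grid))]
    if (best <= range[1] + gridStep / 2 || best >= range[2] - gridStep / 2)
      stop("no interior maximum in range")
    return(best)
  }
  a <- 3 * cf[4]; b <- 2 * cf[3]; cc <- cf[2]
  if (a == 0) {
    if (b == 0) stop("no interior maximum in range")
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("no interior maximum in range")
    # numerically stable quadratic roots (avoids cancellation when the
    # cubic term is nearly degenerate)
    q <- -(b + sign(b + (b == 0)) * sqrt(disc)) / 2
    roots <- unique(c(q / a, if (q != 0) cc / q else -b / a - q / a))
  }
  curv <- 2 * cf[3] + 6 * cf[4] * roots
  cand <- roots[curv < 0 & roots > range[1] & roots < range[2]]
  if (length(cand) == 0L) stop("no interior maximum in range")
  unname(cand[1])
}
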