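test_that("turnover rate constant follows the closed form", {
  expect_equal(turnoverK(0, 100, 1), 0)
  expect_equal(turnoverK(50, 100, 1), log(2))
  # f = 3.7e-4, t = 0.5: high-precision series oracle -ln(1-f) = sum f^i/i
  f <- 3.7e-4
  series <- sum(f^(1:10) / (1:10))
  expect_equal(turnoverK(f * 3.7e4, 3.7e4, 0.5), series / 0.5,
               tolerance = 1e-12)
  expect_equal(series / 0.5, 7.40137e-4, tolerance = 1e-6)
})

test_that("turnoverK validates records and isolates undefined logarithms", {
  expect_error(turnoverK(100, 100, 1), "record 1")
  expect_error(turnoverK(150, 100, 1), "undefined")
  expect_error(turnoverK(10, 100, 0), "t_days")
  expect_error(turnoverK(10, 0, 1), "dpm_dic")
  expect_error(turnoverK(-1, 100, 1), "non-negative")
  # control subtraction floors at zero
  expect_equal(turnoverK(5, 100, 1, control_dpm = 10,
                         subtractControl = TRUE), 0)
  expect_lt(turnoverK(50, 100, 1, control_dpm = 10,
                      subtractControl = TRUE), turnoverK(50, 100, 1))
})

test_that("small-fraction bounds and monotonicity of k hold", {
  set.seed(50)
  f <- runif(200, 1e-6, 0.01)
  t <- runif(200, 0.1, 3)
  k <- turnoverK(f * 1e5, 1e5, t)
  expect_true(all(k >= f / t))
  expect_true(all(k <= (f + f^2) / t))
  # increasing in dpm_poc, decreasing in t
  expect_true(all(diff(turnoverK(1:99, 100, 1)) > 0))
  expect_true(all(diff(turnoverK(50, 100, 1:10)) < 0))
})

test_that("assimilation rates reproduce the live-clam and gill arithmetic", {
  # live clam: k 7.4e-4 /day, DIC 2.64 mmol/L, 15 ml, x1
  expect_equal(assimRate(7.4e-4, 2.64), 29.304, tolerance = 1e-10)
  # gill vial: k 1.593e-3 /day, DIC 3.07 mmol/L, 10 ml, x4 per clam
  expect_equal(assimRate(1.593e-3, 3.07, volume_l = 0.010,
                         norm_factor = 4), 195.62, tolerance = 1e-3)
  expect_equal(assimRate(0, 2.64), 0)
  # linear in every factor
  base <- assimRate(1e-3, 2, volume_l = 0.01, norm_factor = 1)
  expect_equal(assimRate(2e-3, 2, volume_l = 0.01), 2 * base)
  expect_equal(assimRate(1e-3, 4, volume_l = 0.01), 2 * base)
  expect_equal(assimRate(1e-3, 2, volume_l = 0.02), 2 * base)
  expect_equal(assimRate(1e-3, 2, volume_l = 0.01, norm_factor = 2),
               2 * base)
  expect_error(assimRate(1e-3, NA), "DIC")
})

test_that("seawater rates and equivalence volumes follow their definitions", {
  expect_equal(seawaterRate(3.5e-5, 2.41), 8.435, tolerance = 1e-10)
  expect_equal(seawaterRate(0, 2.41), 0)
  expect_equal(seawaterRate(3.5e-5, 4.82), 2 * seawaterRate(3.5e-5, 2.41))
  expect_equal(equivalenceVolume(8.43, 8.43), 100)
  expect_equal(equivalenceVolume(29.3, 8.43), 100 * 29.3 / 8.43)
  expect_equal(equivalenceVolume(58.6, 8.43), 2 * equivalenceVolume(29.3, 8.43))
  expect_error(equivalenceVolume(29.3, 0), "positive")
})

test_that("polynomial fits interpolate, nest and compare as expected", {
  tc <- c(5, 12, 20, 28)
  km <- c(2.15e-3, 5.09e-3, 4.79e-3, 3.51e-3)
  fit3 <- fitTemperatureResponse(tc, km, 3)
  expect_lt(max(abs(fit3$residuals)), 1e-9 * max(abs(km)))
  expect_equal(predict(fit3, tc), km, tolerance = 1e-9)

  # data on an exact parabola: degree 2 fits exactly, cubic term vanishes
  tp <- c(2, 8, 14, 21, 27)
  kp <- 1e-3 * (5 - 0.01 * (tp - 15)^2)
  fit2 <- fitTemperatureResponse(tp, kp, 2)
  expect_lt(max(abs(fit2$residuals)), 1e-12)
  fit3p <- fitTemperatureResponse(tp, kp, 3)
  expect_lt(abs(fit3p$coefficients["T^3"]), 1e-12)

  # noisy cubic-shaped replicates: adjusted R2 prefers the cubic
  set.seed(51)
  tr <- rep(c(5, 12, 20, 28), each = 4)
  mu <- predict(fit3, tr)
  kr <- mu + rnorm(length(tr), 0, 2e-4)
  f3 <- fitTemperatureResponse(tr, kr, 3)
  f2 <- fitTemperatureResponse(tr, kr, 2)
  expect_gt(f3$adjusted_r2, f2$adjusted_r2)
  expect_lt(f3$aicc, f2$aicc)

  expect_error(fitTemperatureResponse(c(5, 12, 20), 1:3 * 1e-3, 3),
               "distinct temperatures")
  expect_error(fitTemperatureResponse(tc, km, 4), "2 or 3")
})

test_that("the closed-form peak matches grid search and symmetry", {
  tc <- c(5, 12, 20, 28)
  km <- c(2.15e-3, 5.09e-3, 4.79e-3, 3.51e-3)
  fit <- fitTemperatureResponse(tc, km, 3)
  closed <- peakTemperature(fit)
  grid <- peakTemperature(fit, method = "grid")
  expect_lt(abs(closed - grid), 0.002)

  # symmetric data peak at the middle temperature
  ts <- c(5, 10, 15, 20, 25)
  ks <- 1e-3 * (4 - (ts - 15)^2 / 100)
  fits <- fitTemperatureResponse(ts, ks, 3)
  expect_equal(peakTemperature(fits, range = c(5, 25)), 15,
               tolerance = 1e-6)

  # monotone cubic: no interior maximum
  mono <- fitTemperatureResponse(c(5, 12, 20, 28),
                                 c(1, 2, 3, 4) * 1e-3, 3)
  expect_error(peakTemperature(mono), "no interior maximum")

  # property: closed form vs 0.001-degree grid on 100 random cubics
  set.seed(52)
  nOK <- 0
  while (nOK < 100) {
    tt <- sort(runif(6, 0, 30))
    kk <- rnorm(6)
    f <- fitTemperatureResponse(tt, kk, 3)
    cl <- tryCatch(peakTemperature(f, range = c(0, 30)),
                   error = function(e) NULL)
    if (is.null(cl)) next
    gr <- tryCatch(peakTemperature(f, range = c(0, 30), method = "grid"),
                   error = function(e) NULL)
    if (is.null(gr)) next
    expect_lt(abs(cl - gr), 0.002)
    nOK <- nOK + 1
  }
})

test_that("the 28-degree rate constant sits at 69% of the thermal maximum", {
  pct <- ratioToMax(c(5, 12, 20, 28),
                    c(2.15e-3, 5.09e-3, 4.79e-3, 3.51e-3))
  expect_identical(unname(pct["28"]), 69L)
  expect_identical(unname(pct["12"]), 100L)
  expect_identical(unname(ratioToMax(c(1, 2), c(1, 0.5))[2]), 50L)
  expect_error(ratioToMax(c(1, 2), c(0, 0)), "zero")
  expect_error(ratioToMax(1, 1), "at least 2")
})
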