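mk_wave <- function(values, times = seq(-100, 500, by = 2)) {
  erp_wave(times, values)
}

test_that("baseline correction zeroes the pre-stimulus interval", {
  t <- seq(-100, 500, by = 2)
  w <- baseline_correct(mk_wave(rep(5, length(t))))
  expect_equal(w$values, rep(0, length(t)), tolerance = 1e-14)

  ramp <- baseline_correct(mk_wave(seq_along(t)))
  expect_equal(mean(ramp$values[t >= -100 & t <= 0]), 0, tolerance = 1e-10)

  centered <- mk_wave(sin(2 * pi * t / 100) - mean(sin(2 * pi * t[t <= 0] / 100)))
  expect_equal(baseline_correct(centered)$values[t > 0],
               centered$values[t > 0], tolerance = 1e-10)
  expect_error(baseline_correct(erp_wave(10:20, 10:20), window = c(-100, 0)),
               "baseline window")
})

test_that("difference waves are exact pointwise subtractions", {
  t <- seq(-100, 500, by = 2)
  a <- mk_wave(rnorm(length(t)))
  b <- mk_wave(rnorm(length(t)))
  cshift <- mk_wave(rnorm(length(t)))
  expect_equal(difference_wave(a, a)$values, rep(0, length(t)))
  # linearity: diff(a+c, b+c) = diff(a, b)
  expect_equal(difference_wave(mk_wave(a$values + cshift$values),
                               mk_wave(b$values + cshift$values))$values,
               difference_wave(a, b)$values, tolerance = 1e-12)
  short <- erp_wave(seq(-100, 498, by = 2), a$values[-1])
  expect_error(difference_wave(a, short), "time axes")
})

test_that("channel-cluster averaging commutes with difference waves", {
  t <- seq(-100, 500, by = 2)
  set.seed(51)
  dev <- list(Fz = mk_wave(rnorm(length(t))), FCz = mk_wave(rnorm(length(t))))
  std <- list(Fz = mk_wave(rnorm(length(t))), FCz = mk_wave(rnorm(length(t))))
  diff_then_avg <- average_channels(list(
    Fz = difference_wave(dev$Fz, std$Fz),
    FCz = difference_wave(dev$FCz, std$FCz)))
  avg_then_diff <- difference_wave(average_channels(dev),
                                   average_channels(std))
  expect_equal(diff_then_avg$values, avg_then_diff$values, tolerance = 1e-12)
})

test_that("peak measures recover a synthetic Gaussian dip in closed form", {
  t <- seq(-100, 500, by = 2)
  dip <- mk_wave(-2 * exp(-(t - 150)^2 / (2 * 40^2)))
  pm <- peak_measures(dip)
  expect_identical(pm$mmn_latency, 150)
  # continuous-time reference: -2 * 0.937... uV over the +/-25 ms window
  expect_equal(pm$mmn_amplitude, gaussian_window_mean(-2, 40),
               tolerance = 5e-4)
  expect_equal(gaussian_window_mean(-2, 40) / -2, 0.937, tolerance = 3e-3)
})

test_that("peak latency is translation-equivariant, amplitude invariant", {
  t <- seq(-100, 500, by = 2)
  f <- function(tt) -1.5 * exp(-(tt - 140)^2 / (2 * 30^2)) +
    0.8 * exp(-(tt - 240)^2 / (2 * 30^2))
  pm0 <- peak_measures(mk_wave(f(t)))
  pm10 <- peak_measures(mk_wave(f(t - 10)))
  expect_identical(pm10$mmn_latency, pm0$mmn_latency + 10)
  expect_identical(pm10$p3a_latency, pm0$p3a_latency + 10)
  expect_equal(pm10$mmn_amplitude, pm0$mmn_amplitude, tolerance = 1e-12)
  expect_equal(pm10$p3a_amplitude, pm0$p3a_amplitude, tolerance = 1e-12)
})

test_that("flat waves resolve ties to the earliest latency", {
  t <- seq(-100, 500, by = 2)
  pm <- peak_measures(mk_wave(rep(0, length(t))))
  expect_identical(pm$mmn_amplitude, 0)
  expect_identical(pm$p3a_amplitude, 0)
  expect_identical(pm$mmn_latency, 70)  # first sample of the window
  expect_identical(pm$p3a_latency, 150)
})

test_that("windows truncated at the epoch edge warn instead of erroring", {
  t <- seq(-100, 360, by = 2) # P3a +/-25 window can exceed 360 ms
  v <- 1 * exp(-(t - 350)^2 / (2 * 20^2))
  expect_warning(pm <- peak_measures(erp_wave(t, v)), "truncated")
  expect_identical(pm$p3a_latency, 350)
})

test_that("pure-noise difference waves bias the MMN amplitude negative", {
  # extremum selection on noise: compare the measurement path against a
  # direct Monte-Carlo of the windowed-minimum statistic on raw draws
  t <- seq(-100, 500, by = 4)
  iw <- which(t >= 70 & t <= 250)
  set.seed(52)
  direct <- replicate(400, {
    v <- rnorm(length(t))
    lat <- t[iw[which.min(v[iw])]]
    mean(v[t >= lat - 25 & t <= lat + 25])
  })
  set.seed(52)
  via_pkg <- replicate(400, peak_measures(erp_wave(t, rnorm(length(t))))$mmn_amplitude)
  expect_equal(mean(via_pkg), mean(direct), tolerance = 1e-10)
  expect_lt(mean(via_pkg) + 3 * sd(via_pkg) / 20, 0) # clearly negative
})

test_that("rejection-rate arithmetic reports one decimal", {
  expect_identical(rejection_rate(13400, 321389), 4.2)
  expect_identical(rejection_rate(0, 100), 0)
  expect_identical(rejection_rate(50, 100), 50)
  expect_error(rejection_rate(5, 0))
})
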