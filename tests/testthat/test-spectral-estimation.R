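test_that("Welch estimate is Parseval-consistent and flat for white noise", {
  n <- 2^18
  fs <- 1000
  x <- withr::with_seed(42, rnorm(n))
  ts <- fes_timeseries(x, sampling_rate = fs)
  ps <- estimate_psd(ts, segment_length = 4096)

  df <- fs / 4096
  expect_equal(sum(ps$density) * df, var(x), tolerance = 0.05)
  # unit-variance white noise: one-sided level 2/fs
  expect_equal(mean(ps$density), 2 / fs, tolerance = 0.05)
  # flat: chord slope of the log-binned spectrum near zero
  lb <- log_bin_spectrum(ps, 12)
  expect_lt(abs(endpoint_slope(lb, 1, 400)), 0.05)
  expect_identical(attr(ps, "n_averages", exact = TRUE), 127L)
})

test_that("a pure sinusoid concentrates at its bin frequency", {
  fs <- 1000
  L <- 1024
  f0 <- 125  # exact bin frequency of a 1024-point segment at 1 kHz
  t <- (0:(8 * L - 1)) / fs
  ts <- fes_timeseries(sin(2 * pi * f0 * t), sampling_rate = fs)
  ps <- estimate_psd(ts, segment_length = L, overlap = 0)
  expect_equal(ps$frequency[which.max(ps$density)], f0)
})

test_that("estimation is deterministic and scale-equivariant, DC is dropped", {
  x <- withr::with_seed(7, rnorm(2^13))
  ts <- fes_timeseries(x, sampling_rate = 500)
  a <- estimate_psd(ts, segment_length = 512)
  b <- estimate_psd(ts, segment_length = 512)
  expect_identical(a, b)
  expect_gt(min(a$frequency), 0)

  scaled <- estimate_psd(fes_timeseries(3 * x, sampling_rate = 500),
                         segment_length = 512)
  expect_equal(scaled$density, 9 * a$density)
})

test_that("estimation rejects undersized and non-finite input", {
  ts <- fes_timeseries(rnorm(100), sampling_rate = 100)
  expect_error(estimate_psd(ts, segment_length = 256),
               class = "fes_sizing_error")
  expect_error(estimate_psd(ts, segment_length = 8),
               class = "fes_sizing_error")
  expect_error(fes_timeseries(c(1, NA, 3), 100), class = "fes_validation_error")
  expect_error(fes_timeseries(rnorm(10), -1), class = "fes_validation_error")
  expect_error(estimate_psd(ts, segment_length = 64, overlap = 1),
               class = "fes_validation_error")
})

test_that("log binning preserves power-law slopes and passes through coarse input", {
  # 1000 linear-grid points over 2 decades
  f <- seq(1, 100, length.out = 1000)
  ps <- fes_spectrum(f, f^-1)
  lb <- log_bin_spectrum(ps, bins_per_decade = 10)
  expect_lte(nrow(lb), 20)
  s_before <- endpoint_slope(ps, 1, 100)
  s_after <- endpoint_slope(lb, min(lb$frequency), max(lb$frequency))
  expect_equal(s_after, s_before, tolerance = 0.01)

  # input coarser than the bin grid: every bin holds at most one point
  coarse <- fes_spectrum(10^seq(0, 2, by = 0.4), 10^-seq(0, 2, by = 0.4))
  lb2 <- log_bin_spectrum(coarse, bins_per_decade = 3)
  expect_equal(lb2$frequency, coarse$frequency)
  expect_equal(lb2$density, coarse$density)

  expect_error(log_bin_spectrum(fes_spectrum(c(1, 1.01), c(1, 1)), 1),
               class = "fes_degenerate_error")
})

test_that("band selection is a closed-interval filter and composes", {
  f <- 10^seq(-1, 2, by = 0.1)
  ps <- fes_spectrum(f, f^-1)
  full <- select_band(ps, min(f), max(f))
  expect_equal(full$frequency, ps$frequency)

  sel <- select_band(ps, 1, 10)
  expect_true(all(sel$frequency >= 1 & sel$frequency <= 10))

  # closed endpoints survive on an exact grid
  exact <- fes_spectrum(c(0.5, 1, 2, 5, 10, 20), rep(1, 6) / c(0.5, 1, 2, 5, 10, 20))
  expect_equal(select_band(exact, 1, 10)$frequency, c(1, 2, 5, 10))

  nested <- select_band(select_band(ps, 0.5, 50), 1, 10)
  expect_equal(nested$frequency, sel$frequency)
  expect_equal(nested$density, sel$density)

  expect_error(select_band(ps, 200, 400), class = "fes_band_error")
  expect_error(select_band(ps, 10, 1), class = "fes_validation_error")
})

test_that("resampling is exact on power laws and refuses extrapolation", {
  ps <- fes_spectrum(c(1, 100), c(1, 0.01))
  mid <- resample_spectrum(ps, c(1, 10, 100))
  expect_equal(mid$density[2], 0.1)

  pl <- power_law_spectrum(1.7, c = 3.2, f_min = 0.5, f_max = 200)
  targets <- c(0.9, 3.7, 55, 180)
  rs <- resample_spectrum(pl, targets)
  expect_equal(rs$density, 3.2 * targets^-1.7, tolerance = 1e-12)

  same <- resample_spectrum(pl, pl$frequency)
  expect_equal(same$density, pl$density, tolerance = 1e-12)

  expect_error(resample_spectrum(ps, c(0.5, 10)),
               class = "fes_extrapolation_error")
})

test_that("spectrum invariants are enforced", {
  expect_error(fes_spectrum(c(1, 2, 3), c(1, -1, 1)),
               class = "fes_validation_error")
  expect_error(fes_spectrum(c(1, 2, 3), c(1, 0, 1)),
               class = "fes_validation_error")
  expect_error(fes_spectrum(c(0, 1, 2), c(1, 1, 1)),
               class = "fes_validation_error")
  expect_error(fes_spectrum(c(1, 3, 2), c(1, 1, 1)),
               class = "fes_validation_error")
  expect_error(fes_spectrum(1, 1), class = "fes_validation_error")
})
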