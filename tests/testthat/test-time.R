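# Pump-probe difference signals, the IRF fit and noise metrics.

test_that("difference signal: zero, antisymmetry, lensing signature", {
  s <- seq(0.1, 2, by = 0.05)
  off <- radial_profile(s, 100 + 10 * s)
  expect_true(all(difference_signal(off, off)$delta_S == 0))
  on <- radial_profile(s, 100 + 10 * s + sin(s))
  d1 <- difference_signal(on, off)
  d2 <- difference_signal(off, on)
  # antisymmetric up to the (slightly different) normalizers
  expect_equal(d1$delta_S * sum(off$intensity),
               -d2$delta_S * sum(on$intensity), tolerance = 1e-12)
  expect_error(difference_signal(on, radial_profile(s + 0.01, off$intensity)),
               "different s grids")
  # synthetic lensing pair: negative at lowest s, positive up to 1 1/A
  scan <- simulate_time_scan(noise_sd = 0, seed = 1)
  peak_row <- which.min(abs(scan$delays - 0))
  shape <- scan$delta_S[[1]][peak_row, ]
  expect_lt(shape[1], 0)
  expect_true(all(shape[scan$s > 0.45 & scan$s <= 1] > 0))
})

test_that("band integration: zero cases, linearity, commutes with averaging", {
  scan <- simulate_time_scan(n_scans = 4, noise_sd = 0.05, seed = 3)
  zero <- scan
  zero$delta_S <- lapply(zero$delta_S, function(m) m * 0)
  expect_true(all(integrate_band(zero) == 0))
  # linearity
  twice <- scan
  twice$delta_S <- lapply(twice$delta_S, function(m) 2 * m)
  expect_equal(integrate_band(twice), 2 * integrate_band(scan), tolerance = 1e-12)
  # average-then-integrate equals integrate-then-average
  per_scan <- sapply(seq_len(4), function(k) integrate_band(scan, scan_index = k))
  expect_equal(integrate_band(scan), rowMeans(per_scan), tolerance = 1e-12)
  expect_error(integrate_band(scan, band = c(5, 6)), "outside")
})

test_that("plasma fit recovers a noiseless trace to 6 significant figures", {
  d <- seq(-1, 1, length.out = 45)
  tr <- plasma_trace_model(d, a = 0.8, b = 0.2, t0 = 0.05, fwhm = 209, c0 = 0.01)
  fit <- fit_plasma_trace(d, tr)
  expect_equal(fit$fwhm, 209, tolerance = 1e-6)
  expect_equal(fit$t0, 0.05, tolerance = 1e-6)
  expect_equal(fit$gaussian_amplitude, 0.8, tolerance = 1e-6)
  expect_equal(fit$step_amplitude, 0.2, tolerance = 1e-6)
  expect_equal(fit$baseline, 0.01, tolerance = 1e-5)
  expect_false(fit$fwhm_at_bound)
  expect_error(fit_plasma_trace(d[1:5], tr[1:5]), "10 delay points")
})

test_that("plasma fit is unbiased on its own model at moderate noise", {
  f <- vapply(1:40, function(seed) {
    scan <- simulate_time_scan(fwhm = 200, noise_sd = 0.02, seed = seed)
    fit_plasma_trace(scan$delays, integrate_band(scan))$fwhm
  }, numeric(1))
  expect_lt(abs(mean(f) / 200 - 1), 0.02)
})

test_that("t0 drift across scans broadens the averaged-trace width", {
  deltas <- vapply(1:8, function(seed) {
    scan <- simulate_time_scan(fwhm = 200, n_scans = 6, drift_fs = 30,
                               noise_sd = 0.01, seed = seed)
    f_avg <- fit_plasma_trace(scan$delays, integrate_band(scan))$fwhm
    f_single <- mean(vapply(1:6, function(k) {
      fit_plasma_trace(scan$delays, integrate_band(scan, scan_index = k))$fwhm
    }, numeric(1)))
    f_avg - f_single
  }, numeric(1))
  expect_true(all(deltas > 0))
})

test_that("geometric smearing: zero at normal incidence, linear in spot size", {
  expect_equal(geometric_smearing(50, 0), 0)
  expect_equal(geometric_smearing(100, 30), 2 * geometric_smearing(50, 30))
  # rms convention at ~50 um, 30 deg is ~35 fs; fwhm convention 2.355x larger
  expect_equal(geometric_smearing(50, 30), 35.4, tolerance = 1e-2)
  expect_equal(geometric_smearing(50, 30, "fwhm"),
               geometric_smearing(50, 30) * 2 * sqrt(2 * log(2)),
               tolerance = 1e-12)
  expect_error(geometric_smearing(50, 90), "90")
})

test_that("noise rms: zero for identical replicates, offset invariant, 1/sqrt(n)", {
  s <- seq(0, 10, by = 0.05)
  # a linear signal passes through the moving average untouched, so
  # identical replicates must give exactly zero noise
  lin <- 0.002 * s - 0.01
  nr0 <- noise_rms(s, rbind(lin, lin, lin))
  expect_true(all(nr0$band_rms < 1e-12))
  expect_true(all(unlist(nr0$vs_integration[, -1]) < 1e-12))
  base <- 0.01 * sin(s)
  set.seed(42)
  curves <- t(replicate(30, base + rnorm(length(s), 0, 0.005)))
  nr <- noise_rms(s, curves)
  shifted <- noise_rms(s, curves + 3)
  expect_equal(nr$band_rms, shifted$band_rms, tolerance = 1e-10)
  # Monte-Carlo 1/sqrt(n): mean squared rms over independent replicate sets,
  # pooled across bands, fit in log-log
  mats <- lapply(1:8, function(seed) {
    set.seed(seed)
    cs <- t(replicate(30, base + rnorm(length(s), 0, 0.005)))
    as.matrix(noise_rms(s, cs)$vs_integration[, c("low", "mid", "high")])^2
  })
  pooled <- sqrt(rowMeans(Reduce(`+`, mats) / length(mats)))
  slope <- unname(coef(stats::lm(log(pooled) ~ log(1:30)))[2])
  expect_equal(slope, -0.5, tolerance = 0.05 / 0.5)
  expect_error(noise_rms(s, curves, window = 1000), "window larger")
})

test_that("band noise ordering reflects jitter and thickness-drift mechanisms", {
  # emulate the instability pattern: pointing jitter boosts the lowest-s
  # band, thickness drift tilts the high-s band, counting noise is flat
  s <- seq(0, 10, by = 0.05)
  set.seed(9)
  curves <- t(replicate(25, {
    jitter_lows <- rnorm(1, 0, 0.004) * exp(-s / 0.5)
    drift_highs <- rnorm(1, 0, 0.003) * pmax(s - 6, 0) / 4
    rnorm(length(s), 0, 0.001) + jitter_lows + drift_highs
  }))
  nr <- noise_rms(s, curves)
  expect_lt(nr$band_rms[["mid"]], nr$band_rms[["low"]])
  expect_lt(nr$band_rms[["mid"]], nr$band_rms[["high"]])
})
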