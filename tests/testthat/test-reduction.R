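# Image reduction, transmission and multiple-scattering metrics.

test_that("azimuthal average of a uniform image is flat and respects masks", {
  img <- detector_image(matrix(7, 64, 64), pixel_pitch = 0.5,
                        beam_center = c(32.5, 32.5))
  prof <- azimuthal_average(img, n_bins = 20)
  expect_true(all(prof$intensity[prof$n_pixels > 0] == 7))
  # masked pixels never contribute
  mask <- matrix(FALSE, 64, 64); mask[1:32, ] <- TRUE
  counts <- matrix(7, 64, 64); counts[mask] <- 1e6
  img2 <- detector_image(counts, 0.5, c(32.5, 32.5), hole_mask = mask)
  prof2 <- azimuthal_average(img2, n_bins = 20)
  expect_true(all(prof2$intensity[prof2$n_pixels > 0] == 7))
  expect_true(all(prof2$n_pixels <= prof$n_pixels))
  # empty bins are NA, not interpolated
  all_masked <- detector_image(counts, 0.5, c(32.5, 32.5),
                               hole_mask = matrix(TRUE, 64, 64))
  prof3 <- azimuthal_average(all_masked, n_bins = 20, s_range = range(prof$s))
  expect_true(all(is.na(prof3$intensity)))
})

test_that("render/reduce round trip recovers the profile within Poisson error", {
  s_ext <- s_grid(0.4, 16, 781)
  prof <- simulate_profile(fx_rdfs_290(), s_ext, poisson = FALSE)
  prof$intensity <- prof$intensity / 30 # mean counts per pixel
  cfg <- sim_config()
  img <- render_detector_image(prof, cfg, seed = 4)
  expect_true(all(img$counts[img$hole_mask] == 0))
  red <- azimuthal_average(img, n_bins = 300, s_range = c(0.4, 10))
  ok <- !is.na(red$intensity) & red$n_pixels > 30 & red$s > 1.05
  pred <- stats::approx(prof$s, prof$intensity, red$s[ok])$y
  chi2 <- mean((red$intensity[ok] - pred)^2 / (pred / red$n_pixels[ok]))
  expect_gt(chi2, 0.8)
  expect_lt(chi2, 1.2)
})

test_that("azimuthal average is invariant under rotation about the center", {
  s_ext <- s_grid(0.4, 16, 781)
  prof <- simulate_profile(fx_rdfs_290(), s_ext, poisson = FALSE)
  prof$intensity <- prof$intensity / 30
  img <- render_detector_image(prof, sim_config(), seed = 11)
  rot <- img
  rot$counts <- t(img$counts)[, nrow(img$counts):1]
  rot$hole_mask <- t(img$hole_mask)[, nrow(img$hole_mask):1]
  p1 <- azimuthal_average(img, n_bins = 200, s_range = c(0.4, 10))
  p2 <- azimuthal_average(rot, n_bins = 200, s_range = c(0.4, 10))
  expect_equal(p1$intensity, p2$intensity, tolerance = 1e-12)
})

test_that("beam-center refinement pulls a misassigned center back", {
  s_ext <- s_grid(0.4, 16, 781)
  prof <- simulate_profile(fx_rdfs_290(), s_ext, poisson = FALSE)
  prof$intensity <- prof$intensity / 50
  cfg <- sim_config(shape = c(128, 128), pixel_pitch = 0.256)
  img <- render_detector_image(prof, cfg, seed = 2)
  img$beam_center <- img$beam_center + c(2, -2)
  ref <- refine_beam_center(img, half_width = 3)
  expect_lt(max(abs(ref - cfg$beam_center)), 1.5)
})

test_that("transmission is a guarded ratio", {
  expect_equal(transmission(920, 1000), 0.92)
  expect_equal(transmission(5, 5), 1)
  expect_warning(transmission(1100, 1000), "exceed")
  expect_error(transmission(10, 0), "positive")
  # Beer-Lambert composition: T = 0.92 with 1 um mfp -> ~83 nm
  expect_equal(thickness_from_transmission(transmission(920, 1000), 1), 83.4,
               tolerance = 1e-2)
})

test_that("multiple-scattering ratio: band widths, pedestal direction", {
  s <- seq(0.4, 10, by = 0.02)
  flat <- radial_profile(s, rep(3, length(s)))
  expect_equal(multiple_scattering_ratio(flat), (9.0 - 6.8) / (3.1 - 1.6),
               tolerance = 1e-12)
  zero_high <- radial_profile(s, ifelse(s > 6, 0, 1))
  expect_equal(multiple_scattering_ratio(zero_high), 0)
  # liquid-like profile: ratio < 1.4667; adding a flat pedestal raises it
  prof <- simulate_profile(fx_rdfs_290(), fx_s(), poisson = FALSE)
  r0 <- multiple_scattering_ratio(prof)
  expect_lt(r0, 1.4667)
  pedestals <- c(0.05, 0.2, 1, 5, 200) * mean(prof$intensity)
  ratios <- vapply(pedestals, function(p) {
    multiple_scattering_ratio(radial_profile(prof$s, prof$intensity + p))
  }, numeric(1))
  expect_true(all(diff(c(r0, ratios)) > 0))
  # in the limit of a dominant pedestal the ratio approaches the width ratio
  expect_equal(ratios[length(ratios)], 1.4667, tolerance = 0.02)
  expect_error(multiple_scattering_ratio(radial_profile(s[s < 5], rep(1, sum(s < 5)))),
               "not covered")
})

test_that("scan map computes both metrics and flags missing references", {
  prof_thin <- simulate_profile(fx_rdfs_290(), fx_s(), thickness = 120,
                                poisson = FALSE)
  prof_thick <- simulate_profile(fx_rdfs_290(), fx_s(), thickness = 600,
                                 poisson = FALSE)
  pts <- list(
    list(x = 0, y = 0, beam_counts = 800, profile = prof_thick),
    list(x = 0, y = 50, beam_counts = 920, profile = prof_thin),
    list(x = 0, y = 100, beam_counts = 850, profile = prof_thick)
  )
  m <- scan_map(pts, beam_counts_no_jet = 1000)
  expect_equal(nrow(m), 3)
  expect_equal(m$transmission, c(0.80, 0.92, 0.85))
  # ms ratio minimum at the thin midpoint
  expect_equal(which.min(m$ms_ratio), 2L)
  expect_equal(attr(m, "position_uncertainty_um"), 50)
  expect_error(scan_map(pts), "reference")
})

test_that("ms pedestal grows with thickness beyond 20% of the mean free path", {
  th <- c(150, 250, 400, 600, 900)
  ratios <- vapply(th, function(d) {
    multiple_scattering_ratio(simulate_profile(fx_rdfs_290(), fx_s(),
                                               thickness = d, poisson = FALSE))
  }, numeric(1))
  expect_equal(ratios[1],
               multiple_scattering_ratio(simulate_profile(fx_rdfs_290(), fx_s(),
                                                          thickness = 100,
                                                          poisson = FALSE)),
               tolerance = 1e-12) # below the bound: no pedestal
  expect_true(all(diff(ratios[-1]) > 0))
})
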