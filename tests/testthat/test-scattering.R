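# Kinematics, form factors and the two IAM intensity routes.

test_that("relativistic de Broglie wavelength matches closed form and limits", {
  # independent evaluation: pc = sqrt((KE + mec2)^2 - mec2^2), lambda = hc/pc
  expect_equal(electron_wavelength(3.7), 0.2966, tolerance = 1e-3)
  expect_equal(signif(electron_wavelength(3.7), 2), 0.30)
  # doubling pc halves the wavelength
  pc <- function(ke) sqrt((ke + 0.51099895)^2 - 0.51099895^2)
  ke2 <- uniroot(function(k) pc(k) - 2 * pc(3.7), c(3.7, 50), tol = 1e-12)$root
  expect_equal(electron_wavelength(ke2), electron_wavelength(3.7) / 2,
               tolerance = 1e-9)
  # classical limit at 100 eV: h / sqrt(2 m KE)
  ke_ev <- 100
  lambda_classical_pm <- 1.23984198 / sqrt(2 * 0.51099895 * ke_ev * 1e-6)
  expect_equal(electron_wavelength(ke_ev * 1e-6), lambda_classical_pm,
               tolerance = 1e-3)
  expect_error(electron_wavelength(0), "positive")
})

test_that("momentum transfer mapping and its inverse are consistent", {
  lam <- electron_wavelength(3.7)
  expect_identical(s_from_angle(0, lam), 0)
  # angle giving s = 10 at lambda = 0.003 A (0.3 pm) is ~4.77 mrad
  th <- angle_from_s(10, 0.3)
  expect_equal(th, 2 * asin(10 * 0.003 / (4 * pi)), tolerance = 1e-12)
  expect_equal(th * 1e3, 4.77, tolerance = 1e-2)
  expect_equal(s_from_angle(th, 0.3), 10, tolerance = 1e-12)
  # real-space resolution at s_max = 10
  expect_equal(2 * pi / 10, 0.63, tolerance = 0.01)
  expect_error(s_from_angle(-0.1, lam), "theta")
})

test_that("form factors: Z ordering, relativistic scaling, table lookup", {
  s <- fx_s(); ff <- fx_ff()
  expect_true(all(ff$O$amplitude > ff$H$amplitude))
  expect_equal(lorentz_gamma(3.7), 1 + 3.7 / 0.51099895, tolerance = 1e-12)
  expect_equal(round(lorentz_gamma(3.7), 2), 8.24)
  # one grid point against the raw parameterization outside the pipeline
  a <- c(0.0974, 0.2921, 0.6910, 0.6990, 0.2039)
  b <- c(0.2067, 1.3815, 4.6943, 12.7105, 32.4726)
  q <- as.numeric(s)[100] / (4 * pi)
  expect_equal(ff$O$amplitude[100],
               lorentz_gamma(3.7) * sum(a * exp(-b * q^2)), tolerance = 1e-12)
  # amplitudes decrease with s for H and O
  expect_true(all(diff(ff$H$amplitude) <= 0))
  expect_true(all(diff(ff$O$amplitude) <= 0))
  expect_error(form_factor("Xx", s), "parameterization")
})

test_that("atomic intensity is the incoherent sum over the composition", {
  s <- fx_s(); ff <- fx_ff()
  expect_equal(atomic_intensity(c(O = 1), ff, s), ff$O$amplitude^2)
  i_w <- atomic_intensity(c(O = 1, H = 2), ff, s)
  expect_equal(i_w, ff$O$amplitude^2 + 2 * ff$H$amplitude^2)
  expect_equal(atomic_intensity(c(O = 7, H = 14), ff, s), 7 * i_w)
  expect_true(all(i_w > 0))
  expect_true(all(diff(i_w) <= 0)) # monotone for pure H/O compositions
  expect_error(atomic_intensity(c(O = 1, Zz = 1), ff, s), "form factor")
})

test_that("Debye sum matches diatomic closed form and a brute-force oracle", {
  s <- fx_s(); ff <- fx_ff()
  r0 <- 1.2
  geom <- molecular_geometry(data.frame(element = c("O", "O"),
                                        x = c(0, r0), y = 0, z = 0))
  expect_equal(molecular_intensity_debye(geom, ff, s),
               2 * ff$O$amplitude^2 * sin(as.numeric(s) * r0) / (as.numeric(s) * r0),
               tolerance = 1e-12)
  # 3-atom water equals an independent double loop over ordered pairs
  geom_w <- water_geometry()
  at <- geom_w$atoms
  acc <- numeric(length(s))
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    rij <- sqrt(sum((at[i, 2:4] - at[j, 2:4])^2))
    x <- as.numeric(s) * rij
    acc <- acc + ff[[at$element[i]]]$amplitude * ff[[at$element[j]]]$amplitude *
      ifelse(x == 0, 1, sin(x) / x)
  }
  expect_equal(molecular_intensity_debye(geom_w, ff, s), acc, tolerance = 1e-10)
  # s -> 0 limit equals sum over pairs of |f_i||f_j|
  s0 <- structure(c(0, 1e-9, 2e-9), class = c("s_grid", "numeric"))
  ff0 <- form_factor_set(c("O", "H"), s0)
  i0 <- molecular_intensity_debye(geom_w, ff0, s0)
  expect_equal(i0[1], 2 * 2 * ff0$O$amplitude[1] * ff0$H$amplitude[1] +
                 2 * ff0$H$amplitude[1]^2, tolerance = 1e-9)
  expect_error(molecular_intensity_debye(
    molecular_geometry(data.frame(element = c("O", "H"), x = 0, y = 0, z = 0)),
    ff, s), "coincident")
})

test_that("RDF forward model: zero g, count scaling, Debye equivalence", {
  s <- fx_s(); ff <- fx_ff()
  r <- seq(0, 25, by = 0.01)
  zero <- rdf_set(r, list(`O-O` = rep(0, length(r))), c(O = 10), 1e3,
                  baseline = 0, validate = FALSE)
  expect_equal(molecular_intensity_rdf(zero, ff, s), rep(0, length(s)))
  # prefactor linearity in N_m (N_l - delta)
  g <- 1 / (4 * pi * pmax(r, 1e-6)^2 * (5 / 1e3)) * stats::dnorm(r, 3, 0.1)
  one <- rdf_set(r, list(`O-H` = g), c(O = 2, H = 5), 1e3,
                 baseline = 0, validate = FALSE)
  two <- rdf_set(r, list(`O-H` = g), c(O = 6, H = 5), 1e3,
                 baseline = 0, validate = FALSE)
  expect_equal(molecular_intensity_rdf(two, ff, s),
               3 * molecular_intensity_rdf(one, ff, s), tolerance = 1e-12)
  # delta-like shell reproduces the Debye sum on the matching geometry
  r0 <- 2.9
  i_rdf <- molecular_intensity_rdf(make_delta_rdf(r0), ff, s)
  geom <- molecular_geometry(data.frame(element = c("O", "H"),
                                        x = c(0, r0), y = 0, z = 0))
  i_deb <- molecular_intensity_debye(geom, ff, s)
  expect_lt(max(abs(i_rdf - i_deb)) / max(abs(i_deb)), 0.01)
})

test_that("RDF quadrature converges under r-grid refinement", {
  s <- fx_s(); ff <- fx_ff()
  shell <- function(r, rho) 1 / (4 * pi * pmax(r, 1e-6)^2 * rho) *
    stats::dnorm(r, 2.8, 0.15)
  mk <- function(step) {
    r <- seq(0, 25, by = step)
    rdf_set(r, list(`O-H` = shell(r, 1 / 1e3)), c(O = 1, H = 1), 1e3,
            baseline = 0, validate = FALSE)
  }
  i1 <- molecular_intensity_rdf(mk(0.01), ff, s)
  i2 <- molecular_intensity_rdf(mk(0.005), ff, s)
  expect_lt(max(abs(i1 - i2) / pmax(abs(i2), max(abs(i2)) * 1e-3)), 1e-3)
})

test_that("rdf_set enforces its invariants", {
  r <- seq(0, 20, by = 0.01)
  expect_error(rdf_set(r, list(`O-O` = rep(-1, length(r))), c(O = 1), 1, 0),
               "negative")
  expect_error(rdf_set(r, list(`O-O` = rep(0.5, length(r))), c(O = 1), 1),
               "baseline")
  expect_silent(rdf_set(r, list(`O-O` = rep(1, length(r))), c(O = 1), 1))
  expect_error(rdf_set(rev(r), list(`O-O` = rep(1, length(r))), c(O = 1), 1),
               "increasing")
})
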