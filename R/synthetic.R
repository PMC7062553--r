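# Seeded synthetic-data generator: parametric water RDFs, forward-simulated
# radial profiles, detector images, pump-probe time scans and thin-film
# fringe observations. Every generator is a pure function of
# (parameters, seed), and each artifact carries its ground truth.

#' Load the parametric water RDF model
#'
#' Reads the shipped (or a user-supplied) Gaussian-shell description of the
#' pairwise radial distribution functions of liquid water. Each pair RDF is
#' a uniform baseline switched on by an erf excluded-volume core plus
#' Gaussian shells parameterized by (center, width, pair weight), with linear
#' temperature coefficients on center and width. The shipped model is frozen:
#' at 290 K its electron-weighted pdf(r) through the full forward chain shows
#' the liquid-water features at 1.0, 1.8, 2.9, 4.4 and 6.9 Angstrom.
#'
#' @param path YAML model file; default the packaged model.
#' @return a `water_rdf_model` list.
#' @export
water_rdf_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "water_rdf_model.yaml", package = "lued")
  }
  if (!file.exists(path)) .stop_invalid("RDF model file not found: ", path)
  model <- yaml::read_yaml(path)
  structure(model, class = "water_rdf_model")
}

# g(r) of one pair at temperature t_k
.pair_g <- function(pair, r, dT, rho_partner) {
  onset <- pair$core_onset + (pair$donset_dT %||% 0) * dT
  g <- 0.5 * (1 + .erf((r - onset) / pair$core_width))
  for (sh in pair$shells) {
    mu <- sh$mu + sh$dmu_dT * dT
    sigma <- sh$sigma + sh$dsigma_dT * dT
    w <- sh$weight * (1 + (sh$dweight_rel_dT %||% 0) * dT)
    # shell of `w` partner atoms per central atom
    amp <- w / (4 * pi * pmax(r, 1e-6)^2 * rho_partner)
    g <- g + amp * stats::dnorm(r, mu, sigma)
  }
  pmax(g, 0)
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Generate pairwise RDFs for water at a temperature
#'
#' Deterministic (no randomness): evaluates the Gaussian-shell model on a
#' uniform r grid and packages it as an [rdf_set()].
#'
#' @param model a [water_rdf_model()].
#' @param temperature Kelvin, within the model's valid range (250-400 K).
#' @return an `rdf_set` with O-O, O-H and H-H RDFs, counts and volume.
#' @export
generate_rdfs <- function(model = water_rdf_model(), temperature = 290) {
  stopifnot(inherits(model, "water_rdf_model"))
  vr <- model$valid_temperature
  if (temperature < vr[1] || temperature > vr[2]) {
    .stop_invalid("temperature ", temperature, " K outside the model's valid range [",
                  vr[1], ", ", vr[2], "] K")
  }
  dT <- temperature - model$reference_temperature
  r <- seq(0, model$r_max, by = model$r_step)
  counts <- c(O = model$n_molecules, H = 2 * model$n_molecules)
  g <- list()
  for (key in names(model$pairs)) {
    partner <- .split_pair(key)[2]
    rho <- counts[[partner]] / model$volume
    g[[key]] <- .pair_g(model$pairs[[key]], r, dT, rho)
  }
  out <- rdf_set(r, g, counts, model$volume)
  attr(out, "temperature") <- temperature
  out
}

#' Forward-simulate an azimuthally averaged scattering profile
#'
#' Expectation model: `scale * (I_at + I_mol) + A s^n + ms_pedestal`, sampled
#' with Poisson counting noise. The multiple-scattering pedestal is flat in s
#' (multiply scattered electrons land at all momentum transfers) and grows
#' once the sheet is thicker than 20\% of the electron mean free path.
#'
#' @param rdfs an [rdf_set()] (e.g. from [generate_rdfs()]).
#' @param s momentum-transfer grid; default `s_grid()` (0.4-10, 481 points).
#' @param thickness sheet thickness in nm.
#' @param flux total expected counts over the profile.
#' @param background_A,background_n power-law background parameters (as a
#'   fraction of the IAM signal scale; the default gives a smooth backdrop
#'   comparable to the coherent signal at low s).
#' @param mean_free_path electron mean free path in nm (1000 nm for 3.7 MeV
#'   electrons in water).
#' @param ms_coeff pedestal strength per unit of thickness excess over the
#'   20\% bound, as a fraction of the mean IAM intensity.
#' @param kinetic_energy beam kinetic energy, MeV.
#' @param poisson sample Poisson noise; `FALSE` returns the expectation.
#' @param seed integer seed used for the Poisson draw.
#' @return a `radial_profile` (see [radial_profile()]) with attribute
#'   `ground_truth` recording all generator parameters.
#' @export
simulate_profile <- function(rdfs, s = s_grid(), thickness = 120,
                             flux = 1e6, background_A = 0.25,
                             background_n = -1.5,
                             mean_free_path = 1000, ms_coeff = 1.5,
                             kinetic_energy = 3.7,
                             poisson = TRUE, seed = 1) {
  if (flux <= 0) .stop_invalid("flux must be positive")
  elements <- unique(unlist(lapply(names(rdfs$g), .split_pair)))
  ff <- form_factor_set(elements, s, kinetic_energy)
  i_at <- atomic_intensity_rdf(rdfs, ff, s)
  i_mol <- molecular_intensity_rdf(rdfs, ff, s)
  iam <- i_at + i_mol
  scale_iam <- mean(i_at)
  bkg <- background_A * scale_iam * as.numeric(s)^background_n
  excess <- max(0, thickness / mean_free_path - 0.2)
  pedestal <- ms_coeff * excess * scale_iam
  # a total intensity cannot be negative; clamp where the parametric RDF
  # model overshoots (deep interference minima at extreme temperatures)
  expectation <- pmax(iam + bkg + pedestal, 0)
  expectation <- expectation / sum(expectation) * flux
  counts <- if (poisson) {
    set.seed(seed)
    stats::rpois(length(expectation), expectation)
  } else {
    expectation
  }
  prof <- radial_profile(as.numeric(s), counts, n_pixels = rep(1L, length(s)))
  attr(prof, "ground_truth") <- list(
    temperature = attr(rdfs, "temperature"), thickness = thickness,
    flux = flux, background_A = background_A, background_n = background_n,
    mean_free_path = mean_free_path, ms_coeff = ms_coeff,
    kinetic_energy = kinetic_energy, poisson = poisson, seed = seed
  )
  prof
}

#' Render an isotropic detector image from a radial profile
#'
#' Inverse of [azimuthal_average()]: each pixel's momentum transfer is
#' computed from the detector geometry and its expected count interpolated
#' from the profile (profile intensities are mean counts per pixel), then
#' Poisson-sampled. Pixels under the central beam hole are masked and carry
#' zero counts.
#'
#' @param profile a `radial_profile` of mean counts per pixel vs s.
#' @param config a [sim_config()] describing the detector geometry.
#' @param seed integer seed.
#' @param poisson sample Poisson noise per pixel.
#' @param jitter_px if nonzero, the realized beam center is offset by a
#'   random 2D Gaussian displacement of this many pixels rms (pointing
#'   jitter); the nominal config center is still reported in the image.
#' @return a `detector_image` (see [detector_image()]).
#' @export
render_detector_image <- function(profile, config = sim_config(), seed = 1,
                                  poisson = TRUE, jitter_px = 0) {
  set.seed(seed)
  shape <- config$shape
  center <- config$beam_center
  if (jitter_px > 0) center <- center + stats::rnorm(2, 0, jitter_px)
  lambda_pm <- electron_wavelength(config$kinetic_energy)
  xi <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  yi <- matrix(seq_len(shape[1]), shape[1], shape[2])
  r_mm <- sqrt((xi - center[1])^2 + (yi - center[2])^2) * config$pixel_pitch
  theta <- atan(r_mm / (config$camera_length * 1000))
  s_px <- s_from_angle(theta, lambda_pm)
  rng <- range(profile$s)
  if (max(s_px[r_mm > config$hole_diameter / 2]) > rng[2] + 1e-9) {
    .stop_invalid("profile s range too small for this detector geometry")
  }
  expect <- matrix(stats::approx(profile$s, profile$intensity, xout = s_px,
                                 rule = 2)$y, shape[1], shape[2])
  hole <- r_mm <= config$hole_diameter / 2
  expect[hole] <- 0
  counts <- if (poisson) {
    matrix(stats::rpois(length(expect), expect), shape[1], shape[2])
  } else {
    expect
  }
  counts[hole] <- 0
  detector_image(counts, pixel_pitch = config$pixel_pitch,
                 beam_center = config$beam_center, hole_mask = hole,
                 camera_length = config$camera_length, wavelength = lambda_pm)
}

#' Simulate a pump-probe plasma-lensing time scan
#'
#' The difference signal is separable, `dS(t, s) = trace(t) * shape(s)`:
#' the time trace is the plasma-lensing model of [plasma_trace_model()]
#' (normalized Gaussian plus its own integral as the post-t0 step) and the
#' s shape reproduces the lensing signature of an elongating beam - negative
#' at the lowest s, positive up to about 1 1/Angstrom, negligible beyond.
#' Time zero drifts linearly across scans.
#'
#' @param delays delay grid in ps (default 45 points over +-1 ps).
#' @param s s grid for the difference signal.
#' @param fwhm instrument-response FWHM in fs.
#' @param t0 nominal time zero in ps.
#' @param gaussian_amplitude,step_amplitude,baseline trace model parameters
#'   (amplitudes in normalized dS units; the Gaussian amplitude is the peak
#'   height of the lensing feature).
#' @param n_scans number of repeated scans.
#' @param drift_fs t0 drift per scan in fs.
#' @param noise_sd additive white noise on dS(t, s), in units of the peak
#'   trace amplitude.
#' @param seed integer seed.
#' @return a `time_scan` list: `delays` (ps), `s`, `delta_S` (list of
#'   delay x s matrices, one per scan), `ground_truth`.
#' @export
simulate_time_scan <- function(delays = seq(-1, 1, length.out = 45),
                               s = seq(0.1, 2, by = 0.05),
                               fwhm = 209, t0 = 0,
                               gaussian_amplitude = 1, step_amplitude = 0.25,
                               baseline = 0, n_scans = 1, drift_fs = 0,
                               noise_sd = 0.05, seed = 1) {
  if (fwhm <= 0) .stop_invalid("fwhm must be positive")
  if (length(delays) < 1) .stop_invalid("empty delay grid")
  set.seed(seed)
  shape <- .lensing_shape(s)
  scans <- vector("list", n_scans)
  for (k in seq_len(n_scans)) {
    t0_k <- t0 + (k - 1) * drift_fs * 1e-3 # fs -> ps
    tr <- plasma_trace_model(delays, gaussian_amplitude, step_amplitude,
                             t0_k, fwhm, baseline)
    m <- outer(tr, shape)
    if (noise_sd > 0) {
      m <- m + stats::rnorm(length(m), 0, noise_sd * max(abs(tr)) )
    }
    scans[[k]] <- m
  }
  structure(
    list(delays = delays, s = s, delta_S = scans,
         ground_truth = list(fwhm = fwhm, t0 = t0,
                             gaussian_amplitude = gaussian_amplitude,
                             step_amplitude = step_amplitude,
                             baseline = baseline, n_scans = n_scans,
                             drift_fs = drift_fs, noise_sd = noise_sd,
                             seed = seed)),
    class = "time_scan"
  )
}

# s signature of plasma lensing: negative at lowest s, positive up to ~1 1/A
.lensing_shape <- function(s) {
  sh <- (s - 0.4) * exp(-(s / 0.7)^2)
  sh / max(abs(sh))
}

#' Simulate thin-film interference fringe observations
#'
#' Emits the fringe orders m at the distances from the nozzle where the
#' constructive-interference condition holds for the given thickness profile.
#' No fringes are produced below the m = 1 thickness (the sensitivity floor).
#'
#' @param distance,thickness thickness profile: distance from nozzle (um) and
#'   thickness (nm); must be monotonic in thickness over the fringe region.
#' @param wavelength illumination wavelength, nm.
#' @param incidence_deg illumination angle from the film normal, degrees.
#' @param n_film refractive index of the film.
#' @return data frame with columns `m`, `distance_um`, `thickness_nm`.
#' @export
simulate_fringes <- function(distance, thickness, wavelength = 505,
                             incidence_deg = 30, n_film = 1.336) {
  stopifnot(length(distance) == length(thickness))
  dmono <- diff(thickness)
  if (!(all(dmono <= 0) || all(dmono >= 0))) {
    .stop_invalid("thickness profile must be monotonic over the fringe region (ambiguous fringe-order assignment)")
  }
  d1 <- thickness_from_fringe(1, wavelength, incidence_deg, n_film)
  d_max <- max(thickness)
  if (d_max < d1) {
    return(data.frame(m = integer(0), distance_um = numeric(0),
                      thickness_nm = numeric(0)))
  }
  m_max <- floor(d_max / (2 * d1) + 0.5) # largest m with (m - 1/2) lambda' <= d_max
  out <- data.frame(m = integer(0), distance_um = numeric(0),
                    thickness_nm = numeric(0))
  for (m in seq_len(m_max)) {
    d_m <- thickness_from_fringe(m, wavelength, incidence_deg, n_film)
    if (d_m < min(thickness) || d_m > d_max) next
    ord <- order(thickness)
    x_m <- stats::approx(thickness[ord], distance[ord], xout = d_m)$y
    out <- rbind(out, data.frame(m = m, distance_um = x_m, thickness_nm = d_m))
  }
  out
}

#' Detector/simulation geometry configuration
#'
#' @param shape image dimensions (rows, cols) in pixels.
#' @param pixel_pitch pixel size, mm.
#' @param camera_length sample-detector distance, m.
#' @param hole_diameter central beam-hole diameter, mm.
#' @param kinetic_energy beam kinetic energy, MeV.
#' @param beam_center beam center (x, y) in pixels; defaults to the image
#'   center.
#' @return a `sim_config` list.
#' @export
sim_config <- function(shape = c(512, 512), pixel_pitch = 0.064,
                       camera_length = 3.2, hole_diameter = 3,
                       kinetic_energy = 3.7, beam_center = NULL) {
  if (is.null(beam_center)) beam_center <- (shape[c(2, 1)] + 1) / 2
  structure(list(shape = shape, pixel_pitch = pixel_pitch,
                 camera_length = camera_length, hole_diameter = hole_diameter,
                 kinetic_energy = kinetic_energy, beam_center = beam_center),
            class = "sim_config")
}
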