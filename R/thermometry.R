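# Jet physical diagnostics (thin-film interference thickness, Beer-Lambert
# thickness, jet velocity, cooling rate) and diffraction thermometry of
# liquid water via the first-diffraction-peak calibration.

#' Sheet thickness from a thin-film interference fringe
#'
#' Constructive-interference condition `2 n d cos(theta_t) = (m - 1/2) lambda`
#' with `theta_t` the interior (refracted) angle obtained from the vacuum
#' incidence angle by Snell's law, `sin(theta_t) = sin(theta_inc) / n`.
#'
#' @param m fringe order (positive integer).
#' @param wavelength illumination wavelength in nm (505 nm default).
#' @param incidence_deg angle of incidence from the film normal, in vacuum,
#'   degrees (30 default).
#' @param n_film refractive index of the film (1.336 for water at 505 nm).
#' @return film thickness in nm.
#' @export
thickness_from_fringe <- function(m, wavelength = 505, incidence_deg = 30,
                                  n_film = 1.336) {
  if (any(m < 1) || any(m != round(m))) .stop_invalid("fringe order m must be a positive integer")
  if (any(incidence_deg < 0) || any(incidence_deg >= 90)) {
    .stop_invalid("incidence angle must lie in [0, 90) degrees")
  }
  if (any(n_film <= 1)) .stop_invalid("n_film must exceed 1")
  if (any(wavelength <= 0)) .stop_invalid("wavelength must be positive")
  sin_t <- sin(incidence_deg * pi / 180) / n_film
  cos_t <- sqrt(1 - sin_t^2)
  (m - 0.5) * wavelength / (2 * n_film * cos_t)
}

#' Sensitivity floor of the interference thickness measurement
#'
#' The thinnest film producing a fringe: [thickness_from_fringe()] at m = 1
#' (102 nm under the default 505 nm / 30 degrees / n = 1.336 conditions).
#'
#' @inheritParams thickness_from_fringe
#' @return minimum detectable thickness, nm.
#' @export
min_detectable_thickness <- function(wavelength = 505, incidence_deg = 30,
                                     n_film = 1.336) {
  thickness_from_fringe(1, wavelength, incidence_deg, n_film)
}

#' Sheet thickness from electron transmission
#'
#' Beer-Lambert inversion `d = -ln(T) * mean_free_path`.
#'
#' @param transmission transmitted fraction, in (0, 1].
#' @param mean_free_path electron mean free path in um (about 1 um in water
#'   for 3.7 MeV electrons).
#' @return thickness in nm.
#' @export
thickness_from_transmission <- function(transmission, mean_free_path = 1) {
  if (any(transmission <= 0) || any(transmission > 1)) {
    .stop_invalid("transmission must lie in (0, 1]")
  }
  -log(transmission) * mean_free_path * 1000
}

#' Jet speed from flow rate and jet diameter
#'
#' Volumetric flow divided by the cross-sectional area of the cylindrical
#' jet.
#'
#' @param flow_rate liquid flow rate, ml/min.
#' @param jet_diameter jet diameter, um.
#' @return speed in m/s.
#' @export
jet_velocity <- function(flow_rate, jet_diameter = 20) {
  if (any(flow_rate <= 0) || any(jet_diameter <= 0)) {
    .stop_invalid("flow rate and jet diameter must be positive")
  }
  q_m3s <- flow_rate * 1e-6 / 60            # ml/min -> m^3/s
  area <- pi * (jet_diameter * 1e-6 / 2)^2  # m^2
  q_m3s / area
}

#' Evaporative cooling rate along the jet
#'
#' Finite-difference temperature gradient along the flow direction times the
#' jet speed; exact for a linear profile.
#'
#' @param distance positions along the jet, um (increasing).
#' @param temperature temperatures at those positions, K.
#' @param velocity jet speed, m/s.
#' @return list with `segment_rate` (signed K/s per segment, dT/dx * v) and
#'   `mean_rate` (overall mean, from the end-to-end gradient).
#' @export
cooling_rate <- function(distance, temperature, velocity) {
  if (length(distance) < 2 || length(temperature) != length(distance)) {
    .stop_invalid("need >= 2 profile points with matching temperatures")
  }
  dx_m <- diff(distance) * 1e-6
  seg <- diff(temperature) / dx_m * velocity
  n <- length(distance)
  overall <- (temperature[n] - temperature[1]) /
    ((distance[n] - distance[1]) * 1e-6) * velocity
  list(segment_rate = seg, mean_rate = overall)
}

#' Position of the first diffraction peak
#'
#' Discrete maximum of the (lightly smoothed) profile within the search
#' window, refined by a local parabola fitted to the raw profile over
#' `refine_bins` bins on either side. The liquid-water first peak is broad
#' (about 0.5 1/Angstrom), so the refinement window spans a sizeable part
#' of the peak top; a narrower window makes the vertex estimate unstable
#' against counting noise. Invariant to rescaling of the profile.
#'
#' @param profile a [radial_profile()] (or list with `s`, `intensity`)
#'   covering the window.
#' @param window search window in 1/Angstrom (default 1.5-4, the liquid
#'   water first-peak region).
#' @param refine_bins half-width of the parabolic refinement, in bins
#'   (default 12, i.e. +-0.24 1/Angstrom on the default 0.02 grid).
#' @param smooth_bins moving-average window (odd) applied only for locating
#'   the discrete maximum; 1 disables smoothing.
#' @return refined peak position s1, 1/Angstrom.
#' @export
first_peak_position <- function(profile, window = c(1.5, 4),
                                refine_bins = 12, smooth_bins = 5) {
  s <- profile$s; y <- profile$intensity
  sel <- which(s >= window[1] & s <= window[2])
  if (length(sel) < 7) .stop_invalid("profile does not cover the search window")
  yy <- y[sel]
  if (anyNA(yy)) .stop_invalid("empty bins inside the search window")
  ys <- if (smooth_bins > 1) {
    as.numeric(stats::filter(yy, rep(1 / smooth_bins, smooth_bins), sides = 2))
  } else yy
  # the peak must be an interior local maximum of the smoothed curve: a
  # decaying background ramp can exceed the liquid peak at the window edge,
  # but it is not itself a peak; bins whose smoothed value is undefined
  # (window edges) are not candidates
  n <- length(ys)
  is_locmax <- c(FALSE, ys[2:(n - 1)] > ys[1:(n - 2)] &
                   ys[2:(n - 1)] >= ys[3:n], FALSE)
  is_locmax[is.na(is_locmax)] <- FALSE
  if (!any(is_locmax)) .stop_invalid("no interior maximum in the search window")
  cand <- which(is_locmax)
  idx <- cand[which.max(ys[cand])]
  ds <- s[sel][2] - s[sel][1]
  vertex <- s[sel][idx]
  # recentre the parabola on its own vertex once: on a broad peak the
  # discrete maximum can sit well off-centre, which biases a single fit
  for (pass in 1:2) {
    ctr <- which.min(abs(s[sel] - vertex))
    lo <- max(1, ctr - refine_bins); hi <- min(length(sel), ctr + refine_bins)
    xs <- s[sel][lo:hi]; yw <- yy[lo:hi]
    cf <- unname(stats::coef(stats::lm(yw ~ xs + I(xs^2))))
    if (!is.finite(cf[3]) || cf[3] >= 0) return(s[sel][idx])
    v <- -cf[2] / (2 * cf[3])
    # fall back to the discrete maximum if the vertex escapes the window
    if (v < xs[1] - ds || v > xs[length(xs)] + ds) return(s[sel][idx])
    vertex <- v
  }
  vertex
}

#' Build the first-peak temperature calibration
#'
#' Fits temperature as a cubic polynomial of the first-peak position s1 over
#' a set of simulated profiles at known temperatures, and verifies that the
#' fitted mapping is strictly monotonic over the calibrated range.
#'
#' @param temperatures simulated temperatures, K (>= 6, spanning the range).
#' @param profiles list of profiles (one per temperature).
#' @param window first-peak search window passed to [first_peak_position()].
#' @return a `temperature_calibration` with cubic coefficients (T as a
#'   function of s1), the calibrated s1 and T ranges, and the training pairs.
#' @export
build_temperature_calibration <- function(temperatures, profiles,
                                          window = c(1.5, 4)) {
  if (length(temperatures) < 6) {
    .stop_invalid("need >= 6 temperatures spanning the range")
  }
  if (length(profiles) != length(temperatures)) {
    .stop_invalid("one profile per temperature required")
  }
  s1 <- vapply(profiles, first_peak_position, numeric(1), window = window)
  ord <- order(temperatures)
  if (is.unsorted(s1[ord], strictly = TRUE) &&
      is.unsorted(rev(s1[ord]), strictly = TRUE)) {
    .stop_invalid("first-peak positions are not monotonic in temperature; calibration failed")
  }
  # fit the cubic in a centered, scaled variable: the s1 range is narrow
  # (hundredths of 1/Angstrom), so raw-power cubics are ill-conditioned
  center <- mean(s1); scale <- stats::sd(s1)
  z <- (s1 - center) / scale
  fit <- stats::lm(temperatures ~ z + I(z^2) + I(z^3))
  cf <- unname(stats::coef(fit))
  cf[is.na(cf)] <- 0
  # verify the fitted cubic is strictly monotonic over the calibrated range
  zz <- seq(min(z), max(z), length.out = 401)
  deriv <- cf[2] + 2 * cf[3] * zz + 3 * cf[4] * zz^2
  if (!(all(deriv > 0) || all(deriv < 0))) {
    .stop_invalid("fitted calibration is not monotonic over the s1 range; calibration failed")
  }
  structure(list(coefficients = cf, s1_center = center, s1_scale = scale,
                 s1_range = range(s1),
                 temperature_range = range(temperatures),
                 training = data.frame(temperature = temperatures, s1 = s1),
                 window = window),
            class = "temperature_calibration")
}

#' Temperature from a first-peak position
#'
#' Evaluates the cubic calibration at s1. Positions outside the calibrated
#' s1 range raise an error; temperatures extrapolated beyond the calibrated
#' temperature range trigger a range warning.
#'
#' @param s1 first-peak position, 1/Angstrom.
#' @param calibration a [build_temperature_calibration()] result.
#' @return temperature in K.
#' @export
temperature_from_peak <- function(s1, calibration) {
  stopifnot(inherits(calibration, "temperature_calibration"))
  rng <- calibration$s1_range
  tol <- 1e-9 * diff(rng)
  if (any(s1 < rng[1] - tol) || any(s1 > rng[2] + tol)) {
    .stop_invalid("s1 = ", format(s1), " outside the calibrated range [",
                  format(rng[1]), ", ", format(rng[2]), "] 1/Angstrom")
  }
  cf <- calibration$coefficients
  z <- (s1 - calibration$s1_center) / calibration$s1_scale
  t_est <- cf[1] + cf[2] * z + cf[3] * z^2 + cf[4] * z^3
  tr <- calibration$temperature_range
  if (any(t_est < tr[1] - 1) || any(t_est > tr[2] + 1)) {
    warning("estimated temperature outside the calibrated range [",
            tr[1], ", ", tr[2], "] K")
  }
  t_est
}
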