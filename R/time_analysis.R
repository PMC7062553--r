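# Pump-probe difference-signal handling: normalization, band integration,
# the plasma-lensing instrument-response fit, geometric time smearing and
# noise-vs-integration metrics.

#' Difference scattering signal
#'
#' `dS = (I_on - I_off) / sum(I_off)`: the laser-on/laser-off difference
#' normalized by the total laser-off scattering.
#'
#' @param laser_on,laser_off [radial_profile()]s on matching s grids.
#' @return list with `s` and `delta_S`.
#' @export
difference_signal <- function(laser_on, laser_off) {
  if (!isTRUE(all.equal(laser_on$s, laser_off$s))) {
    .stop_invalid("laser-on and laser-off profiles are on different s grids")
  }
  norm <- sum(laser_off$intensity)
  list(s = laser_on$s,
       delta_S = (laser_on$intensity - laser_off$intensity) / norm)
}

#' Integrate a time scan over an s band
#'
#' Trapezoidal integral of dS(t, s) over the band, per delay. The default
#' band (0.45-0.85 1/Angstrom) isolates the plasma-lensing feature.
#'
#' @param scan a `time_scan` (see [simulate_time_scan()]); if it holds
#'   several scans they are averaged first.
#' @param band integration band, 1/Angstrom.
#' @param scan_index integrate a single scan instead of the average.
#' @return numeric time trace (one value per delay).
#' @export
integrate_band <- function(scan, band = c(0.45, 0.85), scan_index = NULL) {
  stopifnot(inherits(scan, "time_scan"))
  if (band[1] < min(scan$s) || band[2] > max(scan$s)) {
    .stop_invalid("band outside the scan's s grid")
  }
  m <- if (is.null(scan_index)) {
    Reduce(`+`, scan$delta_S) / length(scan$delta_S)
  } else {
    scan$delta_S[[scan_index]]
  }
  sel <- which(scan$s >= band[1] & scan$s <= band[2])
  if (length(sel) < 2) return(rep(0, length(scan$delays)))
  ds <- diff(scan$s[sel])
  apply(m[, sel, drop = FALSE], 1, function(row) {
    sum(ds * (row[-1] + row[-length(row)]) / 2)
  })
}

#' Plasma-lensing trace model
#'
#' `A * G(t - t0; fwhm) + B * Phi(t - t0; fwhm) + C` where G is a
#' peak-normalized Gaussian (the lensing transient) and Phi its cumulative
#' integral scaled to a 0-1 step (the structural signal switched on at t0,
#' exactly "a step convolved with the same Gaussian").
#'
#' @param t delays, ps.
#' @param a Gaussian (lensing) amplitude.
#' @param b step (structural) amplitude.
#' @param t0 time zero, ps.
#' @param fwhm Gaussian FWHM, fs.
#' @param c0 baseline.
#' @return model values at `t`.
#' @export
plasma_trace_model <- function(t, a, b, t0, fwhm, c0 = 0) {
  sigma <- fwhm * 1e-3 / (2 * sqrt(2 * log(2))) # fs -> ps
  a * exp(-(t - t0)^2 / (2 * sigma^2)) + b * stats::pnorm((t - t0) / sigma) + c0
}

#' Fit the plasma-lensing instrument response
#'
#' Nonlinear least squares of [plasma_trace_model()] to a time trace. The
#' FWHM of the Gaussian component is the upper-limit estimate of the
#' experimental time resolution. Initialization: t0 at the trace extremum,
#' FWHM at 200 fs, amplitudes from the extremum values; FWHM is bounded to
#' [10, 2000] fs and flagged if the fit pins it at a bound.
#'
#' @param delays delay grid, ps.
#' @param trace measured (band-integrated) difference trace.
#' @return a `pump_probe_fit` list: `gaussian_amplitude`, `step_amplitude`,
#'   `t0` (ps), `fwhm` (fs), `baseline`, `uncertainties` (1-sigma, from the
#'   fit covariance), `fwhm_at_bound`, and the `fitted` trace.
#' @export
fit_plasma_trace <- function(delays, trace) {
  if (length(delays) < 10) .stop_invalid("need >= 10 delay points spanning the feature")
  if (length(trace) != length(delays)) .stop_invalid("trace/delays length mismatch")
  i_ext <- which.max(abs(trace - stats::median(trace)))
  a0 <- trace[i_ext] - stats::median(trace)
  start <- list(a = a0, b = (trace[length(trace)] - trace[1]) / 2,
                t0 = delays[i_ext], fwhm = 200,
                c0 = stats::median(trace[seq_len(max(3, length(trace) %/% 5))]))
  dat <- data.frame(t = delays, y = trace)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ plasma_trace_model(t, a, b, t0, fwhm, c0),
      data = dat, start = start,
      lower = c(a = -Inf, b = -Inf, t0 = -Inf, fwhm = 10, c0 = -Inf),
      upper = c(a = Inf, b = Inf, t0 = Inf, fwhm = 2000, c0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) .stop_invalid("plasma-trace fit failed to converge: ",
                                      conditionMessage(e))
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 5))
  at_bound <- cf[["fwhm"]] <= 10 + 1e-6 || cf[["fwhm"]] >= 2000 - 1e-6
  if (at_bound) warning("fitted FWHM pinned at a bound")
  structure(list(
    gaussian_amplitude = cf[["a"]], step_amplitude = cf[["b"]],
    t0 = cf[["t0"]], fwhm = cf[["fwhm"]], baseline = cf[["c0"]],
    uncertainties = se, fwhm_at_bound = at_bound,
    fitted = stats::fitted(fit)
  ), class = "pump_probe_fit")
}

#' Geometric time smearing from tilted pump incidence
#'
#' A pump beam incident at an angle to the electron beam illuminates
#' different transverse positions at different times; across a Gaussian spot
#' this smears the effective time resolution. The default convention reports
#' the rms-equivalent contribution `(spot_fwhm / 2.355) * sin(angle) / c`;
#' the `"fwhm"` convention reports the full path-difference spread
#' `spot_fwhm * sin(angle) / c`. The convention is configurable because the
#' two differ by the factor 2.355 and published broadening figures do not
#' always state which is meant.
#'
#' @param spot_fwhm pump spot size (FWHM), um.
#' @param pump_angle_deg pump-electron angle, degrees, in [0, 90).
#' @param convention `"rms"` (default) or `"fwhm"`.
#' @return broadening in fs.
#' @export
geometric_smearing <- function(spot_fwhm, pump_angle_deg,
                               convention = c("rms", "fwhm")) {
  convention <- match.arg(convention)
  if (pump_angle_deg < 0 || pump_angle_deg >= 90) {
    .stop_invalid("pump angle must lie in [0, 90) degrees")
  }
  spread_um <- spot_fwhm * sin(pump_angle_deg * pi / 180)
  if (convention == "rms") spread_um <- spread_um / (2 * sqrt(2 * log(2)))
  spread_um / .C_UM_FS
}

#' Noise of difference scattering vs s band and integration time
#'
#' For replicate normalized difference curves, subtracts a smoothed (moving
#' average) mean difference signal and reports the rms of the residual per s
#' band, together with the rms of the n-replicate running average (the
#' noise-vs-integration-time curve).
#'
#' @param s s grid, 1/Angstrom.
#' @param curves matrix of replicate difference curves (replicates in rows),
#'   already normalized by the total laser-off scattering.
#' @param window moving-average smoothing window in bins (odd; default 9).
#' @param bands named list of s bands (defaults: low 0-0.75, mid 0.75-6,
#'   high 6-10 1/Angstrom, clipped to the grid).
#' @return list with `band_rms` (per band, single replicates) and
#'   `vs_integration` (data frame: n, then one rms column per band).
#' @export
noise_rms <- function(s, curves, window = 9,
                      bands = list(low = c(0, 0.75), mid = c(0.75, 6),
                                   high = c(6, 10))) {
  curves <- as.matrix(curves)
  if (nrow(curves) < 2) .stop_invalid("need >= 2 replicate curves")
  if (ncol(curves) != length(s)) .stop_invalid("curves/s grid mismatch")
  if (window > length(s)) .stop_invalid("smoothing window larger than the curve")
  mean_curve <- colMeans(curves)
  smooth <- stats::filter(mean_curve, rep(1 / window, window), sides = 2)
  smooth <- as.numeric(smooth)
  # moving average is undefined at the edges; fall back to the raw mean there
  smooth[is.na(smooth)] <- mean_curve[is.na(smooth)]
  band_sel <- lapply(bands, function(b) which(s >= b[1] & s <= b[2]))
  resid <- sweep(curves, 2, smooth)
  band_rms <- vapply(band_sel, function(sel) {
    if (!length(sel)) return(NA_real_)
    sqrt(mean(resid[, sel]^2))
  }, numeric(1))
  # noise after n scans: each running average is compared against its own
  # smoothed version, so the smoothing-removal fraction is the same at every
  # n and the Poisson 1/sqrt(n) scaling is preserved
  smooth_self <- function(v) {
    sv <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
    sv[is.na(sv)] <- v[is.na(sv)]
    sv
  }
  ns <- seq_len(nrow(curves))
  vs <- lapply(ns, function(n) {
    avg <- colMeans(curves[seq_len(n), , drop = FALSE])
    avg <- avg - smooth_self(avg)
    vapply(band_sel, function(sel) {
      if (!length(sel)) return(NA_real_)
      sqrt(mean(avg[sel]^2))
    }, numeric(1))
  })
  vs <- as.data.frame(do.call(rbind, vs))
  vs <- cbind(n = ns, vs)
  list(band_rms = band_rms, vs_integration = vs)
}
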