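# Reduction of 2D detector images to calibrated radial intensity profiles,
# and the jet-quality metrics derived from them (transmission,
# multiple-scattering ratio, scan maps).

#' Detector image container
#'
#' @param counts 2D non-negative matrix of detector counts.
#' @param pixel_pitch pixel size, mm.
#' @param beam_center beam center as (x, y) = (column, row) in pixels.
#' @param hole_mask logical matrix of pixels to exclude (central beam hole,
#'   saturated pixels); same shape as `counts`. NULL for none.
#' @param camera_length sample-detector distance, m.
#' @param wavelength electron de Broglie wavelength, pm.
#' @return a `detector_image` object.
#' @export
detector_image <- function(counts, pixel_pitch, beam_center, hole_mask = NULL,
                           camera_length = 3.2,
                           wavelength = electron_wavelength(3.7)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) .stop_invalid("counts must be non-negative")
  if (is.null(hole_mask)) hole_mask <- matrix(FALSE, nrow(counts), ncol(counts))
  if (!identical(dim(hole_mask), dim(counts))) {
    .stop_invalid("hole_mask must have the same shape as counts")
  }
  if (beam_center[1] < 1 || beam_center[1] > ncol(counts) ||
      beam_center[2] < 1 || beam_center[2] > nrow(counts)) {
    .stop_invalid("beam_center must lie inside the image")
  }
  structure(list(counts = counts, pixel_pitch = pixel_pitch,
                 beam_center = beam_center, hole_mask = hole_mask,
                 camera_length = camera_length, wavelength = wavelength),
            class = "detector_image")
}

#' Radial profile container
#'
#' @param s momentum-transfer bin centers, 1/Angstrom.
#' @param intensity mean counts per bin (NA where no pixel contributed).
#' @param n_pixels pixels contributing per bin.
#' @return a `radial_profile` object.
#' @export
radial_profile <- function(s, intensity, n_pixels = rep(1L, length(s))) {
  stopifnot(length(s) == length(intensity), length(s) == length(n_pixels))
  structure(list(s = as.numeric(s), intensity = as.numeric(intensity),
                 n_pixels = as.integer(n_pixels)),
            class = "radial_profile")
}

#' Azimuthally average a detector image
#'
#' Pixel radii are converted to scattering angle by the exact mapping
#' `r = L tan(theta)` and then to momentum transfer s; pixels under the hole
#' mask are excluded; the per-bin statistic is the mean. Bins with no
#' contributing pixels are flagged empty (NA), never interpolated.
#'
#' @param image a [detector_image()].
#' @param n_bins number of uniform s bins (>= 10).
#' @param s_range optional `c(s_min, s_max)` to bin over; defaults to the
#'   image's observable range.
#' @return a [radial_profile()].
#' @export
azimuthal_average <- function(image, n_bins = 480, s_range = NULL) {
  stopifnot(inherits(image, "detector_image"))
  if (n_bins < 10) .stop_invalid("n_bins must be >= 10")
  dims <- dim(image$counts)
  xi <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  yi <- matrix(seq_len(dims[1]), dims[1], dims[2])
  r_mm <- sqrt((xi - image$beam_center[1])^2 + (yi - image$beam_center[2])^2) *
    image$pixel_pitch
  theta <- atan(r_mm / (image$camera_length * 1000))
  s_px <- s_from_angle(theta, image$wavelength)
  keep <- !image$hole_mask
  s_keep <- s_px[keep]
  c_keep <- image$counts[keep]
  if (is.null(s_range)) s_range <- c(0, max(s_keep))
  breaks <- seq(s_range[1], s_range[2], length.out = n_bins + 1)
  bin <- findInterval(s_keep, breaks, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin <= n_bins
  bin <- bin[inside]; c_in <- c_keep[inside]
  n_px <- tabulate(bin, nbins = n_bins)
  # rowsum drops empty bins; rebuild an aligned per-bin mean vector
  means <- rep(NA_real_, n_bins)
  present <- sort(unique(bin))
  means[present] <- as.numeric(rowsum(c_in, bin)[as.character(present), 1]) /
    n_px[present]
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  radial_profile(centers, means, n_px)
}

#' Refine the beam center by azimuthal symmetry
#'
#' Optional centering aid: minimizes the summed squared difference between
#' the radial profiles of the four image quadrants over a small grid of
#' candidate centers around the nominal one.
#'
#' @param image a [detector_image()].
#' @param half_width search half-width in pixels.
#' @param step search step in pixels.
#' @return the refined (x, y) beam center.
#' @export
refine_beam_center <- function(image, half_width = 3, step = 1) {
  offsets <- seq(-half_width, half_width, by = step)
  best <- image$beam_center; best_cost <- Inf
  for (dx in offsets) for (dy in offsets) {
    im2 <- image
    im2$beam_center <- image$beam_center + c(dx, dy)
    prof <- azimuthal_average(im2, n_bins = 60)
    # asymmetry proxy: variance of per-bin means of left vs right half
    left <- im2; right <- im2
    nc <- ncol(image$counts)
    cx <- round(im2$beam_center[1])
    left$hole_mask[, cx:nc] <- TRUE
    right$hole_mask[, 1:cx] <- TRUE
    pl <- azimuthal_average(left, n_bins = 60, s_range = range(prof$s))
    pr <- azimuthal_average(right, n_bins = 60, s_range = range(prof$s))
    ok <- !is.na(pl$intensity) & !is.na(pr$intensity)
    cost <- sum((pl$intensity[ok] - pr$intensity[ok])^2)
    if (cost < best_cost) { best_cost <- cost; best <- im2$beam_center }
  }
  best
}

#' Electron transmission through the jet
#'
#' Ratio of transmitted beam counts with the jet in place to the average
#' counts with no jet. Values above 1 are permitted but flagged as anomalous.
#'
#' @param beam_counts_with_jet,beam_counts_no_jet positive count totals.
#' @return transmission fraction.
#' @export
transmission <- function(beam_counts_with_jet, beam_counts_no_jet) {
  if (any(beam_counts_no_jet <= 0)) .stop_invalid("no-jet reference counts must be positive")
  if (any(beam_counts_with_jet <= 0)) .stop_invalid("jet counts must be positive")
  t <- beam_counts_with_jet / beam_counts_no_jet
  if (any(t > 1)) {
    warning("transmission > 1: jet counts exceed the no-jet reference")
  }
  t
}

# trapezoidal band integral of a profile on its native grid
.band_integral <- function(s, y, band) {
  if (band[1] < min(s) || band[2] > max(s)) {
    .stop_invalid("band [", band[1], ", ", band[2], "] not covered by the profile")
  }
  sel <- which(s >= band[1] & s <= band[2])
  if (length(sel) < 2) .stop_invalid("band contains fewer than 2 profile points")
  if (anyNA(y[sel])) .stop_invalid("band contains empty (NA) bins")
  sum(diff(s[sel]) * (y[sel][-1] + y[sel][-length(sel)]) / 2)
}

#' Multiple-scattering ratio of a radial profile
#'
#' Ratio of intensity integrated over the high band (6.8-9.0 1/Angstrom,
#' where single scattering is weak) to the low band (1.6-3.1 1/Angstrom, the
#' liquid peak). Multiply scattered electrons form a pedestal at all s, so a
#' larger ratio indicates more multiple scattering.
#'
#' @param profile a [radial_profile()] covering both bands.
#' @param high,low integration bands, 1/Angstrom.
#' @return dimensionless ratio.
#' @export
multiple_scattering_ratio <- function(profile, high = c(6.8, 9.0),
                                      low = c(1.6, 3.1)) {
  stopifnot(inherits(profile, "radial_profile"))
  .band_integral(profile$s, profile$intensity, high) /
    .band_integral(profile$s, profile$intensity, low)
}

#' Jet characterization map over a position grid
#'
#' @param points list of per-position records, each a list with `x`, `y`
#'   (um), `beam_counts` (transmitted counts with jet) and `profile`
#'   (a [radial_profile()]).
#' @param beam_counts_no_jet reference beam counts without the jet (required).
#' @param position_uncertainty vertical-position uncertainty, um (metadata).
#' @return data frame with columns `x_um`, `y_um`, `transmission`,
#'   `ms_ratio`; the position uncertainty is carried as an attribute.
#' @export
scan_map <- function(points, beam_counts_no_jet, position_uncertainty = 50) {
  if (missing(beam_counts_no_jet)) {
    .stop_invalid("a no-jet reference measurement is required")
  }
  rows <- lapply(points, function(p) {
    data.frame(x_um = p$x, y_um = p$y,
               transmission = transmission(p$beam_counts, beam_counts_no_jet),
               ms_ratio = multiple_scattering_ratio(p$profile))
  })
  out <- do.call(rbind, rows)
  attr(out, "position_uncertainty_um") <- position_uncertainty
  out
}
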