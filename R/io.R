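# Plain-format I/O: CSV curves, JSON serializations, 16-bit TIFF detector
# images.

#' Write / read a radial profile as CSV
#'
#' Columns: `s_invA`, `intensity`, `n_pixels`.
#' @param profile a [radial_profile()].
#' @param path file path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(s_invA = profile$s, intensity = profile$intensity,
                              n_pixels = profile$n_pixels),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) .stop_invalid("input file not found: ", path)
  d <- utils::read.csv(path)
  radial_profile(d$s_invA, d$intensity,
                 if ("n_pixels" %in% names(d)) d$n_pixels else rep(1L, nrow(d)))
}

#' Write sM(s) or pdf(r) curves as CSV
#'
#' @param sm a [modified_intensity()].
#' @param pd a [pair_distribution()].
#' @param path file path.
#' @export
write_sm_csv <- function(sm, path) {
  utils::write.csv(data.frame(s_invA = sm$s, sM = sm$sM), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sm_csv
#' @export
write_pdf_csv <- function(pd, path) {
  utils::write.csv(data.frame(r_A = pd$r, pdf = pd$pdf), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted background model, calibration or pump-probe fit to JSON
#'
#' @param x a fitted `background_model`, `temperature_calibration` or
#'   `pump_probe_fit`.
#' @param path file path.
#' @export
write_fit_json <- function(x, path) {
  obj <- unclass(x)
  obj$.class <- class(x)[1]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read a detector image as 16-bit TIFF
#'
#' Counts are stored as 16-bit unsigned integers; the geometry metadata is
#' written alongside as a JSON sidecar (`<path>.json`).
#'
#' @param image a [detector_image()].
#' @param path TIFF file path.
#' @export
write_image_tiff <- function(image, path) {
  counts <- pmin(image$counts, 65535L)
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  meta <- list(pixel_pitch = image$pixel_pitch, beam_center = image$beam_center,
               camera_length = image$camera_length, wavelength = image$wavelength,
               hole_mask_rle = .rle_pack(image$hole_mask))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) .stop_invalid("input file not found: ", path)
  m <- tiff::readTIFF(path)
  counts <- round(m * 65535)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    hole <- .rle_unpack(meta$hole_mask_rle, dim(counts))
    detector_image(counts, meta$pixel_pitch, meta$beam_center, hole,
                   meta$camera_length, meta$wavelength)
  } else {
    detector_image(counts, pixel_pitch = 1, beam_center = (dim(counts) + 1) / 2)
  }
}

.rle_pack <- function(mask) {
  r <- rle(as.logical(mask))
  list(lengths = r$lengths, values = r$values)
}

.rle_unpack <- function(packed, dims) {
  if (is.null(packed)) return(matrix(FALSE, dims[1], dims[2]))
  v <- inverse.rle(structure(list(lengths = packed$lengths,
                                  values = as.logical(packed$values)),
                             class = "rle"))
  matrix(v, dims[1], dims[2])
}

#' Plot methods for reduced curves
#'
#' @param x the object to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.radial_profile <- function(x, ...) {
  graphics::plot(x$s, x$intensity, type = "l", xlab = "s (1/Å)",
                 ylab = "intensity (counts)", ...)
}

#' @rdname plot.radial_profile
#' @export
plot.modified_intensity <- function(x, ...) {
  graphics::plot(x$s, x$sM, type = "l", xlab = "s (1/Å)", ylab = "sM(s)", ...)
}

#' @rdname plot.radial_profile
#' @export
plot.pair_distribution <- function(x, ...) {
  graphics::plot(x$r, x$pdf, type = "l", xlab = "r (Å)", ylab = "pdf(r)", ...)
}
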