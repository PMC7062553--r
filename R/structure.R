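# Retrieval of the modified scattering intensity sM(s) and the real-space
# pair distribution function pdf(r) from reduced scattering curves.

#' Background model for static scattering curves
#'
#' Describes the smooth experimental background response: either a power law
#' `A * s^n` (static curves) or a polynomial of degree <= 3 (difference
#' curves).
#'
#' @param form `"power"` or `"polynomial"`.
#' @param degree polynomial degree (<= 3), ignored for the power form.
#' @param fit_range s interval (1/Angstrom) used for fitting.
#' @param exclude optional s interval excluded from the fit (e.g. the liquid
#'   peak), or NULL.
#' @return a `background_model` specification; fit it with [fit_background()].
#' @export
background_model <- function(form = c("power", "polynomial"), degree = 3,
                             fit_range = c(0.4, 10), exclude = c(1.6, 3.1)) {
  form <- match.arg(form)
  if (form == "polynomial" && (degree < 0 || degree > 3)) {
    .stop_invalid("polynomial degree must be <= 3")
  }
  structure(list(form = form, degree = degree, fit_range = fit_range,
                 exclude = exclude, coef = NULL),
            class = "background_model")
}

#' Fit a background model to a radial profile
#'
#' Power-law backgrounds are fitted by least squares in log-log space; the
#' exclusion window (default the 1.6-3.1 1/Angstrom liquid peak) keeps the
#' structured region from biasing the exponent. Polynomial backgrounds are
#' fitted by ordinary least squares over the full fit range.
#'
#' @param s,intensity the curve to fit (1/Angstrom, arbitrary intensity units).
#' @param model a [background_model()].
#' @return the model with fitted `coef` (named `A`, `n` for the power form;
#'   `c0..c3` for the polynomial form).
#' @export
fit_background <- function(s, intensity, model = background_model()) {
  stopifnot(inherits(model, "background_model"))
  sel <- s >= model$fit_range[1] & s <= model$fit_range[2]
  if (!is.null(model$exclude)) {
    sel <- sel & !(s >= model$exclude[1] & s <= model$exclude[2])
  }
  if (sum(sel) < 4) .stop_invalid("too few points in fit_range")
  ss <- s[sel]; ii <- intensity[sel]
  if (model$form == "power") {
    if (any(ss <= 0)) .stop_invalid("power form requires s > 0")
    if (any(ii <= 0)) {
      .stop_invalid("power-law background requires positive intensity over fit_range")
    }
    fit <- stats::lm(log(ii) ~ log(ss))
    model$coef <- c(A = unname(exp(stats::coef(fit)[1])),
                    n = unname(stats::coef(fit)[2]))
  } else {
    X <- stats::poly(ss, degree = model$degree, raw = TRUE)
    fit <- stats::lm(ii ~ X)
    cf <- stats::coef(fit)
    cf[is.na(cf)] <- 0
    model$coef <- stats::setNames(cf, paste0("c", 0:model$degree))
  }
  model
}

#' Evaluate a fitted background model
#'
#' @param object a fitted [background_model()].
#' @param s grid to evaluate on.
#' @param ... unused.
#' @return background intensity on `s`.
#' @export
predict.background_model <- function(object, s, ...) {
  if (is.null(object$coef)) .stop_invalid("background model has not been fitted")
  cf <- object$coef
  if (object$form == "power") {
    cf[["A"]] * s^cf[["n"]]
  } else {
    drop(outer(s, 0:object$degree, `^`) %*% cf)
  }
}

#' Modified scattering intensity sM(s)
#'
#' \eqn{sM(s) = (I_{exp} - I_{bkg}) / I_{at}(s) \cdot s}: the molecular
#' interference signal after background removal, divided by the atomic
#' scattering and multiplied by s to emphasize structural oscillations.
#'
#' @param s momentum-transfer grid, 1/Angstrom.
#' @param i_exp experimental (or simulated) intensity on `s`.
#' @param i_bkg background intensity on `s` (vector, or a fitted
#'   [background_model()] that will be evaluated on `s`).
#' @param i_at theoretical atomic intensity on `s` (strictly positive).
#' @return a `modified_intensity` object with fields `s` and `sM`.
#' @export
modified_intensity <- function(s, i_exp, i_bkg, i_at) {
  if (inherits(i_bkg, "background_model")) i_bkg <- predict(i_bkg, s)
  n <- length(s)
  if (length(i_exp) != n || length(i_bkg) != n || length(i_at) != n) {
    .stop_invalid("grid mismatch: i_exp, i_bkg, i_at must all be on s (no silent resampling)")
  }
  if (any(i_at <= 0)) .stop_invalid("i_at must be strictly positive")
  structure(list(s = as.numeric(s), sM = (i_exp - i_bkg) / i_at * s),
            class = "modified_intensity")
}

#' Pair distribution function by damped sine transform
#'
#' \deqn{pdf(r) = \int_0^{s_{max}} sM(s) \sin(sr) e^{-k s^2} ds}
#' evaluated by trapezoidal quadrature on the native (uniform) s grid. The
#' Gaussian damping suppresses the ringing caused by truncating sM at s_max.
#'
#' @param sm a [modified_intensity()] on a uniform s grid.
#' @param k damping factor in Angstrom^2; the default gives the damping
#'   amplitude 1e-2 at s_max.
#' @param r_grid real-space grid in Angstrom (default 0-12, step 0.02).
#' @return a `pair_distribution` object with fields `r`, `pdf`, `k`, `s_max`.
#' @export
pdf_transform <- function(sm, k = NULL, r_grid = seq(0, 12, by = 0.02)) {
  stopifnot(inherits(sm, "modified_intensity"))
  if (any(k < 0)) .stop_invalid("k must be >= 0")
  s <- sm$s
  ds <- diff(s)
  if (max(ds) - min(ds) > 1e-8 * mean(ds)) {
    .stop_invalid("sM must be on a uniform s grid")
  }
  s_max <- s[length(s)]
  if (is.null(k)) k <- log(100) / s_max^2
  w <- .trap_w(length(s), ds[1])
  damped <- w * sm$sM * exp(-k * s^2)
  # pdf(r_j) = sum_i w_i sM(s_i) exp(-k s_i^2) sin(s_i r_j)
  pdf <- as.numeric(damped %*% outer(s, r_grid, function(si, rj) sin(si * rj)))
  structure(list(r = as.numeric(r_grid), pdf = pdf, k = k, s_max = s_max),
            class = "pair_distribution")
}

# parabolic refinement of a discrete extremum through three points
.parabolic_refine <- function(x, y, idx) {
  if (idx <= 1 || idx >= length(x)) return(x[idx])
  y1 <- y[idx - 1]; y2 <- y[idx]; y3 <- y[idx + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(x[idx])
  x[idx] + 0.5 * (y1 - y3) / denom * (x[idx + 1] - x[idx])
}

#' Locate structural features of a pair distribution function
#'
#' Peaks are located as the discrete maximum within each search window,
#' refined by a parabola through the three surrounding points. Shoulders are
#' located as extrema of the first derivative within their window.
#'
#' @param pd a [pair_distribution()] (or any list with `r` and `pdf`).
#' @param windows named list of `c(lo, hi)` windows in Angstrom.
#' @param types character vector parallel to `windows`, each `"peak"` or
#'   `"shoulder"` (recycled; default all peaks).
#' @return data frame with columns `feature`, `type`, `r` (NA when no feature
#'   exists in the window - absent features are reported, never fabricated).
#' @export
find_features <- function(pd, windows, types = "peak") {
  r <- pd$r; y <- pd$pdf
  types <- rep_len(types, length(windows))
  out <- data.frame(feature = names(windows), type = types, r = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(windows)) {
    win <- windows[[i]]
    sel <- which(r >= win[1] & r <= win[2])
    if (length(sel) < 3) next
    if (types[i] == "peak") {
      yy <- y[sel]
      idx <- which.max(yy)
      # require an interior local maximum
      if (idx == 1 || idx == length(sel)) next
      out$r[i] <- .parabolic_refine(r[sel], yy, idx)
    } else {
      # shoulder: extremum of the first derivative (inflection of pdf)
      dy <- diff(y) / diff(r)
      rm_ <- (r[-1] + r[-length(r)]) / 2
      sel2 <- which(rm_ >= win[1] & rm_ <= win[2])
      if (length(sel2) < 3) next
      dd <- dy[sel2]
      # interior local extrema of the derivative; take the most curved one
      interior <- which(diff(sign(diff(dd))) != 0) + 1
      if (!length(interior)) next
      curv <- abs(dd[interior - 1] - 2 * dd[interior] + dd[interior + 1])
      idx <- interior[which.max(curv)]
      out$r[i] <- .parabolic_refine(rm_[sel2], dd, idx)
    }
  }
  out
}
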