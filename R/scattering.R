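# Relativistic electron kinematics and independent-atom-model (IAM)
# scattering intensities, both from explicit molecular geometries (Debye sum)
# and from pairwise radial distribution functions (RDF forward model).

#' Relativistic de Broglie wavelength of an electron
#'
#' @param kinetic_energy beam kinetic energy in MeV; must be positive.
#' @return wavelength in picometres, \eqn{\lambda = hc / \sqrt{(KE + m_ec^2)^2 - (m_ec^2)^2}}.
#' @examples
#' electron_wavelength(3.7) # ~0.297 pm
#' @export
electron_wavelength <- function(kinetic_energy) {
  if (!is.numeric(kinetic_energy) || any(kinetic_energy <= 0)) {
    .stop_invalid("kinetic_energy must be positive (MeV)")
  }
  pc <- sqrt((kinetic_energy + .MEC2)^2 - .MEC2^2)
  .HC_MEV_PM / pc
}

#' Momentum transfer from scattering angle
#'
#' @param theta scattering angle in radians, in `[0, pi)`.
#' @param wavelength de Broglie wavelength in pm.
#' @return momentum transfer s in 1/Angstrom, \eqn{s = (4\pi/\lambda)\sin(\theta/2)}.
#' @export
s_from_angle <- function(theta, wavelength) {
  if (any(theta < 0) || any(theta >= pi)) .stop_invalid("theta must lie in [0, pi)")
  if (any(wavelength <= 0)) .stop_invalid("wavelength must be positive (pm)")
  lambda_A <- wavelength * 1e-2 # pm -> Angstrom
  (4 * pi / lambda_A) * sin(theta / 2)
}

#' Scattering angle giving a momentum transfer
#'
#' Inverse of [s_from_angle()].
#'
#' @param s momentum transfer, 1/Angstrom.
#' @param wavelength wavelength in pm.
#' @return angle in radians.
#' @export
angle_from_s <- function(s, wavelength) {
  if (any(s < 0)) .stop_invalid("s must be non-negative")
  lambda_A <- wavelength * 1e-2
  x <- s * lambda_A / (4 * pi)
  if (any(x > 1)) .stop_invalid("s out of range for this wavelength")
  2 * asin(x)
}

#' Uniform momentum-transfer grid
#'
#' @param s_min,s_max grid limits in 1/Angstrom, `s_min >= 0`.
#' @param n number of points.
#' @return an `s_grid` numeric vector (strictly increasing, uniform).
#' @export
s_grid <- function(s_min = 0.4, s_max = 10, n = 481) {
  if (s_min < 0 || s_max <= s_min) .stop_invalid("require 0 <= s_min < s_max")
  structure(seq(s_min, s_max, length.out = n), class = c("s_grid", "numeric"))
}

# ---- form factors ----------------------------------------------------------

.ff_env <- new.env(parent = emptyenv())

.ff_table <- function() {
  if (is.null(.ff_env$table)) {
    path <- system.file("extdata", "electron_form_factors.tsv", package = "lued")
    tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    rownames(tab) <- tab$element
    .ff_env$table <- tab
  }
  .ff_env$table
}

#' Relativistic factor gamma = 1 + KE / (m_e c^2)
#' @param kinetic_energy MeV
#' @export
lorentz_gamma <- function(kinetic_energy) 1 + kinetic_energy / .MEC2

#' Elastic electron scattering amplitude for an element
#'
#' Evaluates the tabulated five-Gaussian scattering-factor parameterization
#' (first Born approximation) on a momentum-transfer grid, scaled by the
#' relativistic factor \eqn{\gamma = 1 + KE/m_ec^2}. Phases default to zero;
#' tabulated phases may be supplied for heavier elements where the Born
#' approximation phase differences are no longer negligible.
#'
#' @param element chemical symbol with a tabulated parameterization (H, C, N, O).
#' @param s_grid momentum-transfer grid, 1/Angstrom.
#' @param kinetic_energy beam kinetic energy, MeV.
#' @param phase optional vector of phases eta(s) in radians (recycled);
#'   defaults to zero.
#' @return an object of class `element_form_factor` with fields `element`,
#'   `s_grid`, `amplitude` (|f(s)| in Angstrom), `phase`, `kinetic_energy`.
#' @export
form_factor <- function(element, s_grid, kinetic_energy = 3.7, phase = 0) {
  tab <- .ff_table()
  if (!element %in% rownames(tab)) {
    .stop_invalid("no tabulated scattering-factor parameterization for element '",
                  element, "'")
  }
  if (any(s_grid < 0)) .stop_invalid("s_grid must be non-negative")
  row <- tab[element, ]
  a <- as.numeric(row[paste0("a", 1:5)])
  b <- as.numeric(row[paste0("b", 1:5)])
  q2 <- (s_grid / (4 * pi))^2 # crystallographic q = s/(4*pi)
  amp <- vapply(q2, function(x) sum(a * exp(-b * x)), numeric(1))
  amp <- lorentz_gamma(kinetic_energy) * amp
  structure(
    list(element = element, s_grid = as.numeric(s_grid), amplitude = amp,
         phase = rep_len(phase, length(s_grid)), kinetic_energy = kinetic_energy),
    class = "element_form_factor"
  )
}

#' Form factors for a set of elements
#'
#' @param elements character vector of symbols.
#' @inheritParams form_factor
#' @return named list of `element_form_factor`.
#' @export
form_factor_set <- function(elements, s_grid, kinetic_energy = 3.7) {
  ffs <- lapply(elements, form_factor, s_grid = s_grid,
                kinetic_energy = kinetic_energy)
  names(ffs) <- elements
  ffs
}

.check_ff <- function(ff, elements, n) {
  missing <- setdiff(elements, names(ff))
  if (length(missing)) {
    .stop_invalid("no form factor supplied for element(s): ",
                  paste(missing, collapse = ", "))
  }
  for (el in elements) {
    if (length(ff[[el]]$amplitude) != n) {
      .stop_invalid("form factor for ", el, " not on the requested s grid")
    }
  }
  invisible(TRUE)
}

# ---- IAM intensities -------------------------------------------------------

#' Atomic scattering intensity
#'
#' \eqn{I_{at}(s) = \sum_i N_i |f_i(s)|^2}: the incoherent sum over all atoms;
#' carries no structural information.
#'
#' @param composition named integer vector of element counts, e.g.
#'   `c(O = 1, H = 2)` for a water unit.
#' @param ff named list of form factors from [form_factor_set()].
#' @param s_grid the momentum-transfer grid the form factors were evaluated on.
#' @return numeric intensity curve (strictly positive).
#' @export
atomic_intensity <- function(composition, ff, s_grid) {
  if (length(composition) == 0 || is.null(names(composition))) {
    .stop_invalid("composition must be a named vector of element counts")
  }
  if (any(composition < 1)) .stop_invalid("element counts must be >= 1")
  .check_ff(ff, names(composition), length(s_grid))
  out <- numeric(length(s_grid))
  for (el in names(composition)) {
    out <- out + composition[[el]] * ff[[el]]$amplitude^2
  }
  out
}

#' Molecular geometry
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z` (Angstrom).
#' @return a `molecular_geometry` object.
#' @export
molecular_geometry <- function(atoms) {
  stopifnot(is.data.frame(atoms), all(c("element", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) >= 2) {
    d <- as.matrix(stats::dist(atoms[, c("x", "y", "z")]))
    if (any(d[upper.tri(d)] <= 0)) .stop_invalid("coincident atoms in geometry")
  }
  structure(list(atoms = atoms), class = "molecular_geometry")
}

#' Water molecule geometry
#'
#' Gas-phase-like water geometry: O-H 0.9572 Angstrom, H-O-H 104.52 degrees.
#' @return a `molecular_geometry`.
#' @export
water_geometry <- function() {
  r_oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  molecular_geometry(data.frame(
    element = c("O", "H", "H"),
    x = c(0, r_oh * sin(half), -r_oh * sin(half)),
    y = c(0, r_oh * cos(half), r_oh * cos(half)),
    z = 0
  ))
}

# sinc with analytic limit at x = 0
.sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' Molecular interference intensity by the Debye sum
#'
#' \eqn{I_{mol}(s) = \sum_{i \neq j} |f_i||f_j| \cos(\eta_i - \eta_j)
#' \sin(s r_{ij})/(s r_{ij})} over all ordered atom pairs of an explicit
#' geometry. The \eqn{s \to 0} limit of the sinc kernel is taken as 1.
#'
#' @param geometry a [molecular_geometry()].
#' @param ff named list of form factors on `s_grid`.
#' @param s_grid momentum-transfer grid, 1/Angstrom.
#' @return numeric intensity curve.
#' @export
molecular_intensity_debye <- function(geometry, ff, s_grid) {
  stopifnot(inherits(geometry, "molecular_geometry"))
  atoms <- geometry$atoms
  if (nrow(atoms) < 2) .stop_invalid("need at least 2 atoms")
  .check_ff(ff, unique(atoms$element), length(s_grid))
  d <- as.matrix(stats::dist(atoms[, c("x", "y", "z")]))
  if (any(d[upper.tri(d)] == 0)) .stop_invalid("coincident atoms (r_ij = 0)")
  s <- as.numeric(s_grid)
  out <- numeric(length(s))
  n <- nrow(atoms)
  for (i in seq_len(n - 1)) {
    fi <- ff[[atoms$element[i]]]
    for (j in seq((i + 1), n)) {
      fj <- ff[[atoms$element[j]]]
      term <- fi$amplitude * fj$amplitude * cos(fi$phase - fj$phase) *
        .sinc(s * d[i, j])
      out <- out + 2 * term # ordered pairs (i,j) and (j,i)
    }
  }
  out
}

# ---- RDF container and forward model ---------------------------------------

#' Set of pairwise radial distribution functions
#'
#' Container for the pair RDFs \eqn{g_{lm}(r)} of a liquid together with the
#' composition of the coherence volume, the forward-model input for scattering
#' from an isotropic liquid.
#'
#' @param r_grid uniform radial grid in Angstrom, strictly increasing, from >= 0.
#' @param g named list of RDF vectors; names are unordered element pairs such
#'   as `"O-O"`, `"O-H"`, `"H-H"`.
#' @param counts named vector of atom counts per element in the volume.
#' @param volume coherence volume V in Angstrom^3.
#' @param baseline asymptotic value of each g (1 for liquid RDFs; 0 for
#'   shell-only constructions such as an isolated molecule), recycled over pairs.
#' @param validate check the liquid-RDF invariants (non-negativity and
#'   g -> baseline within 2\% over the last 10\% of the grid).
#' @return an `rdf_set` object.
#' @export
rdf_set <- function(r_grid, g, counts, volume, baseline = 1, validate = TRUE) {
  r <- as.numeric(r_grid)
  if (is.unsorted(r, strictly = TRUE) || r[1] < 0) {
    .stop_invalid("r_grid must be strictly increasing and start >= 0")
  }
  dr <- diff(r)
  if (max(dr) - min(dr) > 1e-8 * mean(dr)) .stop_invalid("r_grid must be uniform")
  if (is.null(names(g))) .stop_invalid("g must be a named list of pair RDFs")
  baseline <- rep_len(baseline, length(g))
  names(baseline) <- names(g)
  for (key in names(g)) {
    gv <- g[[key]]
    if (length(gv) != length(r)) .stop_invalid("g[['", key, "']] not on r_grid")
    if (any(gv < -1e-12)) .stop_invalid("g[['", key, "']] is negative")
    if (validate && baseline[[key]] > 0) {
      tail_idx <- r >= r[length(r)] - 0.1 * (r[length(r)] - r[1])
      if (any(abs(gv[tail_idx] - baseline[[key]]) > 0.02 * baseline[[key]])) {
        .stop_invalid("g[['", key, "']] does not approach its baseline ",
                      "within 2% over the last 10% of r_grid")
      }
    }
  }
  structure(list(r_grid = r, g = g, counts = counts, volume = volume,
                 baseline = baseline),
            class = "rdf_set")
}

.split_pair <- function(key) strsplit(key, "-", fixed = TRUE)[[1]]

# trapezoidal weights for a uniform grid
.trap_w <- function(n, dr) {
  w <- rep(dr, n)
  w[c(1, n)] <- dr / 2
  w
}

#' Atomic intensity of an RDF set
#'
#' \eqn{I_{at}(s) = \sum_l N_l |f_l(s)|^2} over the elements of the coherence
#' volume.
#'
#' @param rdfs an [rdf_set()].
#' @inheritParams atomic_intensity
#' @export
atomic_intensity_rdf <- function(rdfs, ff, s_grid) {
  atomic_intensity(rdfs$counts, ff, s_grid)
}

#' Molecular interference intensity from pair RDFs
#'
#' Forward model for isotropic liquid scattering:
#' \deqn{I_{mol}(s) = \sum_{l,m} |f_m||f_l| \frac{N_m (N_l - \delta_{ml})}{V}
#'   4\pi \int_0^R r^2 \left[g_{lm}(r) - g_\infty\right]
#'   \frac{\sin(sr)}{sr}\,dr,}
#' summed over ordered element pairs. The asymptotic uniform-density component
#' \eqn{g_\infty} of each RDF scatters only into the unresolved forward
#' direction (a delta at s = 0 in the infinite-volume limit), so it is removed
#' from the quadrature rather than truncated at finite R, where it would
#' produce spurious volume-boundary oscillations.
#'
#' @param rdfs an [rdf_set()]; the grid should extend to R >= 10 Angstrom.
#' @param ff named list of form factors on `s_grid`.
#' @param s_grid momentum-transfer grid, 1/Angstrom.
#' @return numeric intensity curve.
#' @export
molecular_intensity_rdf <- function(rdfs, ff, s_grid) {
  stopifnot(inherits(rdfs, "rdf_set"))
  r <- rdfs$r_grid
  if (r[length(r)] < 10) {
    warning("RDF cutoff R < 10 Angstrom may truncate structural shells")
  }
  elements <- unique(unlist(lapply(names(rdfs$g), .split_pair)))
  .check_ff(ff, elements, length(s_grid))
  s <- as.numeric(s_grid)
  dr <- r[2] - r[1]
  w <- .trap_w(length(r), dr)
  # kernel matrix sinc(s_i * r_j) weighted for trapezoid quadrature
  K <- outer(s, r, function(si, rj) .sinc(si * rj))
  out <- numeric(length(s))
  for (key in names(rdfs$g)) {
    pr <- .split_pair(key)
    l <- pr[1]; m <- pr[2]
    h <- rdfs$g[[key]] - rdfs$baseline[[key]]
    integ <- as.numeric(K %*% (w * r^2 * h)) # \int r^2 h sinc dr
    nl <- rdfs$counts[[l]]; nm <- rdfs$counts[[m]]
    if (l == m) {
      pref <- nm * (nl - 1) / rdfs$volume
      mult <- 1
    } else {
      pref <- nm * nl / rdfs$volume
      mult <- 2 # (l,m) and (m,l) ordered pairs share the same g
    }
    out <- out + mult * pref * 4 * pi *
      ff[[l]]$amplitude * ff[[m]]$amplitude * integ
  }
  out
}
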