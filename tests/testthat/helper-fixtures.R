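# Shared fixtures, computed once per test run. Everything is generated in
# code; no stored data.

fx <- new.env()

fx_s <- function() {
  if (is.null(fx$s)) fx$s <- s_grid(0.4, 10, 481)
  fx$s
}

fx_ff <- function() {
  if (is.null(fx$ff)) fx$ff <- form_factor_set(c("O", "H"), fx_s())
  fx$ff
}

fx_model <- function() {
  if (is.null(fx$model)) fx$model <- water_rdf_model()
  fx$model
}

fx_rdfs_290 <- function() {
  if (is.null(fx$rdfs290)) fx$rdfs290 <- generate_rdfs(fx_model(), 290)
  fx$rdfs290
}

# exact (noise-free) forward components at 290 K on the default grid
fx_forward_290 <- function() {
  if (is.null(fx$fwd290)) {
    s <- fx_s(); ff <- fx_ff(); rdfs <- fx_rdfs_290()
    fx$fwd290 <- list(
      i_at = atomic_intensity_rdf(rdfs, ff, s),
      i_mol = molecular_intensity_rdf(rdfs, ff, s)
    )
  }
  fx$fwd290
}

# noiseless simulated profiles over the calibration temperatures
fx_calib <- function() {
  if (is.null(fx$calib)) {
    temps <- seq(250, 400, by = 10)
    profs <- lapply(temps, function(tk) {
      simulate_profile(generate_rdfs(fx_model(), tk), fx_s(), poisson = FALSE)
    })
    fx$calib <- list(temps = temps, profiles = profs,
                     calibration = build_temperature_calibration(temps, profs))
  }
  fx$calib
}

# delta-like shell RDF for one O-H pair, the Debye-equivalence bridge
make_delta_rdf <- function(r0, sigma = 0.005, r_step = 0.002) {
  r <- seq(0, 25, by = r_step)
  V <- 1e6
  counts <- c(O = 1, H = 1)
  g <- 1 / (4 * pi * pmax(r, 1e-6)^2 * (counts[["H"]] / V)) *
    stats::dnorm(r, r0, sigma)
  rdf_set(r, list(`O-H` = g), counts, V, baseline = 0, validate = FALSE)
}
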