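# lued

Analysis chain for liquid-phase MeV ultrafast electron diffraction (UED) on
thin free-flowing liquid sheets, implemented as an R package.

Electron diffraction from a ~100 nm water sheet probed by relativistic
(3.7 MeV) electrons gives access to the hydrogen-bond network of liquid water
in real space and, in pump–probe mode, to structural dynamics with ~200 fs
resolution. `lued` covers the full reduction and interpretation chain:

* **Scattering theory.** Relativistic kinematics
  (λ = hc/√((E+mec²)² − (mec²)²) ≈ 0.30 pm at 3.7 MeV; s = (4π/λ)sin(θ/2)),
  independent-atom-model (IAM) intensities from tabulated electron scattering
  factors (Peng et al. 1996, γ-scaled), both as a Debye sum over explicit
  geometries and from pairwise radial distribution functions g(r) of an
  isotropic liquid (Dohn-style forward integral).
* **Pattern reduction.** Azimuthal averaging of detector images with exact
  r = L·tanθ mapping, hole/saturation masks, electron transmission, and the
  high/low-band multiple-scattering ratio (∫6.8–9.0 / ∫1.6–3.1 Å⁻¹).
* **Structure retrieval.** Power-law/polynomial background removal, modified
  intensity sM(s) = (I_exp − I_bkg)/I_at·s, damped sine transform
  pdf(r) = ∫ sM(s) sin(sr) e^(−ks²) ds, and feature location (peaks and
  shoulders).
* **Thermometry and jet diagnostics.** Cubic first-peak calibration T(s₁)
  built from simulated profiles over 250–400 K; thin-film interference
  thickness 2nd·cosθₜ = (m − ½)λ (102 nm sensitivity floor at 505 nm / 30°);
  Beer–Lambert thickness; jet velocity; evaporative cooling rate.
* **Pump–probe analysis.** Plasma-lensing instrument-response fit (Gaussian
  plus erf step with shared width), geometric time smearing of tilted pump
  incidence, and rms noise vs s band and integration time.
* **Synthetic data.** A seeded generator (parametric Gaussian-shell water
  RDFs, Poisson detector images, drifting-t₀ time scans, interference
  fringes) that emulates every input the chain consumes.

## Worked example

Forward-model liquid water at 290 K from the packaged RDF model and read its
structure back out of the diffraction pattern:

```r
library(lued)

model <- water_rdf_model()                 # frozen Gaussian-shell water RDFs
rdfs  <- generate_rdfs(model, temperature = 290)
s     <- s_grid(0.4, 10, 481)              # experimental s range, 1/Å
ff    <- form_factor_set(c("O", "H"), s, kinetic_energy = 3.7)

sm <- modified_intensity(s, molecular_intensity_rdf(rdfs, ff, s),
                         rep(0, length(s)), atomic_intensity_rdf(rdfs, ff, s))
pd <- pdf_transform(sm)                    # damped sine transform, k = ln(100)/s_max²
find_features(pd,
              windows = list(oh = c(0.7, 1.4), hb = c(1.5, 2.2),
                             shell1 = c(2.0, 3.5), shell2 = c(3.8, 5.2),
                             shell3 = c(6.0, 7.8)),
              types = c("peak", "shoulder", "peak", "peak", "peak"))
#>   feature     type         r
#> 1      oh     peak 0.9907501
#> 2      hb shoulder 1.8014230
#> 3  shell1     peak 2.8999929
#> 4  shell2     peak 4.3914885
#> 5  shell3     peak 6.9098244
```

The five features are the structural motifs of liquid water: the bonded O–H
distance (1.0 Å), the hydrogen-bonded O···H shoulder (1.8 Å), the
nearest-neighbour O···O distance (2.9 Å), and the second and third hydration
shells (4.4 and 6.9 Å). Thermometry and the time-domain fit:

```r
cal_profiles <- lapply(seq(250, 400, 10), function(tk)
  simulate_profile(generate_rdfs(model, tk), s, poisson = FALSE))
cal <- build_temperature_calibration(seq(250, 400, 10), cal_profiles)
prof <- simulate_profile(rdfs, s, poisson = FALSE)
temperature_from_peak(first_peak_position(prof), cal)
#> [1] 290.0625

scan <- simulate_time_scan(fwhm = 209, noise_sd = 0.05, seed = 1)
fit  <- fit_plasma_trace(scan$delays, integrate_band(scan, c(0.45, 0.85)))
c(fwhm_fs = fit$fwhm, t0_ps = fit$t0)
#>      fwhm_fs        t0_ps
#> 206.0920129   -0.0024040
```

`run_static()`, `run_thermometry()` and `run_timescan()` orchestrate these
stages from a single YAML configuration (see
`inst/extdata/default_config.yaml`) and write CSV/JSON artifacts stamped with
the configuration hash. Note that the full pipeline path fits and subtracts a
power-law background before the transform; the resulting residuals distort
the weakest low-r features (the bonded O–H peak can wash out at realistic
background levels) while the hydration-shell positions remain stable — the
same behaviour the measurement itself exhibits.

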