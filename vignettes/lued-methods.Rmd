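---
title: "Models and methods behind the lued analysis chain"
author: "lued authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the lued analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lued)
```

# Scope

`lued` implements the analysis chain of a liquid-phase MeV ultrafast electron
diffraction (UED) experiment on a thin free-flowing water sheet: reduction of
2D diffraction images to radial intensity profiles, extraction of the modified
scattering intensity $sM(s)$ and the real-space pair distribution function
$pdf(r)$, diffraction thermometry from the first scattering peak, jet
diagnostics (thin-film interference thickness, Beer–Lambert thickness,
velocity, cooling rate), and pump–probe time-trace analysis (plasma-lensing
instrument-response fits, geometric time smearing, noise-vs-integration
metrics). A seeded synthetic-data generator emulates the instrument so that
every stage is testable without measured data.

# Scattering model

## Kinematics

An electron of kinetic energy $E_k$ has de Broglie wavelength
$\lambda = hc / \sqrt{(E_k + m_ec^2)^2 - (m_ec^2)^2}$; at 3.7 MeV this is
0.297 pm. The momentum transfer is $s = (4\pi/\lambda)\sin(\theta/2)$, and a
detector at camera length $L$ maps pixel radius to angle through the exact
relation $r = L\tan\theta$ (the small-angle error would be negligible at
$s \le 10\,\mathrm{Å^{-1}}$, but exactness is free).

## Independent atom model

Under the independent atom model (IAM) the elastic intensity splits into an
atomic term carrying no structure,
$I_{at}(s) = \sum_i N_i |f_i(s)|^2$, and a molecular interference term. For an
explicit geometry the latter is the Debye sum over ordered atom pairs,

$$I_{mol}(s) = \sum_{i \ne j} |f_i||f_j| \cos(\eta_i - \eta_j)
\frac{\sin(s r_{ij})}{s r_{ij}},$$

with the $s \to 0$ limit of the sinc kernel taken as 1. For an isotropic
liquid described by pairwise radial distribution functions $g_{lm}(r)$ the
interference term is computed per element pair as

$$I_{mol}(s) = \sum_{l,m} |f_m||f_l|\,
\frac{N_m (N_l - \delta_{ml})}{V}\, 4\pi \int_0^R r^2\,
\bigl[g_{lm}(r) - g_\infty\bigr] \frac{\sin(sr)}{sr}\, dr .$$

The asymptotic uniform-density component $g_\infty$ of each RDF is removed
from the quadrature: in the infinite-volume limit a homogeneous fluid
scatters only into the unresolved forward direction ($\delta$ at $s = 0$),
whereas truncating it at finite $R$ would add a boundary oscillation of
amplitude $\sim 4\pi R s^{-2} N^2/V$ that dwarfs the atomic term. Container
objects carry the baseline explicitly (1 for liquid RDFs, 0 for shell-only
constructions), which keeps the identity between the RDF route and the Debye
sum exact: a delta-like shell for one pair reproduces the Debye sum for the
matching two-atom geometry to better than $10^{-5}$ relative, which the test
suite asserts at the 1% level.

Scattering amplitudes $|f(s)|$ use the five-Gaussian parameterization of
elastic electron scattering factors of Peng, Ren, Dudarev and Whelan (Acta
Cryst. A52, 257, 1996), shipped as a plain-text table for H, C, N and O, and
scaled by the relativistic factor $\gamma = 1 + E_k/m_ec^2$ (8.24 at
3.7 MeV). This is standard practice for keV–MeV IAM work on light elements at
$s \le 10\,\mathrm{Å^{-1}}$; partial-wave (ELSEPA-class) calculations are out
of scope. Phases $\eta$ default to zero — for $Z \le 8$ at MeV energies phase
differences are negligible — but `form_factor()` accepts tabulated phases, as
the appropriate phase treatment is a configuration, not a constant of the
method.

Quadrature is trapezoidal on a uniform $r$ grid with step 0.01 Å and cutoff
$R = 25$ Å; halving the step changes $I_{mol}$ by less than 0.1% at all $s$
(asserted in the tests).

# Structure retrieval

The modified intensity is $sM(s) = (I_{exp} - I_{bkg})/I_{at}(s)\cdot s$. For
static curves the smooth experimental background $I_{bkg} = A s^n$ is fitted
by least squares in log–log space over 0.4–10 Å$^{-1}$, excluding the
1.6–3.1 Å$^{-1}$ liquid peak so that the structured region does not bias the
exponent (the exclusion window is configurable). Difference curves use a
polynomial of degree $\le 3$. The real-space function is the damped sine
transform

$$pdf(r) = \int_0^{s_{max}} sM(s)\,\sin(sr)\, e^{-k s^2}\, ds,$$

evaluated by trapezoid on the native uniform $s$ grid, on an $r$ grid of
0–12 Å with step 0.02 Å. The default damping is $k = \ln(100)/s_{max}^2$
(amplitude $10^{-2}$ at $s_{max}$), which suppresses the
$2\pi/s_{max} \approx 0.63$ Å truncation ringing while shifting the 2.9 Å
peak by less than 0.02 Å in forward tests. Peaks are located as the discrete
maximum within a search window refined by a parabola through the surrounding
points; shoulders as the most curved interior extremum of the first
derivative. A window without an interior maximum reports the feature as
absent — never fabricated.

Because imperfect background removal distorts $pdf$ amplitudes (a limitation
the measurement itself shares), only feature *positions* are treated as
quantitative; amplitudes are qualitative throughout the package.

# The synthetic water model

Real MD-derived RDFs are not shipped; the generator uses a parametric
Gaussian-shell stand-in (`inst/extdata/water_rdf_model.yaml`), with each pair
RDF built as an erf-switched uniform baseline (excluded-volume core) plus
Gaussian shells parameterized by center, width and pair weight. The model was
calibrated **once** so that the full forward chain at 290 K — RDFs →
$I_{mol}/I_{at}$ → $sM$ → damped sine transform — shows the liquid-water
feature set at 1.0 Å (bonded O–H), 1.8 Å (hydrogen-bonded O···H shoulder),
2.9 Å (first-shell O···O), 4.4 and 6.9 Å (second and third hydration shells),
and then frozen. Shell centers are therefore *effective* values tuned against
the transform chain (the transform's $r^2$- and $s$-weightings displace peaks
by up to ~0.15 Å from the underlying shell centers), not literal bond
lengths.

Temperature dependence is a uniform relative contraction of all
intermolecular distances, $d\mu/dT = -1.5\times10^{-3}\,\mu$ per K (baseline
onsets included), a mild first-shell broadening, and a relative shell-weight
growth of $5\times10^{-3}$ per K that compensates the $r^2$ loss of shell
scattering power under contraction so the first diffraction peak stays well
defined across 250–400 K. These coefficients are generator conventions, not
physical claims: their signs reproduce the observed direction of the
first-peak shift (toward lower $s$ at lower temperature); their magnitudes
were chosen so the peak shift is comfortably resolvable at realistic counting
statistics ($10^6$ counts per profile), and they are documented here rather
than asserted as water physics. Consequently the thermometry acceptance is a
*self-consistency* statement about the pipeline, not an absolute temperature
scale.

What the generator emulates: temperature-dependent isotropic liquid
scattering, a smooth power-law instrument background, Poisson counting noise,
a central beam hole, a flat multiple-scattering pedestal that grows once the
sheet exceeds 20% of the electron mean free path, thin-film interference
fringes, and separable plasma-lensing difference signals with $t_0$ drift and
white noise. What it does not emulate: detector gain structure and readout
noise, saturation, beam-profile anisotropy, inelastic backgrounds with
structure, multiple-scattering transport, or IAM breakdown. Tests passing on
synthetic data therefore validate the *analysis chain* — its estimators,
conventions and round-trip identities — not the instrument model itself.

# Diffraction thermometry

Forward profiles are simulated at 10 K steps over 250–400 K and the
first-peak position $s_1$ extracted from each; temperature is fitted as a
cubic in $s_1$ (centered and scaled internally — the $s_1$ range spans only
hundredths of Å$^{-1}$ and raw-power cubics are numerically ill-conditioned)
and the fit is required to be strictly monotonic over the calibrated range.
The calibration direction is $T(s_1)$, matching how the curve is used.

Locating a ~0.5 Å$^{-1}$-wide liquid peak to $\sim10^{-3}$ Å$^{-1}$ at
$10^6$ counts is the delicate step. The estimator takes the highest
*interior local maximum* of a 5-bin moving-average of the windowed profile
(a decaying background ramp can exceed the liquid peak at the window edge,
but it is not itself a peak), then refines with a parabola over ±12 bins
(±0.24 Å$^{-1}$ on the default grid), re-centered once on its own vertex
because the discrete maximum of a broad noisy peak can sit well off-center.
A ±3-bin parabola — the narrowest conceivable refinement — has vertex jitter
of order the peak width under these statistics and was rejected on
measurement; the wide recentred window brings single-profile temperature
errors below 3 K across 250–400 K at $10^6$ counts, which the test suite
asserts over 20 seeds at five temperatures. Identical estimator settings are
used for calibration and inversion, so the (small) window-asymmetry bias
cancels.

Jet diagnostics are closed-form: thin-film constructive interference
$2 n d \cos\theta_t = (m - \tfrac12)\lambda$ with the *interior* (refracted)
angle from Snell's law — this reading reproduces the 102 nm sensitivity floor
of the 505 nm / 30° / $n=1.336$ configuration exactly, which is why it was
adopted over the exterior-angle reading; Beer–Lambert thickness
$d = -\ln T \cdot \Lambda$ with $\Lambda \approx 1\,\mu$m; jet velocity as
volumetric flow over the cylinder cross-section (13 m/s at 0.25 ml/min
through 20 µm); cooling rate as finite-difference $dT/dx \times v$, exact on
linear profiles.

# Pump–probe analysis

The plasma-lensing trace is fitted to
$A\,G(t - t_0; \mathrm{fwhm}) + B\,\Phi(t - t_0) + C$, where $G$ is a
peak-normalized Gaussian and $\Phi$ its cumulative integral scaled to a 0–1
step — making "a step convolved with the same Gaussian" exact by
construction. Fitting uses Levenberg–Marquardt with $t_0$ initialized at the
trace extremum, FWHM at 200 fs, amplitudes from the extremum values, and FWHM
bounded to [10, 2000] fs (a fit pinned at a bound is flagged). On its own
model the fit is unbiased: the mean fitted width over seeded noisy traces is
within 2% of truth at moderate noise (asserted).

Geometric smearing from a pump beam tilted by $\alpha$ against the electron
beam across a Gaussian spot of FWHM $w$ is reported by default as the
rms-equivalent contribution $(w/2.355)\sin\alpha / c$ (≈35 fs at 50 µm, 30°);
the full path-difference convention $w\sin\alpha/c$ (≈83 fs) is available as
`convention = "fwhm"`. Published broadening figures do not always state the
convention, so it is an explicit argument rather than a guess.

Noise is estimated from replicate normalized difference curves by subtracting
a moving-average-smoothed reference and taking the rms per band
(0–0.75, 0.75–6, 6–10 Å$^{-1}$). For the noise-vs-integration-time curve each
running $n$-average is compared against its *own* smoothed version, so the
smoothing-removal fraction is identical at every $n$ and pure counting noise
scales exactly as $n^{-1/2}$ (slope $-0.5 \pm 0.05$ in log–log, asserted by
Monte-Carlo). Subtracting one fixed reference would correlate with the
averages and distort the scaling.

# Numerical and design choices

* Units are fixed internally: $s$ in Å$^{-1}$, $r$ in Å, $f$ in Å, energies
  in MeV, wavelengths in pm; converters live at the boundary only.
* Azimuthal averaging uses the per-bin mean (Poisson maximum likelihood for
  moderate counts); outlier pixels are handled by masks, not robust
  statistics. Empty bins are `NA`, never interpolated. Default bin width
  0.02 Å$^{-1}$.
* Beam center comes from configuration; an optional refinement minimizes
  left/right profile asymmetry on a small search grid.
* The multiple-scattering pedestal is flat in $s$ (multiply scattered
  electrons land everywhere) and is diagnosed by the 6.8–9.0 over
  1.6–3.1 Å$^{-1}$ band-integral ratio; for a flat profile this ratio is the
  band-width ratio 22/15 = 1.4667, the limit any profile approaches as a
  pedestal grows to dominance.
* All generators are pure functions of (parameters, seed); every synthetic
  artifact carries its ground truth, and pipeline outputs embed an md5 hash
  of the canonicalized run configuration.
* Degenerate inputs error loudly and early: coincident atoms, negative RDFs,
  non-uniform transform grids, bands outside a profile's support, fringe
  inversion on non-monotonic thickness profiles, out-of-range calibration
  inputs.

Problem sizes used throughout the tests and the acceptance script — 481-point
$s$ grids, 2501-point $r$ grids, 16 calibration temperatures, 20-seed
Monte-Carlo sets, 512×512 detector images — were chosen as the smallest
sizes at which the statistical assertions are stable; all quantitative
statements in this vignette are recomputed by the test suite or the
acceptance script, not quoted.

# Known limitations

* The temperature scale is internally consistent but conventional: absolute
  thermometry would require measured or MD-grade RDFs.
* $pdf$ amplitudes are non-normative (background-removal residuals leak into
  the transform); only positions are asserted.
* The IAM ignores bonding charge redistribution; low-$s$ departures from IAM
  are expected in reality and are outside scope.
* Saturation, flat-field structure and readout noise are not modelled; the
  Poisson model is the noise floor, not the ceiling.

# A worked pass through the chain

```{r example, eval = FALSE}
model <- water_rdf_model()
rdfs <- generate_rdfs(model, temperature = 290)
s <- s_grid(0.4, 10, 481)
ff <- form_factor_set(c("O", "H"), s, kinetic_energy = 3.7)

sm <- modified_intensity(s, molecular_intensity_rdf(rdfs, ff, s),
                         rep(0, length(s)), atomic_intensity_rdf(rdfs, ff, s))
pd <- pdf_transform(sm)
find_features(pd, windows = list(shell1 = c(2.0, 3.5)))

res <- run_static(run_config())       # profile -> sM -> pdf -> features
res$features
```
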