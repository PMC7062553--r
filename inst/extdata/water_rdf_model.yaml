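# Parametric Gaussian-shell model of the pairwise radial distribution
# functions of liquid water, calibrated once at 290 K so that the
# electron-weighted pair distribution function obtained through the full
# forward chain (RDF -> I_mol/I_at -> sM -> damped sine transform, s_max =
# 10 1/A) exhibits the liquid-water features at 1.0, 1.8, 2.9, 4.4 and 6.9 A
# (bonded O-H, hydrogen-bonded O..H, first, second and third hydration
# shells). SYNTHETIC stand-in for MD-derived RDFs: shell centers are
# effective values tuned against the transform chain, not literal bond
# lengths. Shell weights are pair counts per central atom (first element of
# the pair key). Temperature coefficients implement a uniform relative
# contraction of intermolecular distances with rising temperature
# (dmu/dT = -1.5e-3 * mu per K, likewise the baseline onsets) plus a mild first-shell broadening; they are
# generator conventions chosen only to give a smooth, monotonic shift of
# the first diffraction peak toward higher s at higher temperature; the
# relative weight growth compensates the r^2 loss of shell scattering
# power under contraction so the peak stays well defined over the range.
reference_temperature: 290
valid_temperature: [250, 400]
n_molecules: 4054
volume: 125000          # A^3 (50 x 50 x 50 box)
r_max: 25               # A
r_step: 0.01            # A
pairs:
  O-O:
    core_onset: 2.45    # A, erf switch of the uniform baseline
    core_width: 0.18
    donset_dT: -3.675e-3
    shells:
      - {mu: 2.75, sigma: 0.145, weight: 2.6, dmu_dT: -4.125e-3, dsigma_dT: 3.0e-4, dweight_rel_dT: 5.0e-3}
      - {mu: 3.55, sigma: 0.45, weight: -1.3, dmu_dT: -5.325e-3, dsigma_dT: 0.0, dweight_rel_dT: 5.0e-3}
      - {mu: 4.45, sigma: 0.45, weight: 2.4, dmu_dT: -6.675e-3, dsigma_dT: 0.0, dweight_rel_dT: 5.0e-3}
      - {mu: 5.6, sigma: 0.55, weight: -2.0, dmu_dT: -8.4e-3, dsigma_dT: 0.0, dweight_rel_dT: 5.0e-3}
      - {mu: 6.82, sigma: 0.65, weight: 3.2, dmu_dT: -1.023e-2, dsigma_dT: 0.0, dweight_rel_dT: 5.0e-3}
  O-H:
    core_onset: 2.95
    core_width: 0.25
    donset_dT: -4.425e-3
    shells:
      - {mu: 1.00, sigma: 0.035, weight: 2.0, dmu_dT: 0.0, dsigma_dT: 0.0}
      - {mu: 1.66, sigma: 0.12, weight: 2.6, dmu_dT: -2.49e-3, dsigma_dT: 0.0, dweight_rel_dT: 5.0e-3}
      - {mu: 3.25, sigma: 0.35, weight: 3.0, dmu_dT: -4.875e-3, dsigma_dT: 0.0, dweight_rel_dT: 5.0e-3}
  H-H:
    core_onset: 2.2
    core_width: 0.3
    donset_dT: -3.3e-3
    shells:
      - {mu: 1.55, sigma: 0.045, weight: 1.0, dmu_dT: 0.0, dsigma_dT: 0.0}
      - {mu: 2.35, sigma: 0.25, weight: 2.0, dmu_dT: -3.525e-3, dsigma_dT: 0.0, dweight_rel_dT: 5.0e-3}
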