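# Full-defaults run configuration. Every tunable the pipeline uses lives
# here; user configs override individual keys.
seed: 1
beam:
  kinetic_energy: 3.7      # MeV
  camera_length: 3.2       # m
  hole_diameter: 3         # mm
static:
  temperature: 290         # K (synthetic input)
  s_min: 0.4               # 1/A
  s_max: 10
  n_s: 481
  thickness: 120           # nm
  flux: 1.0e+6             # total counts
  background_A: 0.25
  background_n: -1.5
  background_exclude: [1.6, 3.1]
  damping_k: null          # null -> ln(100)/s_max^2
  r_max: 12                # A
  r_step: 0.02
  poisson: false
  profile: null            # CSV path of a measured profile, or null
thermometry:
  calibration_range: [250, 400]   # K
  calibration_step: 10
  positions_um: [0, 150, 300, 450]
  position_temperatures: [320, 310, 300, 290]
  poisson: false
  flow_rate_ml_min: 0.25
  jet_diameter_um: 20
timescan:
  delay_range: [-1, 1]     # ps
  n_delays: 45
  fwhm: 209                # fs
  t0: 0
  gaussian_amplitude: 1.0
  step_amplitude: 0.25
  n_scans: 6
  drift_fs: 0
  noise_sd: 0.05
  band: [0.45, 0.85]       # 1/A
jet:
  mean_free_path_um: 1
  fringe_wavelength_nm: 505
  fringe_incidence_deg: 30
  n_film: 1.336
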