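{
  "_comment": "Annotated run configuration for twinrisk::run_pipeline / twinrisk_cli. Keys mirror run_config(); 'scenario' mirrors simulation_params() and is used when no 'input' cohort CSV is given.",
  "seed": 1,
  "models": ["sat", "ACE", "AE", "CE", "E"],
  "sex_modes": ["adjusted", "stratified_F", "stratified_M"],
  "age_grid": [40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95, 100],
  "n_boot": 50,
  "weight_cap": 20,
  "scenario": {
    "_comment": "registry-scale default: ~46,000 pairs, A/C/E = 0.18/0.61/0.21, 13-year window",
    "n_mz": 9998, "n_dz_ss": 17339, "n_dz_os": 19037,
    "a2": 0.18, "d2": 0, "c2": 0.61, "e2": 0.21,
    "lifetime_risk_F": 0.082, "lifetime_risk_M": 0.055,
    "onset_shape": 6, "onset_scale": 85,
    "gompertz_a": 1e-4, "gompertz_b": 0.085,
    "birth_year_range": [1905, 1985],
    "window_start_year": 1997, "window_length": 13,
    "include_prevalent": false,
    "seed": 1
  }
}
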