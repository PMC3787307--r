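{
  "cohort": {
    "n_subjects": 181,
    "n_trials": 100
  },
  "control": {
    "n_grid": 4,
    "tol": 1e-06,
    "prob_floor": 1e-10,
    "theta_variant": "pow3",
    "c_max": 5
  },
  "split": 40,
  "seed": 20160901
}
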