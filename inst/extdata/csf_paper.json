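{
  "model": "csf",
  "mu": 0.04,
  "parameters": {
    "gamma_max": { "range": [2, 2000],  "grid": 20, "spacing": "log10" },
    "f_max":     { "range": [0.2, 100], "grid": 20, "spacing": "log10" },
    "beta1":     { "range": [2, 128],   "grid": 20, "spacing": "log10" },
    "delta1":    { "range": [0.2, 3],   "grid": 20, "spacing": "log10" }
  },
  "stimuli": {
    "log_f": { "range": [-0.6989700043360187, 1.5563025007672873], "grid": 20 },
    "log_c": { "range": [-3, 0], "grid": 20 }
  },
  "truth": { "gamma_max": 100, "f_max": 2.5, "beta1": 2.5, "delta1": 0.25 },
  "policy": { "kind": "ee", "epsilon": 1.5, "trials": 250 },
  "replications": 5000,
  "seed": 1
}
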