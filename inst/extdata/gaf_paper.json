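{
  "model": "gaf",
  "parameters": {
    "t_cr":  { "range": [5, 10], "grid": 20, "spacing": "linear" },
    "sigma": { "range": [1, 4],  "grid": 20, "spacing": "linear" }
  },
  "stimuli": {
    "gap": { "range": [4, 12], "grid": 25 }
  },
  "truth": { "t_cr": 7.3, "sigma": 2.2804 },
  "policy": { "kind": "ee", "epsilon": 6.4, "trials": 300 },
  "replications": 5000,
  "seed": 1
}
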