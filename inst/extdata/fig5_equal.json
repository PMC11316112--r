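{
  "stream_x": {
    "mu_true": 0.8,
    "sigma": 0.25,
    "rate": 1
  },
  "stream_y": {
    "mu_true": 0.2,
    "sigma": 0.25,
    "rate": 1
  },
  "agents": {
    "D": {
      "w": 0.5,
      "bias_x": 0,
      "bias_y": 0,
      "prior_x": {
        "m": 0.5,
        "s2": 1
      },
      "prior_y": {
        "m": 0.5,
        "s2": 1
      },
      "inertia": 0
    },
    "R": {
      "w": 0.5,
      "bias_x": 0,
      "bias_y": 0,
      "prior_x": {
        "m": 0.5,
        "s2": 1
      },
      "prior_y": {
        "m": 0.5,
        "s2": 1
      },
      "inertia": 0
    }
  },
  "threshold": 0.5,
  "n_steps": 10000,
  "n_runs": 100,
  "seed": 0,
  "record": "log",
  "truncate": false
}
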