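{
  "release_models": {
    "synchronous": {
      "r0_per_ms": 5.70e-9,
      "components": [
        {"label": "S1", "P": 0.0175,  "tau_ms": 0.163, "k_per_ms": 1.79,  "mu_ms": 3.41, "sigma_ms": 0.168},
        {"label": "S2", "P": 0.0220,  "tau_ms": 6.50,  "k_per_ms": 18.0,  "mu_ms": 3.56, "sigma_ms": 0.0977},
        {"label": "S3", "P": 1.70e-5, "tau_ms": 80.0,  "k_per_ms": 0.526, "mu_ms": 10.0, "sigma_ms": 4.44},
        {"label": "S4", "P": 1.10e-5, "tau_ms": 1000,  "k_per_ms": 0.142, "mu_ms": 50.0, "sigma_ms": 11.5}
      ]
    },
    "asynchronous": {
      "r0_per_ms": 1.84e-5,
      "components": [
        {"label": "A1", "P": 3.72e-3, "tau_ms": 17.7,  "k_per_ms": 1.60,   "mu_ms": 3.05, "sigma_ms": 0.243},
        {"label": "A2", "P": 0.0111,  "tau_ms": 76.9,  "k_per_ms": 0.0759, "mu_ms": 4.00, "sigma_ms": 1.14},
        {"label": "A3", "P": 0.0136,  "tau_ms": 1000,  "k_per_ms": 0.0337, "mu_ms": 76.5, "sigma_ms": 21.9}
      ]
    }
  }
}
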