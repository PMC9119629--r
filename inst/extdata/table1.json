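{
  "sensors": {
    "synchronous": {
      "n_sites": 5,
      "k_on_per_M_s": 6.12e7,
      "k_off_per_s": 2.32e3,
      "gamma_per_s": 6.0e3,
      "coop_b": 0.25,
      "refractory_eps_ms": 6.34
    },
    "asynchronous": {
      "n_sites": 2,
      "k_on_per_M_s": 3.82e6,
      "k_off_per_s": 13,
      "gamma_per_s": 50,
      "coop_b": 0.25,
      "refractory_eps_ms": 6.34
    }
  }
}
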