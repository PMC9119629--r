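{
 "sensors": {
  "synchronous": {
   "n_sites": 5,
   "k_on_per_M_s": 61200000.0,
   "k_off_per_s": 2320.0,
   "gamma_per_s": 6000.0,
   "coop_b": 0.25,
   "refractory_eps_ms": 6.34
  },
  "asynchronous": {
   "n_sites": 2,
   "k_on_per_M_s": 3820000.0,
   "k_off_per_s": 13,
   "gamma_per_s": 50,
   "coop_b": 0.25,
   "refractory_eps_ms": 6.34
  }
 },
 "release_models": {
  "synchronous": {
   "r0_per_ms": 5.7e-09,
   "components": [
    {
     "label": "S1",
     "P": 0.0175,
     "tau_ms": 0.163,
     "k_per_ms": 1.79,
     "mu_ms": 3.41,
     "sigma_ms": 0.168
    },
    {
     "label": "S2",
     "P": 0.022,
     "tau_ms": 6.5,
     "k_per_ms": 18.0,
     "mu_ms": 3.56,
     "sigma_ms": 0.0977
    },
    {
     "label": "S3",
     "P": 1.7e-05,
     "tau_ms": 80.0,
     "k_per_ms": 0.526,
     "mu_ms": 10.0,
     "sigma_ms": 4.44
    },
    {
     "label": "S4",
     "P": 1.1e-05,
     "tau_ms": 1000,
     "k_per_ms": 0.142,
     "mu_ms": 50.0,
     "sigma_ms": 11.5
    }
   ]
  },
  "asynchronous": {
   "r0_per_ms": 1.84e-05,
   "components": [
    {
     "label": "A1",
     "P": 0.00372,
     "tau_ms": 17.7,
     "k_per_ms": 1.6,
     "mu_ms": 3.05,
     "sigma_ms": 0.243
    },
    {
     "label": "A2",
     "P": 0.0111,
     "tau_ms": 76.9,
     "k_per_ms": 0.0759,
     "mu_ms": 4.0,
     "sigma_ms": 1.14
    },
    {
     "label": "A3",
     "P": 0.0136,
     "tau_ms": 1000,
     "k_per_ms": 0.0337,
     "mu_ms": 76.5,
     "sigma_ms": 21.9
    }
   ]
  }
 },
 "facilitation": {
  "S1": [
   {
    "label": "S11",
    "tau_ms": 95.9,
    "n_steps": 7.0,
    "xi": 1.27
   },
   {
    "label": "S12",
    "tau_ms": 7.66,
    "n_steps": 2.32,
    "xi": 2.93
   }
  ],
  "S2": [
   {
    "label": "S21",
    "tau_ms": 13.1,
    "n_steps": 10.0,
    "xi": 1.23
   },
   {
    "label": "S22",
    "tau_ms": 114,
    "n_steps": 17.6,
    "xi": 1.68
   }
  ],
  "S3": [
   {
    "label": "S3",
    "tau_ms": 199,
    "n_steps": 12.5,
    "xi": 2.67
   }
  ],
  "S4": [
   {
    "label": "S4",
    "tau_ms": 1,
    "n_steps": 1,
    "xi": 0
   }
  ],
  "A1": [
   {
    "label": "A11",
    "tau_ms": 141,
    "n_steps": 12.2,
    "xi": 1.48
   },
   {
    "label": "A12",
    "tau_ms": 17.2,
    "n_steps": 12.5,
    "xi": 0.996
   }
  ],
  "A2": [
   {
    "label": "A2",
    "tau_ms": 126,
    "n_steps": 12.1,
    "xi": 1.67
   }
  ],
  "A3": [
   {
    "label": "A3",
    "tau_ms": 1,
    "n_steps": 1,
    "xi": 0
   }
  ]
 },
 "calcium": {
  "baseline_uM": 0.1,
  "onset_delay_ms": 1.0,
  "distance_um": 0.4,
  "length_constant_um": 0.204,
  "components": [
   {
    "amplitude_uM": 15.0,
    "tau_ms": 1.5
   },
   {
    "amplitude_uM": 0.6,
    "tau_ms": 20
   },
   {
    "amplitude_uM": 0.11,
    "tau_ms": 1000
   }
  ]
 }
}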