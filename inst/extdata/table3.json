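{
  "facilitation": {
    "S1": [
      {"label": "S11", "tau_ms": 95.9, "n_steps": 7.00, "xi": 1.27},
      {"label": "S12", "tau_ms": 7.66, "n_steps": 2.32, "xi": 2.93}
    ],
    "S2": [
      {"label": "S21", "tau_ms": 13.1, "n_steps": 10.0, "xi": 1.23},
      {"label": "S22", "tau_ms": 114,  "n_steps": 17.6, "xi": 1.68}
    ],
    "S3": [
      {"label": "S3",  "tau_ms": 199,  "n_steps": 12.5, "xi": 2.67}
    ],
    "S4": [
      {"label": "S4",  "tau_ms": 1,    "n_steps": 1,    "xi": 0}
    ],
    "A1": [
      {"label": "A11", "tau_ms": 141,  "n_steps": 12.2, "xi": 1.48},
      {"label": "A12", "tau_ms": 17.2, "n_steps": 12.5, "xi": 0.996}
    ],
    "A2": [
      {"label": "A2",  "tau_ms": 126,  "n_steps": 12.1, "xi": 1.67}
    ],
    "A3": [
      {"label": "A3",  "tau_ms": 1,    "n_steps": 1,    "xi": 0}
    ]
  }
}
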