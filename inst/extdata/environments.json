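[
  {
    "name": "LD",
    "label": "large difference",
    "betas": [0.37, 0.23, 0.11, 0.07, 0.04],
    "beta_e": 0.18
  },
  {
    "name": "MD",
    "label": "medium difference",
    "betas": [0.26, 0.20, 0.16, 0.13, 0.11],
    "beta_e": 0.16
  },
  {
    "name": "SD",
    "label": "small difference",
    "betas": [0.19, 0.18, 0.17, 0.16, 0.15],
    "beta_e": 0.15
  },
  {
    "name": "ND",
    "label": "no difference",
    "betas": [0.17, 0.17, 0.17, 0.17, 0.17],
    "beta_e": 0.15
  }
]
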