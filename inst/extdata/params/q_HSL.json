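{
  "mu_c": 0.73,
  "nu_c": 0.15,
  "alpha_c": 0.52,
  "beta_c": 0.68,
  "mu": 4.41,
  "nu": 1.84,
  "alpha": 0.51,
  "beta": 8.35,
  "mu_h": 0.47,
  "sigma_h": 0.3,
  "gamma": 1.8
}
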