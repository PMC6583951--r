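{
  "mu_c": 0.42,
  "nu_c": 0.71,
  "alpha_c": 0.63,
  "beta_c": 1.16,
  "mu": 4.43,
  "nu": 1.72,
  "alpha": 0.56,
  "beta": 6.35,
  "mu_h": 0.47,
  "sigma_h": 0.3,
  "gamma": 1.8
}
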