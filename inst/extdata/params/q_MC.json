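{
  "mu_c": 0.6,
  "nu_c": 0.69,
  "alpha_c": 0.3,
  "beta_c": 0.4,
  "mu": 4.42,
  "nu": 1.82,
  "alpha": 0.58,
  "beta": 8.35,
  "mu_h": 0.47,
  "sigma_h": 0.3,
  "gamma": 1.8
}
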