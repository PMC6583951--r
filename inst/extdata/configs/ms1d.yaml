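# Striped-pattern setting: 1D opponent axis c = s - 1 on [-2, 2].
setting: ms1d
seed: 1
grid:
  nx: 80
  ny: 8
  spacing: 0.05
  nc: 41
  boundary: zero
stimulus:
  stripe_width: 4
  n_pairs: 4
  c_test: "opp:0"
params: q_MC
search:
  n_candidates: 41
  temperature: 0.01
  refine: 1
  tol: 1.0e-3
  max_iter: 100
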