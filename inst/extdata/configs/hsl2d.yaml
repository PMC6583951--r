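# Square-in-surround setting on the chromatic disk (constant luminance).
setting: hsl2d
seed: 1
grid:
  nx: 17
  ny: 17
  spacing: 0.1
  nc: 11
  boundary: zero
stimulus:
  patch_half_width: 0.5
  surround_half_width: 0.8
  test_surround: "hsl:60,0.5,0.5"
params: q_HSL
search:
  temperature: 0.002
  refine: 3
  refine_points: 5
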