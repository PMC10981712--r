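# Default reference values for the eight-element heavy-metal panel.
# background: local non-agricultural-land soil background C0, mg/kg
# toxicity_coefficient: Hakanson toxicity response coefficients T_r
# igeo_k: correction coefficient of the geo-accumulation index
background:
  As: 7.94
  Hg: 11.48
  Cd: 0.10
  Pb: 14.67
  Cr: 40.54
  Cu: 15.23
  Zn: 48.00
  Ni: 18.53
toxicity_coefficient:
  As: 10
  Hg: 40
  Cd: 30
  Pb: 5
  Cr: 2
  Cu: 5
  Zn: 1
  Ni: 5
igeo_k: 1.5
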