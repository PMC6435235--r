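# Unharvested polygyny grid over harem size and divorce rate.
model:
  h: 2
  mu_m1: 0.5
  mu_f1: 0.5
  mu_m2: 0.1
  mu_f2: 0.1
  alpha_m: 0.5
  alpha_f: 0.5
  d: 0
  k: 20
  s1: 0.5
  E: 0
sweep:
  h: [2, 4, 6, 8, 10]
  d: [0, 0.5, 1, 2]
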