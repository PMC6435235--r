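# Monogamy baseline: symmetric vital rates, no harvest.
model:
  h: 1
  mu_m1: 0.5
  mu_f1: 0.5
  mu_m2: 0.1
  mu_f2: 0.1
  alpha_m: 0.5
  alpha_f: 0.5
  d: 0.1
  k: 20
  s1: 0.5
  E: 0
mating:
  family: harmonic
integrator:
  tol: 1.0e-10
  t_max: 10000
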