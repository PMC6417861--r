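# Example run configuration: wild-type scenario at the reference point of
# the phase diagrams. Unspecified parameters fall back to package defaults;
# the fully resolved configuration is written next to every run's outputs.
dials:
  alpha_over_l: 1.2
  beta_scaled: 100.0
scenario: wt
grid:
  n: 256
  t_max: 20000
  dt_max: 0.25
  tol: 1.0e-06
noise:
  amp: 0.0
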