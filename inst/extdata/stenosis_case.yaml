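# Example case file: cosine-stenosis microvessel, study conditions.
geometry:
  case: stenosis
  H: 50.0e-6        # unobstructed radius, m
  hs: 25.0e-6       # throat radius, m (eta_h = 0.5)
  Ls: 70.0e-6       # stenosis length, m (eta_L = 1.4)
  L_up: 500.0e-6
  L_down: 500.0e-6
  mode: axisymmetric
grid:
  nx: 120
  ny: 20
  cluster_wall: -1.2    # negative: concentrate cells toward the core
  cluster_throat: 2.5
fluid:
  plasma_density: 1027
  plasma_viscosity: 0.96e-3
  rbc_density: 1093
  rbc_size_a: 8.0e-6
bc:
  Vt: 0.2           # inlet velocity amplitude, m/s
  Ht: 0.2           # inlet hematocrit
solver:
  max_outer: 400
  tol: 2.0e-5
  scheme: tvd
output:
  sections: [-30.0e-6, 0.0, 30.0e-6]
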