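domain:
  L: 0.1
  'N': 128
tumors:
- center:
  - 0.05
  - 0.05
  - 0.05
  radius: 0.01
tissue:
  healthy:
    k: 0.51
    omega_b: 0.0005
    rho: 1000.0
    rho_b: 1000.0
    Q_m: 420.0
    c: 4200.0
    c_b: 4200.0
  tumor:
    k: 0.64
    omega_b: 0.00125
    rho: 1000.0
    rho_b: 1000.0
    Q_m: 4200.0
    c: 4200.0
    c_b: 4200.0
treatment:
  A: 80000.0
  r0: 0.019
  Np: 1
  t_end: 3000.0
  ht: 0.1
  T_a: 37.0
  T_init: 37.0
  T_damage: 43.0
optimizer:
  pop_multiplier: 35
  F:
  - 0.5
  - 1.0
  C: 0.7
  atol: 0.0
  tol: 0.01
  max_generations: 10000
  force_mutant_index: yes
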