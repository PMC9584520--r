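# Fixed chaotic reference input vector of the focal three-strain topology
# (one QS produced by strain 1 positively inducing bacteriocins B1 and B2;
# B1 made by strains 1 and 2 and killing strain 1; B2 made and felt by
# strain 3). Second half-max regulation constant applies to B2.
parameters:
  C_N: 1.0e9
  C_B: 1.0e-9
  C_A: 1.0e-9
  D: 0.167
  K: 3.9e-5
  K_omega: 1.6e-7
  S0: 0.02
  gamma: 1.0e11
  kA: [3.5e-17]
  KBmax: [3.58e-17, 8.89e-16]
  K_AB: [3.37e-9, 4.26e-8]
  mu_max: [2.61, 1.17, 1.48]
  n_z: [1.2, 1.43]
  n_omega: 1.87
  omega_max: 0.79
initial_state:
  N1: 0.24
  N2: 0.25
  N3: 0.27
  S: 0.02
  B1: 1.0e-71
  B2: 1.0e-71
  A1: 1.0e-10
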