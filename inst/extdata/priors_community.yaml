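# Uniform prior table for community model parameters and initial state.
# Constants have equal bounds. Wide rate/affinity parameters are sampled on
# a log10 scale; all others on a linear scale.
parameters:
  C_N:       {min: 1.0e9,   max: 1.0e9,   scale: linear}   # OD -> cells
  C_B:       {min: 1.0e-9,  max: 1.0e-9,  scale: linear}   # bacteriocin state scale
  C_A:       {min: 1.0e-9,  max: 1.0e-9,  scale: linear}   # QS state scale
  D:         {min: 0.01,    max: 0.5,     scale: linear}   # dilution rate (1/h)
  K_AB:      {min: 1.0e-9,  max: 1.0e-6,  scale: log10}    # half-max regulation (M)
  K:         {min: 3.9e-5,  max: 3.9e-5,  scale: linear}   # Monod half-saturation (M)
  K_omega:   {min: 1.0e-7,  max: 1.0e-6,  scale: log10}    # half-max killing (M)
  S0:        {min: 0.02,    max: 0.02,    scale: linear}   # feed substrate (M)
  gamma:     {min: 1.0e11,  max: 1.0e11,  scale: linear}   # yield (cells/M)
  kA:        {min: 1.0e-22, max: 1.0e-15, scale: log10}    # QS production (M/h/cell)
  KBmax:     {min: 1.0e-22, max: 1.0e-15, scale: log10}    # max expression (M/h/cell)
  mu_max:    {min: 0.4,     max: 3.0,     scale: linear}   # max growth (1/h)
  n_z:       {min: 1.0,     max: 2.0,     scale: linear}   # regulation Hill coefficient
  n_omega:   {min: 1.0,     max: 2.0,     scale: linear}   # killing Hill coefficient
  omega_max: {min: 0.5,     max: 2.0,     scale: linear}   # max killing rate (1/h)
  N0:        {min: 0.01,    max: 0.5,     scale: linear}   # initial strain density (OD)
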