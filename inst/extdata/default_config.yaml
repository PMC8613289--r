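# Default configuration of the nucleocytoplasmic actin model.
# All quantities are in the model's arbitrary units: concentration,
# length (the cell has unit diameter: outer radius 0.45 on a [-0.5, 0.5]
# square) and "time units". The kinetic values are a documented
# constraint-satisfying set: cofilin-actin associates faster (and
# dissociates slower) in the cytoplasm than the nucleus, profilin-actin the
# mirror image, cofilin/profilin transfer is symmetric, cofilin-actin
# import outpaces profilin-actin export, F-actin and the catalytic factor
# do not diffuse, and nuclear diffusion is tenfold the cytoplasmic value so
# nuclear profiles stay comparatively flat.
parameters:
  gamma_Gc: 0.2
  gamma_Fc: 0.2
  alpha_Xi_c: 1.0
  gamma_Xi_c: 0.1
  alpha_Xi_n: 0.1
  gamma_Xi_n: 1.0
  alpha_Ups_c: 0.1
  gamma_Ups_c: 1.0
  alpha_Ups_n: 1.0
  gamma_Ups_n: 0.1
  alpha_Theta_c: 0.05
  gamma_Theta_c: 0.05
  mu1: 0.08
  mu2: 8.0
  gamma_Ec: 0.0
  beta_Pc: 0.01
  beta_Pn: 0.01
  beta_Cc: 0.01
  beta_Cn: 0.01
  beta_Xi_c: 0.02
  beta_Ups_n: 0.004
  D:
    G_c: 5.0e-3
    F_c: 0.0
    C_c: 5.0e-3
    Xi_c: 5.0e-3
    P_c: 5.0e-3
    Ups_c: 5.0e-3
    Theta_c: 5.0e-3
    E_c: 0.0
    G_n: 5.0e-2
    C_n: 5.0e-2
    Xi_n: 5.0e-2
    P_n: 5.0e-2
    Ups_n: 5.0e-2
geometry:
  p1: [0.0, 0.0]
  r1: 0.15
  p2: [0.0, 0.0]
  r2: 0.45
  p3: [0.225, 0.0]   # tangent to the nucleus along +x
  r3: 0.075
  Ec_init: 50.0
  xlim: [-0.5, 0.5]
  ylim: [-0.5, 0.5]
solver:
  dt: 0.01
  t_end: 400.0
  output_every: 100
  positivity_tolerance: 1.0e-12
  ec_decay_order: zeroth
equilibration:
  seed_concentrations:
    G_c: 0.3
    F_c: 0.3
    C_c: 0.6
    Xi_c: 0.0
    P_c: 0.6
    Ups_c: 0.0
    Theta_c: 0.0
    E_c: 0.0
    G_n: 0.3
    C_n: 0.6
    Xi_n: 0.0
    P_n: 0.6
    Ups_n: 0.0
  tol: 1.0e-6
  max_t: 4000.0
  check_every: 5.0
  ode_burnin: true
scenario:
  name: full
  mu1_active: true
  mu2_active: true
  region_distance: 0.0
  t_end: 400.0
  snapshot_times: [0.0, 50.0, 400.0]
  grid: 201
  seed: 1
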