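test_that("implicit diffusion fixes uniform fields and D = 0 is identity", {
  dom <- toy_domain()$domain
  u <- matrix(0, dom$nx, dom$ny)
  u[dom$cells_c] <- 0.8
  out <- diffusion_step(u, dom, "cytoplasm", D = 0.3, dt = 0.05, n_steps = 7)
  expect_equal(out, u, tolerance = 1e-12)

  st <- make_random_state(dom, fixture_spec(seed = 11))
  out0 <- diffusion_step(st$fields$G_c, dom, "cytoplasm", D = 0, dt = 0.01)
  expect_identical(out0, st$fields$G_c)
})

test_that("implicit diffusion conserves mass and damps roughness", {
  dom <- toy_domain()$domain
  u <- make_random_state(dom, fixture_spec(seed = 12))$fields$G_c
  out <- diffusion_step(u, dom, "cytoplasm", D = 0.01, dt = 0.01,
                        n_steps = 50)
  expect_equal(sum(out), sum(u), tolerance = 1e-12)
  expect_lt(stats::var(out[dom$cells_c]), stats::var(u[dom$cells_c]))
  expect_true(all(out[dom$cells_c] >= 0))
  # nothing leaks outside the compartment
  expect_true(all(out[dom$mask != 1L] == 0))
})

test_that("cosine eigenmode decays at the analytic heat-equation rate", {
  # coarse companion of the high-resolution validation run
  dom <- rectangular_domain(101)
  mode <- matrix(cos(pi * dom$x), dom$nx, dom$ny)
  D <- 0.01; Tt <- 5; dt <- 0.01
  out <- diffusion_step(mode, dom, "cytoplasm", D = D, dt = dt,
                        n_steps = Tt / dt)
  ratio <- sum(out * mode) / sum(mode * mode)
  expect_equal(ratio, exp(-D * pi^2 * Tt), tolerance = 0.01)
})

test_that("null model is a fixed point and time still advances", {
  dom <- toy_domain()$domain
  p <- default_parameters()
  p$D[] <- 0
  for (nm in setdiff(nucactin:::scalar_param_names(), character(0))) p[[nm]] <- 0
  st <- flat_state(dom, default_seed_concentrations(), t = 0)
  out <- step_state(st, dom, p, solver_config(dt = 0.01), n_steps = 25)
  expect_equal(out$t, 0.25)
  for (sp in nucactin_species()) {
    expect_identical(out$fields[[sp]], st$fields[[sp]])
  }
})

test_that("pure dephosphorylation follows the explicit-Euler recurrence", {
  dom <- toy_domain()$domain
  p <- default_parameters()
  p$D[] <- 0
  for (nm in nucactin:::scalar_param_names()) p[[nm]] <- 0
  p$gamma_Theta_c <- 0.3
  st <- flat_state(dom, c(Theta_c = 1))
  k <- 200; dt <- 0.01
  out <- step_state(st, dom, p, solver_config(dt = dt), n_steps = k)
  got <- out$fields$Theta_c[dom$cells_c[1]]
  expect_equal(got, (1 - p$gamma_Theta_c * dt)^k, tolerance = 1e-12)
  # and the continuous limit to first order in dt
  expect_equal(got, exp(-p$gamma_Theta_c * k * dt), tolerance = 5e-3)
})

test_that("trajectories record schedules, totals and catalytic invariance", {
  dom <- toy_domain()$domain
  geom <- toy_domain()$geom
  p <- default_parameters()
  st <- flat_state(dom, default_seed_concentrations())
  st$fields$E_c <- initialize_catalytic_field(dom, geom)

  cfg <- solver_config(dt = 0.01, t_end = 5, output_every = 100)
  tr <- run_simulation(st, dom, p, cfg, snapshot_times = c(0, 2, 5))
  expect_equal(tr$summary$t, seq(0, 5, by = 1))
  expect_equal(vapply(tr$snapshots, function(s) s$t, numeric(1)), c(0, 2, 5))
  expect_identical(tr$clip_events, 0)
  expect_identical(tr$limited_fluxes, 0)

  # catalytic factor total is exactly constant under gamma_Ec = 0
  expect_true(all(tr$summary$total_E == tr$summary$total_E[1]))
  # conserved groups drift only at round-off level even on this short run
  expect_lt(max(conservation_drift(tr)$drift_percent), 1e-8)

  # t_end = 0: only the initial state
  tr0 <- run_simulation(st, dom, p, solver_config(t_end = 0))
  expect_identical(nrow(tr0$summary), 1L)
  expect_equal(tr0$summary$t, 0)
})

test_that("runaway states are caught, not propagated", {
  dom <- toy_domain()$domain
  p <- default_parameters()
  p$gamma_Theta_c <- 300   # dt * rate > 2 drives Theta_c negative
  st <- flat_state(dom, c(Theta_c = 1))
  expect_error(
    run_simulation(st, dom, p, solver_config(dt = 0.01, t_end = 1)),
    "positivity_tolerance")
  expect_error(diffusion_step(st$fields$Theta_c, dom, "cytoplasm",
                              D = -1, dt = 0.01))
})
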