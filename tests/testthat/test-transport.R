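test_that("transfer table covers every species with the stated flux laws", {
  sp <- transfer_spec(default_parameters())
  expect_setequal(sp$species, c("P", "C", "Xi", "Ups", "G", "F", "Theta", "E"))
  expect_identical(sp$type[sp$species == "Xi"], "one_way_into_nucleus")
  expect_identical(sp$type[sp$species == "Ups"], "one_way_into_cytoplasm")
  # G-actin itself never crosses the envelope directly
  expect_true(all(sp$type[sp$species %in% c("G", "F", "Theta", "E")] ==
                    "no_flux"))
})

test_that("face flux laws match direct substitution", {
  p <- default_parameters()
  sp <- transfer_spec(p)

  # symmetric cofilin at equal concentrations carries no net flux
  expect_equal(nuclear_face_flux("C", 0.7, 0.7, sp), 0)
  # cofilin-actin import ignores the nuclear side entirely
  expect_equal(nuclear_face_flux("Xi", 0, 100, sp), 0)
  expect_equal(nuclear_face_flux("Xi", 2, 0, sp), 2 * p$beta_Xi_c)
  # profilin-actin export: c_nuc = 2 with beta 0.5 gives magnitude 1 outward
  p2 <- default_parameters(beta_Ups_n = 0.5, beta_Xi_c = 0.6)
  expect_equal(nuclear_face_flux("Ups", 5, 2, transfer_spec(p2)), -1.0)
  # no-flux species
  expect_equal(nuclear_face_flux("G", 3, 1, sp), 0)

  expect_error(nuclear_face_flux("Z", 1, 1, sp), "unknown species")
  expect_error(nuclear_face_flux("C", -1, 1, sp), ">= 0")
})

test_that("boundary transfer conserves each species exactly", {
  fx <- make_toy_domain(fixture_spec(seed = 5))
  dom <- fx$domain
  st <- make_random_state(dom, fixture_spec(seed = 5))
  p <- default_parameters()
  d <- apply_boundary_fluxes(st, dom, transfer_spec(p), dt = 0.01)

  for (pair in list(c("P_c", "P_n"), c("C_c", "C_n"), c("Xi_c", "Xi_n"),
                    c("Ups_c", "Ups_n"))) {
    expect_lt(abs(sum(d[[pair[1]]]) + sum(d[[pair[2]]])), 1e-12)
  }
  # one-way directionality
  expect_true(all(d$Xi_c <= 0) && all(d$Xi_n >= 0))
  expect_true(all(d$Ups_n <= 0) && all(d$Ups_c >= 0))
  expect_identical(attr(d, "limited"), 0L)

  # all transfer coefficients zero: no increments at all
  p0 <- p
  for (b in c("beta_Pc", "beta_Pn", "beta_Cc", "beta_Cn", "beta_Xi_c",
              "beta_Ups_n")) p0[[b]] <- 0
  d0 <- apply_boundary_fluxes(st, dom, transfer_spec(p0), dt = 0.01)
  expect_true(all(vapply(d0, function(m) all(m == 0), logical(1))))
})

test_that("uniform symmetric cofilin exchanges nothing on any cell", {
  dom <- toy_domain()$domain
  st <- flat_state(dom, c(C_c = 0.4, C_n = 0.4))
  d <- apply_boundary_fluxes(st, dom, transfer_spec(default_parameters()),
                             dt = 0.01)
  expect_true(all(d$C_c == 0) && all(d$C_n == 0))
})

test_that("compiled transfer step matches the exposed flux operation", {
  fx <- make_toy_domain(fixture_spec(seed = 8))
  dom <- fx$domain
  st <- make_random_state(dom, fixture_spec(seed = 8))
  # isolate transfer in the engine: no reactions, no diffusion
  p <- default_parameters()
  p$D[] <- 0
  for (r in c("gamma_Gc", "gamma_Fc", "alpha_Xi_c", "gamma_Xi_c",
              "alpha_Xi_n", "gamma_Xi_n", "alpha_Ups_c", "gamma_Ups_c",
              "alpha_Ups_n", "gamma_Ups_n", "alpha_Theta_c",
              "gamma_Theta_c", "mu1", "mu2")) p[[r]] <- 0
  dt <- 0.01
  out <- step_state(st, dom, p, solver_config(dt = dt))
  d <- apply_boundary_fluxes(st, dom, transfer_spec(p), dt = dt)
  for (nm in names(d)) {
    expect_equal(out$fields[[nm]], st$fields[[nm]] + d[[nm]],
                 tolerance = 1e-13)
  }
})

test_that("documented explicit-transfer stability margin holds at defaults", {
  dom <- build_domain(cell_geometry(), 201, 201)
  expect_true(nucactin:::check_transfer_stability(default_parameters(),
                                                  dom, dt = 0.01))
})
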