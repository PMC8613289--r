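zeros_c <- function(...) {
  v <- list(G_c = 0, F_c = 0, C_c = 0, Xi_c = 0, P_c = 0, Ups_c = 0,
            Theta_c = 0, E_c = 0)
  utils::modifyList(v, list(...))
}
zeros_n <- function(...) {
  v <- list(G_n = 0, C_n = 0, Xi_n = 0, P_n = 0, Ups_n = 0)
  utils::modifyList(v, list(...))
}

test_that("single-species activations produce exactly the printed terms", {
  p <- default_parameters()

  r0 <- cytoplasm_reaction_rates(zeros_c(), p)
  expect_true(all(unlist(r0) == 0))   # gamma_Ec = 0 makes dE_c vanish too

  r <- cytoplasm_reaction_rates(zeros_c(G_c = 1), p)
  expect_equal(r$G_c, -p$gamma_Gc)
  expect_equal(r$F_c, p$gamma_Gc)
  expect_true(all(unlist(r[c("C_c", "Xi_c", "P_c", "Ups_c", "Theta_c",
                             "E_c")]) == 0))

  rn0 <- nucleus_reaction_rates(zeros_n(), p)
  expect_true(all(unlist(rn0) == 0))

  rn <- nucleus_reaction_rates(zeros_n(G_n = 1, C_n = 1), p)
  expect_equal(rn$Xi_n, p$alpha_Xi_n)
  expect_equal(rn$G_n, -p$alpha_Xi_n)
  expect_equal(rn$C_n, -p$alpha_Xi_n)
  expect_true(all(unlist(rn[c("P_n", "Ups_n")]) == 0))
})

test_that("reactions conserve actin, cofilin and profilin pointwise", {
  p <- default_parameters()
  set.seed(42)
  n <- 1000
  loc <- as.list(stats::setNames(
    as.data.frame(matrix(stats::runif(8 * n, 0, 3), n, 8)),
    cytoplasm_species()))
  r <- cytoplasm_reaction_rates(loc, p)
  expect_lt(max(abs(r$G_c + r$F_c + r$Xi_c + r$Ups_c)), 1e-12)
  expect_lt(max(abs(r$C_c + r$Xi_c + r$Theta_c)), 1e-12)
  expect_lt(max(abs(r$P_c + r$Ups_c)), 1e-12)

  locn <- as.list(stats::setNames(
    as.data.frame(matrix(stats::runif(5 * n, 0, 3), n, 5)),
    nucleus_species()))
  rn <- nucleus_reaction_rates(locn, p)
  expect_lt(max(abs(rn$G_n + rn$Xi_n + rn$Ups_n)), 1e-12)
  expect_lt(max(abs(rn$C_n + rn$Xi_n)), 1e-12)
  expect_lt(max(abs(rn$P_n + rn$Ups_n)), 1e-12)
})

test_that("linear part is homogeneous and mu is inert without catalyst", {
  # with associations off and E = 0 every term is linear
  p_lin <- default_parameters(alpha_Xi_c = 1e-6, alpha_Xi_n = 1e-9,
                              alpha_Ups_c = 1e-9, alpha_Ups_n = 1e-6)
  p_lin$alpha_Xi_c <- 0; p_lin$alpha_Xi_n <- 0
  p_lin$alpha_Ups_c <- 0; p_lin$alpha_Ups_n <- 0
  loc <- zeros_c(G_c = 0.7, F_c = 0.2, C_c = 0.5, Xi_c = 0.1, P_c = 0.4,
                 Ups_c = 0.3, Theta_c = 0.2)
  r1 <- cytoplasm_reaction_rates(loc, p_lin)
  loc2 <- lapply(loc, function(x) 2 * x)
  r2 <- cytoplasm_reaction_rates(loc2, p_lin)
  expect_equal(unlist(r2), 2 * unlist(r1), tolerance = 1e-12)

  # with E_c = 0 the catalytic enhancements cannot act
  p <- default_parameters()
  pa <- default_parameters(mu1 = 0.0, mu2 = 0.0)
  loc <- zeros_c(G_c = 1, F_c = 1, C_c = 1, Xi_c = 1, P_c = 1, Ups_c = 1,
                 Theta_c = 1, E_c = 0)
  expect_equal(cytoplasm_reaction_rates(loc, p),
               cytoplasm_reaction_rates(loc, pa))
})

test_that("negative or missing concentrations are rejected", {
  p <- default_parameters()
  expect_error(cytoplasm_reaction_rates(zeros_c(G_c = -0.1), p), "positivity")
  bad <- zeros_c(); bad$Theta_c <- NULL
  expect_error(cytoplasm_reaction_rates(bad, p), "Theta_c")
  expect_error(nucleus_reaction_rates(zeros_n(C_n = NaN), p), "finite")
})

test_that("compiled reaction step matches the exposed rate functions", {
  fx <- make_toy_domain(fixture_spec(seed = 3))
  dom <- fx$domain
  st <- make_random_state(dom, fixture_spec(seed = 3))
  # isolate reactions: no diffusion, no transfer
  p <- default_parameters()
  p$D[] <- 0
  for (b in c("beta_Pc", "beta_Pn", "beta_Cc", "beta_Cn", "beta_Xi_c",
              "beta_Ups_n")) p[[b]] <- 0
  dt <- 0.01
  out <- step_state(st, dom, p, solver_config(dt = dt))

  loc_c <- lapply(st$fields[cytoplasm_species()], function(m) m[dom$cells_c])
  rc <- cytoplasm_reaction_rates(loc_c, p)
  for (sp in cytoplasm_species()) {
    expect_equal(out$fields[[sp]][dom$cells_c],
                 st$fields[[sp]][dom$cells_c] + dt * rc[[sp]],
                 tolerance = 1e-13)
  }
  loc_n <- lapply(st$fields[nucleus_species()], function(m) m[dom$cells_n])
  rn <- nucleus_reaction_rates(loc_n, p)
  for (sp in nucleus_species()) {
    expect_equal(out$fields[[sp]][dom$cells_n],
                 st$fields[[sp]][dom$cells_n] + dt * rn[[sp]],
                 tolerance = 1e-13)
  }
})
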