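# small, fast scenario setup shared below: 41-cell grid, short horizon
small_spec <- function(...) {
  scenario_spec(grid = 41, t_end = 40, snapshot_times = c(0, 40), ...)
}

test_that("degenerate all-zero kinetics leave the seed concentrations alone", {
  p <- default_parameters()
  p$D[] <- 0
  for (nm in nucactin:::scalar_param_names()) p[[nm]] <- 0
  seeds <- default_seed_concentrations()
  eq <- equilibrate(p, cell_geometry(), solver_config(), nx = 41,
                    seed_conc = seeds, validate = FALSE)
  m <- stats::setNames(eq$averages$mean, eq$averages$species)
  expect_equal(m[names(seeds)], seeds, tolerance = 1e-12)
  expect_true(eq$converged)
})

test_that("baseline equilibrium is nuclear-enriched and near-stationary", {
  eq <- cached("eq41", equilibrate(default_parameters(), cell_geometry(),
                                   solver_config(), nx = 41))
  g <- glance(eq)
  expect_true(g$converged)
  expect_gt(g$mean_Gn, g$mean_Gc)

  # re-equilibrating from the computed averages moves every average < 0.1%
  m <- stats::setNames(eq$averages$mean, eq$averages$species)
  eq2 <- equilibrate(default_parameters(), cell_geometry(), solver_config(),
                     nx = 41, seed_conc = m, ode_burnin = FALSE)
  m2 <- stats::setNames(eq2$averages$mean, eq2$averages$species)
  keep <- setdiff(nucactin_species(), "E_c")
  expect_lt(max(abs(m2[keep] - m[keep]) / pmax(m[keep], 1e-12)), 1e-3)
})

test_that("invalid parameters are refused before any integration", {
  p <- default_parameters(gamma_Ec = 1)
  expect_error(equilibrate(p, cell_geometry(), nx = 41), "constraints")
  st <- flat_state(toy_domain()$domain, default_seed_concentrations())
  expect_error(run_simulation(st, toy_domain()$domain, p), "constraints")
})

test_that("scenario runs are deterministic and schedule snapshots", {
  eq <- cached("eq41", equilibrate(default_parameters(), cell_geometry(),
                                   solver_config(), nx = 41))
  sp <- small_spec()
  r1 <- run_scenario(sp, equilibrium = eq)
  r2 <- run_scenario(sp, equilibrium = eq)
  expect_identical(r1$summary, r2$summary)
  expect_equal(vapply(r1$snapshots, function(s) s$t, numeric(1)), c(0, 40))
  # catalytic field installed on the cytoplasmic region only
  e0 <- r1$snapshots[[1]]$fields$E_c
  dom <- eq$domain
  expect_true(all(e0[dom$mask != 1L] == 0))
  expect_gt(sum(e0 > 0), 0)
})

test_that("pathway switches steer nuclear depletion as expected", {
  eq <- cached("eq41", equilibrate(default_parameters(), cell_geometry(),
                                   solver_config(), nx = 41))
  ko <- knockout_comparison(small_spec(), equilibrium = eq)
  d <- stats::setNames(ko$depletion, ko$scenario)

  expect_lt(abs(d[["neither"]]), 0.01)          # control stays put
  expect_gt(d[["both"]], 0.02)                  # catalysis depletes G_n
  expect_gt(d[["mu2_only"]], d[["mu1_only"]])   # phospho-pathway dominates
  expect_gte(d[["both"]], d[["mu2_only"]] - 1e-6)
  g <- glance(ko)
  expect_true(g$ordering_holds)
  expect_true(g$control_near_zero)
})

test_that("relocating the catalytic region weakens depletion", {
  eq <- cached("eq41", equilibrate(default_parameters(), cell_geometry(),
                                   solver_config(), nx = 41))
  rel <- relocation_comparison(small_spec(), equilibrium = eq)
  expect_equal(rel$distance[1], 0)
  expect_identical(nrow(rel), 3L)
  expect_lt(rel$depletion[nrow(rel)], rel$depletion[1])
  # rows are keyed by distance and reproducible
  rel2 <- relocation_comparison(small_spec(), equilibrium = eq,
                                distances = rel$distance)
  expect_identical(tidy(rel), tidy(rel2))
})

test_that("scenario bookkeeping rejects inconsistent setups", {
  expect_error(scenario_spec(t_end = 10, snapshot_times = c(0, 50)),
               "snapshot")
  eq <- cached("eq41", equilibrate(default_parameters(), cell_geometry(),
                                   solver_config(), nx = 41))
  sp <- small_spec(); sp$grid <- 61L
  expect_error(run_scenario(sp, equilibrium = eq), "resolution")
})
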