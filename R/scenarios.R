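#' Default seed concentrations for equilibration
#'
#' The starting pools from which the baseline (catalytic-factor-free) model
#' is relaxed to its equilibrium averages: one unit of total actin split
#' between free G-actin and F-actin, and free cofilin/profilin pools, with
#' the bound complexes and phospho-cofilin starting empty. Equilibration
#' redistributes these; only the conserved-group totals they imply matter.
#'
#' @return Named numeric vector over [nucactin_species()] (E_c fixed at 0).
#' @export
default_seed_concentrations <- function() {
  c(G_c = 0.3, F_c = 0.3, C_c = 0.6, Xi_c = 0, P_c = 0.6, Ups_c = 0,
    Theta_c = 0, E_c = 0,
    G_n = 0.3, C_n = 0.6, Xi_n = 0, P_n = 0.6, Ups_n = 0)
}

# well-mixed two-compartment ODE over compartment averages, used as a cheap
# burn-in before the spatial polish; membrane terms use the discrete
# perimeter/area measures of the target domain
wellmixed_derivs <- function(t, y, parms) {
  p <- parms$params
  geomf <- parms$geomf   # list(Lc = perim/area_c, Ln = perim/area_n)
  cy <- as.list(y[cytoplasm_species()])
  nu <- as.list(y[nucleus_species()])
  dcy <- cytoplasm_reaction_rates(cy, p, ec_decay_order = parms$ec_order)
  dnu <- nucleus_reaction_rates(nu, p)
  d <- c(unlist(dcy[1, ]), unlist(dnu[1, ]))
  names(d) <- nucactin_species()
  fluxP  <- p$beta_Pc * cy$P_c - p$beta_Pn * nu$P_n
  fluxC  <- p$beta_Cc * cy$C_c - p$beta_Cn * nu$C_n
  fluxXi <- p$beta_Xi_c * cy$Xi_c
  fluxU  <- -p$beta_Ups_n * nu$Ups_n
  d["P_c"]   <- d["P_c"]   - geomf$Lc * fluxP
  d["P_n"]   <- d["P_n"]   + geomf$Ln * fluxP
  d["C_c"]   <- d["C_c"]   - geomf$Lc * fluxC
  d["C_n"]   <- d["C_n"]   + geomf$Ln * fluxC
  d["Xi_c"]  <- d["Xi_c"]  - geomf$Lc * fluxXi
  d["Xi_n"]  <- d["Xi_n"]  + geomf$Ln * fluxXi
  d["Ups_c"] <- d["Ups_c"] - geomf$Lc * fluxU
  d["Ups_n"] <- d["Ups_n"] + geomf$Ln * fluxU
  list(d[nucactin_species()])
}

#' Relax the baseline model to spatially constant initial conditions
#'
#' Runs the model without the catalytic factor (`E_c = 0` everywhere) until
#' the compartment average of every species changes by less than `tol` per
#' time unit (relative), then returns spatially constant fields at the
#' computed averages. Because the true equilibrium profiles are not flat,
#' the returned state is close to — but deliberately not exactly — a steady
#' state; scenario runs therefore do not start at steady state.
#'
#' A well-mixed two-compartment ODE burn-in (integrated with `deSolve`)
#' supplies the starting point of the spatial relaxation, which shortens the
#' polish phase without changing the result (the spatial run alone defines
#' convergence).
#'
#' @param params A valid `nucactin_params` object.
#' @param geom A [cell_geometry()].
#' @param cfg A [solver_config()]; its `dt` is used for the polish.
#' @param nx,ny Grid resolution used for the spatial relaxation.
#' @param domain Optional pre-built domain (overrides `nx`/`ny`).
#' @param seed_conc Named starting concentrations, see
#'   [default_seed_concentrations()].
#' @param tol Convergence tolerance: max relative change of any compartment
#'   average per unit time (default `1e-6`).
#' @param max_t Cap on the spatial relaxation time; reaching it without
#'   converging is an error (or a warning with `on_nonconverged = "warn"`),
#'   carrying the residual.
#' @param check_every Interval (time units) between convergence checks.
#' @param ode_burnin Use the well-mixed ODE burn-in (default TRUE).
#' @param on_nonconverged `"error"` (default) or `"warn"`.
#' @param validate Check the parameter constraints first (default TRUE;
#'   disable only for degenerate diagnostic runs such as all-zero rates,
#'   for which every state is an equilibrium).
#' @return An object of class `actin_equilibrium`: `state` (flat
#'   `field_state` at t = 0), `averages` (tibble), `converged`, `residual`
#'   (last observed max relative rate of change), `t_relaxed`.
#' @export
equilibrate <- function(params, geom = cell_geometry(), cfg = solver_config(),
                        nx = 101, ny = nx, domain = NULL,
                        seed_conc = default_seed_concentrations(),
                        tol = 1e-6, max_t = 4000, check_every = 5,
                        ode_burnin = TRUE,
                        on_nonconverged = c("error", "warn"),
                        validate = TRUE) {
  on_nonconverged <- match.arg(on_nonconverged)
  if (validate) {
    rep <- validate_parameters(params)
    if (!isTRUE(attr(rep, "pass"))) {
      stop("parameter set violates model constraints; see validate_parameters()",
           call. = FALSE)
    }
  }
  if (is.null(domain)) domain <- build_domain(geom, nx, ny)

  avgs <- seed_conc[nucactin_species()]
  avgs[is.na(avgs)] <- 0
  names(avgs) <- nucactin_species()
  avgs["E_c"] <- 0

  if (isTRUE(ode_burnin)) {
    geomf <- list(Lc = domain$perim_n / domain$area_c,
                  Ln = domain$perim_n / domain$area_n)
    sol <- deSolve::ode(
      y = avgs, times = c(0, 2000), func = wellmixed_derivs,
      parms = list(params = params, geomf = geomf, ec_order = cfg$ec_decay_order),
      method = "lsoda", rtol = 1e-10, atol = 1e-12)
    avgs <- sol[nrow(sol), nucactin_species()]
    avgs[avgs < 0] <- 0
    avgs["E_c"] <- 0
  }

  state <- flat_state(domain, avgs, t = 0)
  chunk_cfg <- solver_config(dt = cfg$dt, t_end = check_every,
                             output_every = max(1L, round(check_every / cfg$dt)),
                             positivity_tolerance = cfg$positivity_tolerance,
                             ec_decay_order = cfg$ec_decay_order)
  monitored <- setdiff(nucactin_species(), "E_c")
  t_done <- 0
  residual <- Inf
  converged <- FALSE
  old <- state_means(state, domain)[monitored]
  while (t_done < max_t) {
    state <- step_state(state, domain, params, chunk_cfg,
                        n_steps = round(check_every / cfg$dt))
    t_done <- t_done + check_every
    new <- state_means(state, domain)[monitored]
    residual <- max(abs(new - old) / (pmax(abs(new), 1e-12) * check_every))
    old <- new
    if (residual < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    msg <- sprintf(
      "equilibration did not reach tol = %g within max_t = %g (residual %g)",
      tol, max_t, residual)
    if (on_nonconverged == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }

  final <- state_means(state, domain)
  final["E_c"] <- 0
  structure(
    list(state = flat_state(domain, final, t = 0),
         averages = tibble::tibble(
           species = nucactin_species(),
           compartment = unname(species_compartment()[nucactin_species()]),
           mean = unname(final[nucactin_species()])),
         converged = converged, residual = residual, t_relaxed = t_done,
         domain = domain, params = params),
    class = "actin_equilibrium")
}

state_means <- function(state, domain) {
  a <- state_averages(state, domain)
  stats::setNames(a$mean, a$species)
}

#' @export
print.actin_equilibrium <- function(x, ...) {
  cat(sprintf("<actin_equilibrium> relaxed %g time units, residual %.3g (%s)\n",
              x$t_relaxed, x$residual,
              if (x$converged) "converged" else "NOT converged"))
  gn <- x$averages$mean[x$averages$species == "G_n"]
  gc <- x$averages$mean[x$averages$species == "G_c"]
  cat(sprintf("  mean G_n = %.4g, mean G_c = %.4g (ratio %.3g)\n",
              gn, gc, gn / gc))
  invisible(x)
}

#' Specification of one in-silico experiment
#'
#' @param name Scenario label.
#' @param mu1_active,mu2_active Whether the catalysed polymerization
#'   (`mu1`) and catalysed cofilin-phosphorylation (`mu2`) pathways are
#'   switched on; an inactive pathway has its `mu` set to zero while the
#'   catalytic field itself stays in place.
#' @param region_distance Distance of the catalytic region from the nuclear
#'   surface (0 = juxta-nuclear tangent placement), applied via
#'   [place_region_at_distance()].
#' @param t_end Duration (default 400 time units).
#' @param snapshot_times Times at which full fields are stored (default
#'   0, 50 and 400).
#' @param params,geom,cfg Model parameter set, geometry and solver
#'   configuration.
#' @param grid Grid resolution (cells per side).
#' @param seed Integer seed recorded with the run (the scenario itself is
#'   deterministic; the seed feeds any downstream sampling).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name = "full",
                          mu1_active = TRUE, mu2_active = TRUE,
                          region_distance = 0,
                          t_end = 400, snapshot_times = c(0, 50, 400),
                          params = default_parameters(),
                          geom = cell_geometry(),
                          cfg = solver_config(t_end = t_end),
                          grid = 201, seed = 1) {
  if (t_end < max(snapshot_times)) {
    stop("t_end must cover every snapshot time", call. = FALSE)
  }
  cfg$t_end <- t_end
  structure(list(name = name, mu1_active = mu1_active, mu2_active = mu2_active,
                 region_distance = region_distance, t_end = t_end,
                 snapshot_times = snapshot_times, params = params,
                 geom = geom, cfg = cfg, grid = as.integer(grid),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Run one in-silico experiment
#'
#' Builds the domain, relaxes the baseline model to flat initial conditions
#' (unless a pre-computed equilibrium is supplied), installs the localized
#' catalytic-factor field with the scenario's pathway switches, runs to
#' `t_end`, and reduces the trajectory to a compartment-level summary plus
#' field snapshots.
#'
#' @param spec A [scenario_spec()].
#' @param equilibrium Optional `actin_equilibrium` (reused across scenarios
#'   that share parameters, e.g. a knockout matrix). Its domain must match
#'   the spec's grid.
#' @param ... Passed on to [equilibrate()] when no equilibrium is given.
#' @return An object of class `actin_scenario`: the `actin_trajectory`
#'   fields plus `spec`, `depletion` (1 - mean G_n(t_end)/mean G_n(0)) and
#'   the equilibrium used.
#' @export
run_scenario <- function(spec, equilibrium = NULL, ...) {
  stopifnot(inherits(spec, "scenario_spec"))
  geom <- if (spec$region_distance > 0) {
    place_region_at_distance(spec$geom, spec$region_distance)
  } else spec$geom
  if (is.null(equilibrium)) {
    equilibrium <- equilibrate(spec$params, spec$geom, spec$cfg,
                               nx = spec$grid, ...)
  }
  domain <- equilibrium$domain
  if (domain$nx != spec$grid) {
    stop("equilibrium domain resolution does not match the scenario grid",
         call. = FALSE)
  }
  # relocation moves only p3, so the compartment discretization is unchanged
  state <- equilibrium$state
  state$fields[["E_c"]] <- initialize_catalytic_field(domain, geom)

  params <- spec$params
  if (!spec$mu1_active) params$mu1 <- 0
  if (!spec$mu2_active) params$mu2 <- 0

  traj <- run_simulation(state, domain, params, spec$cfg,
                         snapshot_times = spec$snapshot_times)
  s <- traj$summary
  traj$spec <- spec
  traj$equilibrium <- equilibrium
  traj$depletion <- 1 - s$mean_Gn[nrow(s)] / s$mean_Gn[1]
  class(traj) <- c("actin_scenario", class(traj))
  traj
}

#' @export
print.actin_scenario <- function(x, ...) {
  cat(sprintf("<actin_scenario> '%s' (mu1 %s, mu2 %s, d = %g)\n",
              x$spec$name,
              if (x$spec$mu1_active) "on" else "off",
              if (x$spec$mu2_active) "on" else "off",
              x$spec$region_distance))
  cat(sprintf("  nuclear G-actin depletion over %g time units: %.3f\n",
              x$spec$t_end, x$depletion))
  NextMethod()
}

#' Knockout matrix over the two catalysed pathways
#'
#' Runs the four scenarios {both pathways, polymerization only, cofilin
#' phosphorylation only, neither} from identical equilibrated initial
#' conditions and reports the nuclear G-actin depletion fraction
#' `1 - mean G_n(t_end) / mean G_n(0)` for each.
#'
#' @param base A [scenario_spec()] defining parameters, geometry, grid and
#'   duration.
#' @param equilibrium Optional pre-computed `actin_equilibrium`.
#' @param keep_runs Keep the four full scenario objects in the result
#'   (default FALSE stores summaries only).
#' @param ... Passed to [equilibrate()].
#' @return An object of class `actin_knockouts`: a tibble with one row per
#'   scenario (`scenario`, `mu1_active`, `mu2_active`, `depletion`) plus
#'   attributes.
#' @export
knockout_comparison <- function(base = scenario_spec(), equilibrium = NULL,
                                keep_runs = FALSE, ...) {
  if (is.null(equilibrium)) {
    equilibrium <- equilibrate(base$params, base$geom, base$cfg,
                               nx = base$grid, ...)
  }
  variants <- list(
    both     = c(TRUE, TRUE),
    mu1_only = c(TRUE, FALSE),
    mu2_only = c(FALSE, TRUE),
    neither  = c(FALSE, FALSE)
  )
  runs <- purrr::imap(variants, function(fl, nm) {
    sp <- base
    sp$name <- nm
    sp$mu1_active <- fl[1]
    sp$mu2_active <- fl[2]
    run_scenario(sp, equilibrium = equilibrium)
  })
  out <- tibble::tibble(
    scenario   = names(variants),
    mu1_active = vapply(variants, `[`, logical(1), 1),
    mu2_active = vapply(variants, `[`, logical(1), 2),
    depletion  = vapply(runs, function(r) r$depletion, numeric(1))
  )
  attr(out, "equilibrium") <- equilibrium
  attr(out, "summaries") <- purrr::map(runs, "summary")
  if (keep_runs) attr(out, "runs") <- runs
  class(out) <- c("actin_knockouts", class(out))
  out
}

#' @export
print.actin_knockouts <- function(x, ...) {
  NextMethod()
  d <- stats::setNames(x$depletion, x$scenario)
  cat(sprintf("ordering (phospho-pathway knockout dominance): %s\n",
              if (d[["mu2_only"]] > d[["mu1_only"]]) "holds" else "violated"))
  invisible(x)
}

#' Catalytic-region relocation experiment
#'
#' Runs the full model (both pathways active) with the catalytic region
#' placed at each requested distance from the nuclear surface and reports
#' the nuclear G-actin depletion fraction per distance. Region size and
#' level are held fixed so placement is the only manipulated variable, and
#' all runs share one equilibrated initial state (the baseline carries no
#' catalytic factor, so equilibrium is placement-independent).
#'
#' @param base A [scenario_spec()].
#' @param distances Distances to test; defaults to 0, half-way and the
#'   largest admissible distance (backed off by one grid spacing).
#' @param equilibrium Optional pre-computed `actin_equilibrium`.
#' @param ... Passed to [equilibrate()].
#' @return An object of class `actin_relocation`: tibble with `distance` and
#'   `depletion`.
#' @export
relocation_comparison <- function(base = scenario_spec(), distances = NULL,
                                  equilibrium = NULL, ...) {
  if (is.null(equilibrium)) {
    equilibrium <- equilibrate(base$params, base$geom, base$cfg,
                               nx = base$grid, ...)
  }
  if (is.null(distances)) {
    h <- equilibrium$domain$h
    d_max <- max_region_distance(base$geom, slack = h)
    distances <- c(0, 0.5, 1) * d_max
  }
  deltas <- vapply(distances, function(d) {
    sp <- base
    sp$name <- sprintf("relocated_d=%g", d)
    sp$mu1_active <- TRUE
    sp$mu2_active <- TRUE
    sp$region_distance <- d
    run_scenario(sp, equilibrium = equilibrium)$depletion
  }, numeric(1))
  out <- tibble::tibble(distance = distances, depletion = deltas)
  attr(out, "equilibrium") <- equilibrium
  class(out) <- c("actin_relocation", class(out))
  out
}

#' Robustness of the knockout ordering over sampled parameter sets
#'
#' Draws constraint-satisfying parameter sets and, for each, runs the two
#' single-pathway knockouts from that set's own equilibrated baseline,
#' recording whether the cofilin-phosphorylation knockout ordering
#' (depletion with only `mu2` active exceeding depletion with only `mu1`
#' active) holds. This screens the qualitative prediction, not its effect
#' size, so a shorter horizon and a relaxed equilibration tolerance are
#' used by default (see the package vignette for the protocol).
#'
#' @param base A [scenario_spec()] providing geometry, grid and solver
#'   settings.
#' @param n_sets Number of parameter sets (default 20).
#' @param seed Base seed; set `i` uses `seed * 1000 + i`.
#' @param ranges Sampling ranges, see [default_ranges()].
#' @param t_end Screening horizon (default 200 time units).
#' @param equil_tol,equil_max_t Equilibration settings for the screen.
#' @return An object of class `actin_robustness`: tibble with one row per
#'   set (`set`, `seed`, `depletion_mu1_only`, `depletion_mu2_only`,
#'   `ordering_holds`), attribute `fraction` = share of sets with the
#'   ordering intact.
#' @export
knockout_robustness <- function(base = scenario_spec(), n_sets = 20, seed = 1,
                                ranges = default_ranges(), t_end = 200,
                                equil_tol = 1e-5, equil_max_t = 600) {
  rows <- purrr::map(seq_len(n_sets), function(i) {
    set_seed <- as.integer(seed) * 1000L + i
    params <- sample_constrained_parameters(set_seed, ranges = ranges)
    sp <- base
    sp$params <- params
    sp$t_end <- t_end
    sp$cfg$t_end <- t_end
    sp$snapshot_times <- numeric(0)
    eq <- suppressWarnings(
      equilibrate(params, sp$geom, sp$cfg, nx = sp$grid,
                  tol = equil_tol, max_t = equil_max_t,
                  on_nonconverged = "warn"))
    sp1 <- sp; sp1$mu1_active <- TRUE;  sp1$mu2_active <- FALSE
    sp2 <- sp; sp2$mu1_active <- FALSE; sp2$mu2_active <- TRUE
    d1 <- run_scenario(sp1, equilibrium = eq)$depletion
    d2 <- run_scenario(sp2, equilibrium = eq)$depletion
    tibble::tibble(set = i, seed = set_seed,
                   depletion_mu1_only = d1, depletion_mu2_only = d2,
                   ordering_holds = d2 > d1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fraction") <- mean(out$ordering_holds)
  class(out) <- c("actin_robustness", class(out))
  out
}

#' @export
print.actin_robustness <- function(x, ...) {
  NextMethod()
  cat(sprintf("ordering holds in %.0f%% of sampled parameter sets\n",
              100 * attr(x, "fraction")))
  invisible(x)
}
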