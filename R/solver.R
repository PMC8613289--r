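#' Field state: the thirteen concentration fields at one time point
#'
#' Fields are stored as full-grid matrices that are zero outside their own
#' compartment. [flat_state()] builds the spatially constant state used as
#' the initial condition of every scenario.
#'
#' @param domain A [build_domain()] result.
#' @param values Named numeric vector/list of per-species levels (missing
#'   species default to 0).
#' @param t Model time attached to the state.
#' @return An object of class `field_state`: `fields` (named list of
#'   matrices) and `t`.
#' @export
flat_state <- function(domain, values = NULL, t = 0) {
  stopifnot(inherits(domain, "simulation_domain"))
  comp <- species_compartment()
  vals <- if (is.null(values)) list() else as.list(values)
  fields <- lapply(nucactin_species(), function(sp) {
    m <- matrix(0, domain$nx, domain$ny)
    lev <- if (!is.null(vals[[sp]])) vals[[sp]] else 0
    cells <- if (comp[[sp]] == "cytoplasm") domain$cells_c else domain$cells_n
    m[cells] <- lev
    m
  })
  names(fields) <- nucactin_species()
  structure(list(fields = fields, t = t), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> t = %g, %d species fields %d x %d\n",
              x$t, length(x$fields), nrow(x$fields[[1]]), ncol(x$fields[[1]])))
  invisible(x)
}

#' Compartment averages of a field state
#'
#' @param state A `field_state`.
#' @param domain The matching `simulation_domain`.
#' @return A tibble with `species`, `compartment`, `mean`.
#' @export
state_averages <- function(state, domain) {
  comp <- species_compartment()
  means <- vapply(nucactin_species(), function(sp) {
    cells <- if (comp[[sp]] == "cytoplasm") domain$cells_c else domain$cells_n
    mean(state$fields[[sp]][cells])
  }, numeric(1))
  tibble::tibble(species = nucactin_species(),
                 compartment = unname(comp[nucactin_species()]),
                 mean = unname(means))
}

#' Solver configuration
#'
#' @param dt Fixed time step in model time units (default 0.01).
#' @param t_end Simulated duration (default 400 time units).
#' @param output_every Steps between recorded summary rows (default 100,
#'   i.e. one row per time unit at the default `dt`).
#' @param positivity_tolerance Any field value falling below minus this
#'   threshold aborts the run; values between it and zero are clipped to
#'   zero and counted as clip events (which shipped runs must keep at zero).
#' @param ec_decay_order Decay law for the catalytic factor: `"zeroth"`
#'   (constant-rate, as the governing equation is written) or `"first"`
#'   (proportional to `E_c`); inert under the default `gamma_Ec = 0`.
#' @return A `solver_config` list.
#' @export
solver_config <- function(dt = 0.01, t_end = 400, output_every = 100,
                          positivity_tolerance = 1e-12,
                          ec_decay_order = c("zeroth", "first")) {
  ec_decay_order <- match.arg(ec_decay_order)
  stopifnot(dt > 0, t_end >= 0, output_every >= 1)
  structure(list(dt = dt, t_end = t_end,
                 output_every = as.integer(output_every),
                 positivity_tolerance = positivity_tolerance,
                 ec_decay_order = ec_decay_order),
            class = "solver_config")
}

#' One implicit diffusion update of a single field
#'
#' Backward-Euler diffusion within one compartment with no-flux closure on
#' all compartment edges, realised as dimension-split tridiagonal line
#' solves on the finite-volume grid. `D = 0` returns the field unchanged;
#' the update conserves the field's total exactly (unit column sums of the
#' line systems). Several steps can be taken at once with `n_steps`.
#'
#' @param field `nx` by `ny` matrix.
#' @param domain A [build_domain()] result.
#' @param compartment `"cytoplasm"` or `"nucleus"`.
#' @param D Diffusion coefficient (>= 0).
#' @param dt Time step.
#' @param n_steps Number of consecutive steps (default 1).
#' @return The updated field matrix.
#' @export
diffusion_step <- function(field, domain, compartment = c("cytoplasm", "nucleus"),
                           D, dt, n_steps = 1) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(domain, "simulation_domain"),
            is.matrix(field), nrow(field) == domain$nx, ncol(field) == domain$ny,
            D >= 0, dt > 0, n_steps >= 0)
  comp_code <- if (compartment == "cytoplasm") 1L else 2L
  out <- cpp_diffuse(as.numeric(field), as.integer(domain$mask),
                     domain$nx, domain$ny, comp_code, D, dt, domain$h,
                     as.integer(n_steps))
  matrix(out, domain$nx, domain$ny)
}

engine_params <- function(params) {
  params[scalar_param_names()]
}

run_engine <- function(state, domain, params, cfg, n_steps,
                       snapshot_steps = integer(0)) {
  cpp_run(unname(lapply(state$fields[nucactin_species()], as.numeric)),
          as.integer(domain$mask), domain$nx, domain$ny, domain$h,
          engine_params(params), as.numeric(params$D),
          cfg$dt, as.integer(n_steps), cfg$output_every,
          as.integer(snapshot_steps), cfg$positivity_tolerance,
          identical(cfg$ec_decay_order, "first"), state$t)
}

fields_from_engine <- function(raw, domain, t) {
  fields <- lapply(raw, function(v) matrix(v, domain$nx, domain$ny))
  names(fields) <- nucactin_species()
  structure(list(fields = fields, t = t), class = "field_state")
}

#' Advance the full model by one (or more) time steps
#'
#' Applies, in this order: explicit mass-action reaction increments,
#' explicit nuclear-envelope transfers, and implicit diffusion per species
#' (Lie splitting, each sub-step first-order in `dt`).
#'
#' @param state A `field_state`.
#' @param domain A [build_domain()] result.
#' @param params A valid `nucactin_params` object.
#' @param cfg A [solver_config()].
#' @param n_steps Number of steps (default 1).
#' @return The advanced `field_state`.
#' @export
step_state <- function(state, domain, params, cfg = solver_config(), n_steps = 1) {
  res <- run_engine(state, domain, params, cfg, n_steps)
  fields_from_engine(res$final_fields, domain, res$t_end)
}

#' Run the model over a time span and record a trajectory
#'
#' Integrates from `state$t` to `state$t + cfg$t_end`, recording a
#' compartment-level summary row every `cfg$output_every` steps and full
#' field snapshots at the requested times.
#'
#' @param state Initial `field_state`.
#' @param domain A [build_domain()] result.
#' @param params A valid `nucactin_params` object.
#' @param cfg A [solver_config()]; `cfg$t_end` sets the duration.
#' @param snapshot_times Model times (relative to `state$t`) at which to
#'   store full field states; must be multiples of `dt` within the run.
#' @return An object of class `actin_trajectory`: `summary` (tibble with
#'   columns `t`, `mean_Gn`, `mean_Gc`, `total_Fc`, `total_Theta_c` and the
#'   conserved-group totals), `snapshots` (list of `field_state`),
#'   `final_state`, `clip_events`, `limited_fluxes`.
#' @export
run_simulation <- function(state, domain, params, cfg = solver_config(),
                           snapshot_times = NULL) {
  stopifnot(inherits(state, "field_state"))
  rep <- validate_parameters(params)
  if (!isTRUE(attr(rep, "pass"))) {
    stop("parameter set violates model constraints; see validate_parameters()",
         call. = FALSE)
  }
  if (!check_transfer_stability(params, domain, cfg$dt)) {
    warning("explicit transfer stability margin exceeded: ",
            "max(beta) * dt / h >= 0.5", call. = FALSE)
  }
  n_steps <- round(cfg$t_end / cfg$dt)
  if (abs(n_steps * cfg$dt - cfg$t_end) > 1e-9 * max(1, cfg$t_end)) {
    stop("t_end must be a multiple of dt", call. = FALSE)
  }
  snap_steps <- integer(0)
  if (!is.null(snapshot_times)) {
    snap_steps <- round(snapshot_times / cfg$dt)
    if (any(abs(snap_steps * cfg$dt - snapshot_times) > 1e-9) ||
        any(snap_steps < 0) || any(snap_steps > n_steps)) {
      stop("snapshot_times must be multiples of dt within [0, t_end]",
           call. = FALSE)
    }
  }
  res <- run_engine(state, domain, params, cfg, n_steps, snap_steps)
  summary <- tibble::as_tibble(res$summary)
  snapshots <- Map(function(fl, tt) fields_from_engine(fl, domain, tt),
                   res$snapshots, res$snapshot_times)
  structure(
    list(summary = summary,
         snapshots = snapshots,
         final_state = fields_from_engine(res$final_fields, domain, res$t_end),
         clip_events = res$clip_events,
         limited_fluxes = res$limited_fluxes,
         domain = domain, params = params, cfg = cfg),
    class = "actin_trajectory")
}

#' @export
print.actin_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<actin_trajectory> t in [%g, %g], %d summary rows, %d snapshots\n",
              s$t[1], s$t[nrow(s)], nrow(s), length(x$snapshots)))
  cat(sprintf("  mean G_n: %.4g -> %.4g; mean G_c: %.4g -> %.4g\n",
              s$mean_Gn[1], s$mean_Gn[nrow(s)],
              s$mean_Gc[1], s$mean_Gc[nrow(s)]))
  dr <- conservation_drift(x)
  cat(sprintf("  max conserved-group drift: %.3g%%; clip events: %g; limited fluxes: %g\n",
              max(dr$drift_percent), x$clip_events, x$limited_fluxes))
  invisible(x)
}

#' Relative drift of the conserved-group totals over a trajectory
#'
#' @param traj An `actin_trajectory`.
#' @return A tibble with `group` and `drift_percent` (max |total(t) -
#'   total(0)| / total(0) * 100).
#' @export
conservation_drift <- function(traj) {
  s <- traj$summary
  groups <- c(actin = "total_actin", cofilin = "total_cofilin",
              profilin = "total_profilin", catalytic_factor = "total_E")
  drift <- vapply(groups, function(col) {
    v <- s[[col]]
    if (v[1] == 0) return(max(abs(v - v[1])) * 100)
    max(abs(v - v[1]) / abs(v[1])) * 100
  }, numeric(1))
  tibble::tibble(group = names(groups), drift_percent = unname(drift))
}
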