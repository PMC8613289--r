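the_config_cache <- new.env(parent = emptyenv())

default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "nucactin",
              mustWork = TRUE)
}

#' Load (and validate) a model configuration
#'
#' Reads a YAML configuration with blocks `parameters`, `geometry`,
#' `solver`, `equilibration` and `scenario`. Missing keys are filled from
#' the packaged defaults; unknown keys are an error naming the offending key
#' path, so a misspelt rate constant cannot silently fall back to its
#' default. The resulting parameter set must pass [validate_parameters()] or
#' the load fails with the validation report.
#'
#' @param path Path to a YAML file, or `NULL` for the packaged defaults.
#' @return An object of class `nucactin_config`: the merged configuration
#'   list, with `$parameters` additionally available via
#'   [default_parameters()] and the geometry via [config_geometry()].
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$solver$dt
load_config <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the_config_cache$default)) return(the_config_cache$default)
    raw <- yaml::read_yaml(default_config_path())
    merged <- raw
  } else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    defaults <- yaml::read_yaml(default_config_path())
    check_unknown_keys(raw, defaults, "")
    merged <- merge_config(defaults, raw)
  }

  params <- new_params(merged$parameters)
  rep <- validate_parameters(params)
  if (!isTRUE(attr(rep, "pass"))) {
    bad <- rep$check[!rep$pass]
    stop("configuration parameters violate model constraints: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  out <- structure(merged, class = "nucactin_config")
  if (is.null(path)) the_config_cache$default <- out
  out
}

check_unknown_keys <- function(x, ref, prefix) {
  if (!is.list(x) || !is.list(ref) || is.null(names(ref))) return(invisible())
  extra <- setdiff(names(x), names(ref))
  if (length(extra)) {
    stop("unknown configuration key: ",
         paste0(sub("^\\.", "", paste0(prefix, ".", extra)), collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(x)) {
    check_unknown_keys(x[[nm]], ref[[nm]], paste0(prefix, ".", nm))
  }
  invisible()
}

merge_config <- function(defaults, override) {
  if (!is.list(defaults) || !is.list(override) || is.null(names(defaults))) {
    return(override)
  }
  for (nm in names(override)) {
    defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]])
  }
  defaults
}

#' @rdname load_config
#' @param config A `nucactin_config`.
#' @export
config_geometry <- function(config = load_config()) {
  g <- config$geometry
  cell_geometry(p1 = g$p1, r1 = g$r1, p2 = g$p2, r2 = g$r2,
                p3 = g$p3, r3 = g$r3, Ec_init = g$Ec_init,
                xlim = g$xlim, ylim = g$ylim)
}

#' @rdname load_config
#' @export
config_solver <- function(config = load_config()) {
  s <- config$solver
  solver_config(dt = s$dt, t_end = s$t_end, output_every = s$output_every,
                positivity_tolerance = s$positivity_tolerance,
                ec_decay_order = s$ec_decay_order)
}

#' @rdname load_config
#' @export
config_scenario <- function(config = load_config()) {
  sc <- config$scenario
  scenario_spec(name = sc$name, mu1_active = sc$mu1_active,
                mu2_active = sc$mu2_active,
                region_distance = sc$region_distance,
                t_end = sc$t_end, snapshot_times = unlist(sc$snapshot_times),
                params = default_parameters(config = config),
                geom = config_geometry(config),
                cfg = config_solver(config),
                grid = sc$grid, seed = sc$seed)
}

#' Write a configuration back to YAML
#'
#' @param config A `nucactin_config` (or plain nested list).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write / read a summary time series as CSV
#'
#' One row per recorded time with a fixed, documented column order (`t`,
#' `mean_Gn`, `mean_Gc`, `total_Fc`, `total_Theta_c`, `total_actin`,
#' `total_cofilin`, `total_profilin`, `total_E`); floats are written at full
#' round-trip precision.
#'
#' @param series Summary tibble (from an `actin_trajectory`).
#' @param path Output path.
#' @return `path` invisibly; `read_summary()` returns the tibble.
#' @export
write_summary <- function(series, path) {
  stopifnot(nrow(series) >= 1)
  cols <- c("t", "mean_Gn", "mean_Gc", "total_Fc", "total_Theta_c",
            "total_actin", "total_cofilin", "total_profilin", "total_E")
  readr::write_csv(series[, cols], path)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a gridded field snapshot
#'
#' Stores all thirteen fields, the compartment mask and the grid/model-time
#' attributes in one self-describing JSON container. Doubles are serialized
#' at full precision, so the read-back fields equal the written fields
#' exactly.
#'
#' @param state A `field_state`.
#' @param domain The matching `simulation_domain`.
#' @param path Output path (conventionally `.json`).
#' @return `path` invisibly; `read_snapshot()` returns a list with `state`
#'   (a `field_state`), `mask`, `h`, `nx`, `ny`, `xlim`, `ylim`.
#' @export
write_snapshot <- function(state, domain, path) {
  stopifnot(inherits(state, "field_state"),
            inherits(domain, "simulation_domain"))
  obj <- list(
    container = "nucactin_snapshot",
    version = 1L,
    model_time = state$t,
    nx = domain$nx, ny = domain$ny, h = domain$h,
    xlim = domain$xlim, ylim = domain$ylim,
    mask = as.integer(domain$mask),
    fields = lapply(state$fields, as.numeric)
  )
  # I(17) = 17 significant digits, enough to round-trip any double exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "nucactin_snapshot")) {
    stop("not a nucactin snapshot container: ", path, call. = FALSE)
  }
  nx <- obj$nx; ny <- obj$ny
  fields <- lapply(obj$fields, function(v) matrix(v, nx, ny))
  list(
    state = structure(list(fields = fields, t = obj$model_time),
                      class = "field_state"),
    mask = matrix(as.integer(obj$mask), nx, ny),
    nx = nx, ny = ny, h = obj$h,
    xlim = obj$xlim, ylim = obj$ylim
  )
}

#' Write a run manifest
#'
#' Records everything needed to re-execute a run bit-identically on the same
#' platform: the full configuration echo, package version, seed, model time
#' span, conservation-drift summary and the clip/flux-limit counters.
#'
#' @param path Output JSON path.
#' @param config Configuration list echoed into the manifest.
#' @param seed Integer seed.
#' @param traj Optional `actin_trajectory` supplying time span, drift and
#'   counters.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed = NA_integer_, traj = NULL,
                           extra = list()) {
  man <- list(
    package = "nucactin",
    version = as.character(utils::packageVersion("nucactin")),
    seed = seed,
    config = unclass(config)
  )
  if (!is.null(traj)) {
    s <- traj$summary
    man$t_start <- s$t[1]
    man$t_end <- s$t[nrow(s)]
    man$conservation_drift_percent <- stats::setNames(
      as.list(conservation_drift(traj)$drift_percent),
      conservation_drift(traj)$group)
    man$clip_events <- traj$clip_events
    man$limited_fluxes <- traj$limited_fluxes
  }
  man <- utils::modifyList(man, extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
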