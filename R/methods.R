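#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for simulation results
#'
#' `tidy()` returns the result in long format; `glance()` a one-row summary.
#'
#' @param x An `actin_trajectory`, `actin_knockouts`, `actin_relocation`,
#'   `actin_robustness` or `actin_equilibrium` object.
#' @param ... Unused.
#' @return A tibble.
#' @name nucactin-tidiers
NULL

#' @rdname nucactin-tidiers
#' @exportS3Method generics::tidy
tidy.actin_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$summary, -"t",
                      names_to = "quantity", values_to = "value")
}

#' @rdname nucactin-tidiers
#' @exportS3Method generics::glance
glance.actin_trajectory <- function(x, ...) {
  s <- x$summary
  dr <- conservation_drift(x)
  tibble::tibble(
    t_start = s$t[1],
    t_end = s$t[nrow(s)],
    depletion = 1 - s$mean_Gn[nrow(s)] / s$mean_Gn[1],
    mean_Gn_start = s$mean_Gn[1],
    mean_Gn_end = s$mean_Gn[nrow(s)],
    mean_Gc_start = s$mean_Gc[1],
    mean_Gc_end = s$mean_Gc[nrow(s)],
    max_drift_percent = max(dr$drift_percent),
    clip_events = x$clip_events,
    limited_fluxes = x$limited_fluxes
  )
}

#' @rdname nucactin-tidiers
#' @exportS3Method generics::tidy
tidy.actin_knockouts <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname nucactin-tidiers
#' @exportS3Method generics::glance
glance.actin_knockouts <- function(x, ...) {
  d <- stats::setNames(x$depletion, x$scenario)
  tibble::tibble(
    depletion_both = d[["both"]],
    depletion_mu1_only = d[["mu1_only"]],
    depletion_mu2_only = d[["mu2_only"]],
    depletion_neither = d[["neither"]],
    ordering_holds = d[["mu2_only"]] > d[["mu1_only"]],
    control_near_zero = abs(d[["neither"]]) < 0.01
  )
}

#' @rdname nucactin-tidiers
#' @exportS3Method generics::tidy
tidy.actin_relocation <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname nucactin-tidiers
#' @exportS3Method generics::glance
glance.actin_relocation <- function(x, ...) {
  tibble::tibble(
    depletion_tangent = x$depletion[which.min(x$distance)],
    depletion_farthest = x$depletion[which.max(x$distance)],
    mobilization_reduced = x$depletion[which.max(x$distance)] <
      x$depletion[which.min(x$distance)]
  )
}

#' @rdname nucactin-tidiers
#' @exportS3Method generics::tidy
tidy.actin_robustness <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname nucactin-tidiers
#' @exportS3Method generics::glance
glance.actin_robustness <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x),
    fraction_ordering_holds = attr(x, "fraction")
  )
}

#' @rdname nucactin-tidiers
#' @exportS3Method generics::tidy
tidy.actin_equilibrium <- function(x, ...) {
  x$averages
}

#' @rdname nucactin-tidiers
#' @exportS3Method generics::glance
glance.actin_equilibrium <- function(x, ...) {
  m <- stats::setNames(x$averages$mean, x$averages$species)
  tibble::tibble(
    mean_Gn = m[["G_n"]],
    mean_Gc = m[["G_c"]],
    gn_gc_ratio = m[["G_n"]] / m[["G_c"]],
    converged = x$converged,
    residual = x$residual,
    t_relaxed = x$t_relaxed
  )
}

#' Plot a summary trajectory
#'
#' Time courses of mean nuclear and cytoplasmic G-actin, total F-actin and
#' total phospho-cofilin, each normalized to its initial value so the four
#' panels share a scale.
#'
#' @param object An `actin_trajectory` (or `actin_scenario`).
#' @param normalize Divide each series by its value at the first recorded
#'   time (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.actin_trajectory <- function(object, normalize = TRUE, ...) {
  keep <- c("mean_Gn", "mean_Gc", "total_Fc", "total_Theta_c")
  labels <- c(mean_Gn = "nuclear G-actin",
              mean_Gc = "cytoplasmic G-actin",
              total_Fc = "F-actin (total)",
              total_Theta_c = "phospho-cofilin (total)")
  df <- tidy(object)
  df <- df[df$quantity %in% keep, ]
  if (normalize) {
    df <- dplyr::mutate(
      dplyr::group_by(df, .data$quantity),
      value = .data$value / .data$value[1])
    df <- dplyr::ungroup(df)
  }
  df$quantity <- labels[df$quantity]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (model units)",
                  y = if (normalize) "level (relative to t = 0)" else "level",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.actin_trajectory
#' @exportS3Method ggplot2::autoplot
autoplot.actin_knockouts <- function(object, ...) {
  df <- tidy(object)
  df$scenario <- factor(df$scenario,
                        levels = c("both", "mu2_only", "mu1_only", "neither"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$depletion)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "nuclear G-actin depletion fraction") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.actin_trajectory
#' @exportS3Method ggplot2::autoplot
autoplot.actin_relocation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$depletion)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "catalytic-region distance from nuclear surface",
                  y = "nuclear G-actin depletion fraction") +
    ggplot2::theme_minimal()
}

#' Render a G-actin field snapshot
#'
#' Combines nuclear and cytoplasmic G-actin into one field (each species on
#' its own compartment) and renders it with the viridis colour mapping;
#' exterior cells are blank. Fixed colour limits make stills from different
#' times directly comparable.
#'
#' @param state A `field_state`.
#' @param domain The matching `simulation_domain`.
#' @param limits Optional fixed colour limits `c(lo, hi)`.
#' @param species Species to render; the default overlays `G_c` and `G_n`.
#' @return A ggplot object.
#' @export
plot_snapshot <- function(state, domain, limits = NULL,
                          species = c("G_c", "G_n")) {
  stopifnot(inherits(state, "field_state"),
            inherits(domain, "simulation_domain"))
  combined <- Reduce(`+`, state$fields[species])
  df <- tidyr::expand_grid(iy = seq_len(domain$ny), ix = seq_len(domain$nx))
  df$x <- domain$x[df$ix]
  df$y <- domain$y[df$iy]
  df$value <- combined[cbind(df$ix, df$iy)]
  df$value[domain$mask[cbind(df$ix, df$iy)] == 0L] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = limits, na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "G-actin",
                  title = sprintf("t = %g", state$t)) +
    ggplot2::theme_void()
}
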