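#' Kinetic and transport parameters of the actin-shuttling model
#'
#' Bundles every rate constant, diffusion coefficient and nuclear-envelope
#' transfer coefficient of the model. All quantities are in the model's
#' arbitrary units (concentration, length and "time units"); no unit
#' conversion is performed anywhere in the package.
#'
#' The fields are:
#' \describe{
#'   \item{gamma_Gc, gamma_Fc}{basal G-to-F polymerization and F-to-G
#'     depolymerization rates (1/time). Polymerization is catalytically
#'     enhanced to `gamma_Gc * (1 + mu1 * E_c)` where the catalytic factor is
#'     present.}
#'   \item{alpha_Xi_c, gamma_Xi_c}{cytoplasmic cofilin--actin association
#'     (1/(conc time)) and dissociation (1/time).}
#'   \item{alpha_Theta_c, gamma_Theta_c}{cofilin phosphorylation and
#'     dephosphorylation rates (1/time); phosphorylation is enhanced to
#'     `alpha_Theta_c * (1 + mu2 * E_c)`.}
#'   \item{alpha_Ups_c, gamma_Ups_c}{cytoplasmic profilin--actin association
#'     and dissociation.}
#'   \item{alpha_Xi_n, gamma_Xi_n, alpha_Ups_n, gamma_Ups_n}{the nuclear
#'     counterparts.}
#'   \item{mu1, mu2}{dimensionless catalytic enhancement factors per unit of
#'     catalytic factor for polymerization and cofilin phosphorylation.}
#'   \item{gamma_Ec}{catalytic-factor decay rate; the model assumes a
#'     conserved catalytic factor, i.e. 0.}
#'   \item{D}{named numeric vector of 13 diffusion coefficients
#'     (length^2/time), one per species in [nucactin_species()] order.
#'     F-actin and the catalytic factor are non-diffusing.}
#'   \item{beta_Pc, beta_Pn, beta_Cc, beta_Cn, beta_Xi_c, beta_Ups_n}{membrane
#'     transfer coefficients (length/time): profilin and cofilin exchange
#'     bidirectionally, cofilin-actin crosses one-way into the nucleus,
#'     profilin-actin one-way into the cytoplasm.}
#' }
#'
#' @param ... Named overrides of individual fields. `D` may be given as a
#'   full named vector or as a named list/vector of partial overrides.
#' @param config Optional configuration list (as produced by [load_config()])
#'   whose `parameters` block supplies the base values; defaults to the
#'   packaged default configuration.
#' @return An object of class `nucactin_params` (a named list).
#' @seealso [validate_parameters()], [sample_constrained_parameters()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$beta_Xi_c
#' validate_parameters(p)
default_parameters <- function(..., config = NULL) {
  cfg <- if (is.null(config)) load_config() else config
  p <- cfg$parameters
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), c(scalar_param_names(), "D"))
    if (length(bad)) {
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (!is.null(dots$D)) {
      Dnew <- unlist(dots$D)
      bad_sp <- setdiff(names(Dnew), nucactin_species())
      if (length(bad_sp)) {
        stop("unknown species in D override: ", paste(bad_sp, collapse = ", "),
             call. = FALSE)
      }
      p$D[names(Dnew)] <- Dnew
      dots$D <- NULL
    }
    p[names(dots)] <- dots
  }
  new_params(p)
}

scalar_param_names <- function() {
  c("gamma_Gc", "gamma_Fc",
    "alpha_Xi_c", "gamma_Xi_c", "alpha_Xi_n", "gamma_Xi_n",
    "alpha_Ups_c", "gamma_Ups_c", "alpha_Ups_n", "gamma_Ups_n",
    "alpha_Theta_c", "gamma_Theta_c",
    "mu1", "mu2", "gamma_Ec",
    "beta_Pc", "beta_Pn", "beta_Cc", "beta_Cn", "beta_Xi_c", "beta_Ups_n")
}

new_params <- function(p) {
  needed <- c(scalar_param_names(), "D")
  missing <- setdiff(needed, names(p))
  if (length(missing)) {
    stop("parameter set is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in scalar_param_names()) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter field '", nm, "' must be a single finite number",
           call. = FALSE)
    }
    p[[nm]] <- as.numeric(v)
  }
  D <- unlist(p$D)
  miss_d <- setdiff(nucactin_species(), names(D))
  if (length(miss_d)) {
    stop("diffusion map D is missing species: ", paste(miss_d, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(D))) {
    bad <- names(D)[!is.finite(D)][1L]
    stop("diffusion coefficient for '", bad, "' is not finite", call. = FALSE)
  }
  p$D <- D[nucactin_species()]
  structure(p[c(scalar_param_names(), "D")], class = "nucactin_params")
}

#' @export
print.nucactin_params <- function(x, ...) {
  cat("<nucactin_params>\n")
  sc <- unlist(x[scalar_param_names()])
  cat("  rates/transfer:\n")
  print(sc)
  cat("  diffusion coefficients:\n")
  print(x$D)
  rep_ok <- attr(validate_parameters(x), "pass")
  cat(if (isTRUE(rep_ok)) "  all constraints satisfied\n"
      else "  CONSTRAINT VIOLATIONS present (see validate_parameters())\n")
  invisible(x)
}

#' Validate a parameter set against the model's structural constraints
#'
#' Checks every inequality and structural assumption the model places on its
#' parameters: non-negativity, non-diffusing F-actin and catalytic factor,
#' conservation of the catalytic factor, the cytoplasm/nucleus asymmetries of
#' the cofilin and profilin association/dissociation rates, symmetric
#' cofilin and profilin transfer, cofilin-actin import outpacing
#' profilin-actin export, and nuclear diffusion coefficients exceeding their
#' cytoplasmic counterparts (so nuclear profiles stay comparatively flat).
#'
#' @param params A `nucactin_params` object.
#' @param margin Minimum margin by which strict inequalities must hold
#'   (default `1e-9`), guarding against degenerate equality sets.
#' @return A tibble with one row per check (`check`, `pass`, `detail`) and an
#'   attribute `pass` that is `TRUE` iff every check passed. The input is
#'   never modified.
#' @export
#' @examples
#' rep <- validate_parameters(default_parameters())
#' attr(rep, "pass")
validate_parameters <- function(params, margin = 1e-9) {
  if (!inherits(params, "nucactin_params")) params <- new_params(params)
  p <- params
  all_vals <- c(unlist(p[scalar_param_names()]), p$D)

  checks <- list(
    list("non-negative rates",
         all(all_vals >= 0),
         "every rate, transfer and diffusion coefficient must be >= 0"),
    list("F-actin non-diffusing",
         p$D[["F_c"]] == 0,
         sprintf("D[F_c] = %g (must be 0)", p$D[["F_c"]])),
    list("catalytic factor non-diffusing",
         p$D[["E_c"]] == 0,
         sprintf("D[E_c] = %g (must be 0)", p$D[["E_c"]])),
    list("catalytic factor conserved",
         p$gamma_Ec == 0,
         sprintf("gamma_Ec = %g (must be 0)", p$gamma_Ec)),
    list("cytoplasmic cofilin-actin association faster",
         p$alpha_Xi_c > p$alpha_Xi_n + margin,
         sprintf("alpha_Xi_c = %g vs alpha_Xi_n = %g", p$alpha_Xi_c, p$alpha_Xi_n)),
    list("nuclear cofilin-actin dissociation faster",
         p$gamma_Xi_n > p$gamma_Xi_c + margin,
         sprintf("gamma_Xi_n = %g vs gamma_Xi_c = %g", p$gamma_Xi_n, p$gamma_Xi_c)),
    list("nuclear profilin-actin association faster",
         p$alpha_Ups_n > p$alpha_Ups_c + margin,
         sprintf("alpha_Ups_n = %g vs alpha_Ups_c = %g", p$alpha_Ups_n, p$alpha_Ups_c)),
    list("cytoplasmic profilin-actin dissociation faster",
         p$gamma_Ups_c > p$gamma_Ups_n + margin,
         sprintf("gamma_Ups_c = %g vs gamma_Ups_n = %g", p$gamma_Ups_c, p$gamma_Ups_n)),
    list("cofilin transfer symmetry",
         p$beta_Cc == p$beta_Cn,
         sprintf("beta_Cc = %g vs beta_Cn = %g", p$beta_Cc, p$beta_Cn)),
    list("profilin transfer symmetry",
         p$beta_Pc == p$beta_Pn,
         sprintf("beta_Pc = %g vs beta_Pn = %g", p$beta_Pc, p$beta_Pn)),
    list("import outpaces export",
         p$beta_Xi_c > p$beta_Ups_n + margin,
         sprintf("beta_Xi_c = %g vs beta_Ups_n = %g", p$beta_Xi_c, p$beta_Ups_n))
  )
  for (pair in shuttling_pairs()) {
    checks[[length(checks) + 1L]] <- list(
      paste0("nuclear diffusion dominance (", pair[[1]], ")"),
      p$D[[pair[2]]] > p$D[[pair[1]]] + margin,
      sprintf("D[%s] = %g vs D[%s] = %g",
              pair[2], p$D[[pair[2]]], pair[1], p$D[[pair[1]]]))
  }

  out <- tibble::tibble(
    check  = vapply(checks, function(x) x[[1]], character(1)),
    pass   = vapply(checks, function(x) isTRUE(x[[2]]), logical(1)),
    detail = vapply(checks, function(x) x[[3]], character(1))
  )
  attr(out, "pass") <- all(out$pass)
  class(out) <- c("nucactin_validation", class(out))
  out
}

#' @export
print.nucactin_validation <- function(x, ...) {
  NextMethod()
  cat(if (isTRUE(attr(x, "pass"))) "All constraints satisfied.\n"
      else paste0(sum(!x$pass), " constraint(s) violated.\n"))
  invisible(x)
}

#' Export a validation report as JSON
#'
#' @param report A report from [validate_parameters()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "nucactin_validation"))
  jsonlite::write_json(
    list(pass = isTRUE(attr(report, "pass")),
         checks = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default sampling ranges for constraint-satisfying parameter sets
#'
#' One interval per tunable parameter, roughly a factor of two around the
#' shipped defaults. Intervals for the paired, inequality-constrained rates
#' are disjoint so that any draw satisfies the constraints by construction;
#' the symmetric transfer coefficients are drawn once and mirrored; diffusion
#' coefficients are drawn as a cytoplasmic base value and a nucleus-to-
#' cytoplasm ratio in `[5, 20]`.
#'
#' @return A named list of `c(min, max)` intervals.
#' @export
default_ranges <- function() {
  list(
    gamma_Gc      = c(0.1, 0.4),
    gamma_Fc      = c(0.1, 0.4),
    alpha_Xi_c    = c(0.5, 2),
    alpha_Xi_n    = c(0.05, 0.2),
    gamma_Xi_c    = c(0.05, 0.2),
    gamma_Xi_n    = c(0.5, 2),
    alpha_Ups_c   = c(0.05, 0.2),
    alpha_Ups_n   = c(0.5, 2),
    gamma_Ups_c   = c(0.5, 2),
    gamma_Ups_n   = c(0.05, 0.2),
    alpha_Theta_c = c(0.025, 0.1),
    gamma_Theta_c = c(0.025, 0.1),
    mu1           = c(0.04, 0.16),
    mu2           = c(4, 16),
    beta_C        = c(0.005, 0.02),
    beta_P        = c(0.005, 0.02),
    beta_Xi_c     = c(0.01, 0.04),
    beta_Ups_n    = c(0.002, 0.008),
    D_cyt         = c(2.5e-3, 1e-2),
    D_ratio       = c(5, 20)
  )
}

#' Sample a constraint-satisfying parameter set
#'
#' Draws each parameter log-uniformly from its range and assembles a full
#' `nucactin_params` object that provably satisfies every constraint checked
#' by [validate_parameters()]: paired rates come from disjoint intervals,
#' symmetric transfer coefficients are drawn once, nuclear diffusion is the
#' cytoplasmic value times a ratio > 1, and F-actin/catalytic-factor
#' diffusion and `gamma_Ec` are pinned to zero. A rejection loop with a
#' documented cap guards against user-supplied ranges that make the
#' inequalities unsatisfiable.
#'
#' @param seed Integer seed; identical seeds give identical parameter sets
#'   and the caller's RNG state is left untouched.
#' @param ranges Named list of `c(min, max)` intervals, see [default_ranges()].
#' @param max_tries Maximum rejection-sampling attempts (default 1000).
#' @param margin Strictness margin passed to [validate_parameters()].
#' @return A valid `nucactin_params` object.
#' @export
#' @examples
#' p1 <- sample_constrained_parameters(seed = 1)
#' p2 <- sample_constrained_parameters(seed = 1)
#' identical(p1, p2)
sample_constrained_parameters <- function(seed, ranges = default_ranges(),
                                          max_tries = 1000, margin = 1e-9) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  needed <- names(default_ranges())
  missing <- setdiff(needed, names(ranges))
  if (length(missing)) {
    stop("ranges is missing interval(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in needed) {
    rg <- ranges[[nm]]
    if (length(rg) != 2L || any(!is.finite(rg)) || any(rg < 0) || rg[1] > rg[2])
      stop("invalid range for '", nm, "'", call. = FALSE)
  }

  draw <- function(nm) {
    rg <- ranges[[nm]]
    if (rg[1] == 0 || rg[2] == 0) return(stats::runif(1, rg[1], rg[2]))
    exp(stats::runif(1, log(rg[1]), log(rg[2])))
  }

  withr::with_seed(as.integer(seed), {
    for (try in seq_len(max_tries)) {
      p <- list(
        gamma_Gc      = draw("gamma_Gc"),
        gamma_Fc      = draw("gamma_Fc"),
        alpha_Xi_c    = draw("alpha_Xi_c"),
        gamma_Xi_c    = draw("gamma_Xi_c"),
        alpha_Xi_n    = draw("alpha_Xi_n"),
        gamma_Xi_n    = draw("gamma_Xi_n"),
        alpha_Ups_c   = draw("alpha_Ups_c"),
        gamma_Ups_c   = draw("gamma_Ups_c"),
        alpha_Ups_n   = draw("alpha_Ups_n"),
        gamma_Ups_n   = draw("gamma_Ups_n"),
        alpha_Theta_c = draw("alpha_Theta_c"),
        gamma_Theta_c = draw("gamma_Theta_c"),
        mu1           = draw("mu1"),
        mu2           = draw("mu2"),
        gamma_Ec      = 0
      )
      bC <- draw("beta_C"); bP <- draw("beta_P")
      p$beta_Cc <- bC; p$beta_Cn <- bC
      p$beta_Pc <- bP; p$beta_Pn <- bP
      p$beta_Xi_c  <- draw("beta_Xi_c")
      p$beta_Ups_n <- draw("beta_Ups_n")
      Dc <- draw("D_cyt")
      Dn <- Dc * draw("D_ratio")
      D <- stats::setNames(rep(Dc, 13L), nucactin_species())
      D[nucleus_species()] <- Dn
      D[c("F_c", "E_c")] <- 0
      p$D <- D
      params <- new_params(p)
      rep <- validate_parameters(params, margin = margin)
      if (isTRUE(attr(rep, "pass"))) return(params)
    }
  })
  stop("no constraint-satisfying parameter set found after ", max_tries,
       " attempts; the supplied ranges make the inequalities unsatisfiable",
       call. = FALSE)
}
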