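#' Pointwise reaction source terms
#'
#' The non-diffusive right-hand sides of the governing equations, evaluated
#' cell-locally. In the cytoplasm: G-actin polymerizes to F-actin at rate
#' `gamma_Gc * (1 + mu1 * E_c)` and F-actin depolymerizes at `gamma_Fc`;
#' cofilin and profilin reversibly bind G-actin (mass action); cofilin is
#' phosphorylated at `alpha_Theta_c * (1 + mu2 * E_c)` and phospho-cofilin
#' dephosphorylated at `gamma_Theta_c`; the catalytic factor decays at
#' `gamma_Ec` (zeroth order as the model writes it, or first order via
#' `ec_decay_order`; inert under the model's assumption `gamma_Ec = 0`).
#' In the nucleus only the two reversible binding reactions occur — no
#' polymerization and no phosphorylation.
#'
#' Reactions conserve total actin, total cofilin and total profilin
#' pointwise; this cancellation is the module's primary test surface.
#'
#' @param local Named list, data frame or named numeric vector of local
#'   concentrations; must contain every species of the compartment
#'   ([cytoplasm_species()] or [nucleus_species()]). Values may be vectors
#'   (one entry per cell).
#' @param params A `nucactin_params` object.
#' @param ec_decay_order `"zeroth"` (as the governing equation is written) or
#'   `"first"` (decay proportional to `E_c`).
#' @return A tibble of rate-of-change contributions, one column per species
#'   of the compartment.
#' @export
#' @examples
#' p <- default_parameters()
#' cytoplasm_reaction_rates(
#'   list(G_c = 1, F_c = 0, C_c = 0, Xi_c = 0, P_c = 0, Ups_c = 0,
#'        Theta_c = 0, E_c = 0), p)
cytoplasm_reaction_rates <- function(local, params,
                                     ec_decay_order = c("zeroth", "first")) {
  ec_decay_order <- match.arg(ec_decay_order)
  v <- check_local(local, cytoplasm_species())
  p <- params
  pol  <- p$gamma_Gc * (1 + p$mu1 * v$E_c) * v$G_c
  dep  <- p$gamma_Fc * v$F_c
  aXi  <- p$alpha_Xi_c * v$G_c * v$C_c
  dXi  <- p$gamma_Xi_c * v$Xi_c
  aU   <- p$alpha_Ups_c * v$G_c * v$P_c
  dU   <- p$gamma_Ups_c * v$Ups_c
  ph   <- p$alpha_Theta_c * (1 + p$mu2 * v$E_c) * v$C_c
  deph <- p$gamma_Theta_c * v$Theta_c
  dEc  <- if (ec_decay_order == "zeroth") {
    rep(-p$gamma_Ec, length(v$E_c))
  } else {
    -p$gamma_Ec * v$E_c
  }
  tibble::tibble(
    G_c     = dep - pol + dXi - aXi + dU - aU,
    F_c     = pol - dep,
    C_c     = dXi - aXi - ph + deph,
    Xi_c    = aXi - dXi,
    P_c     = dU - aU,
    Ups_c   = aU - dU,
    Theta_c = ph - deph,
    E_c     = dEc
  )
}

#' @rdname cytoplasm_reaction_rates
#' @export
nucleus_reaction_rates <- function(local, params) {
  v <- check_local(local, nucleus_species())
  p <- params
  aXi <- p$alpha_Xi_n * v$G_n * v$C_n
  dXi <- p$gamma_Xi_n * v$Xi_n
  aU  <- p$alpha_Ups_n * v$G_n * v$P_n
  dU  <- p$gamma_Ups_n * v$Ups_n
  tibble::tibble(
    G_n  = dXi - aXi + dU - aU,
    C_n  = dXi - aXi,
    Xi_n = aXi - dXi,
    P_n  = dU - aU,
    Ups_n = aU - dU
  )
}

check_local <- function(local, species) {
  local <- as.list(local)
  missing <- setdiff(species, names(local))
  if (length(missing)) {
    stop("local state is missing species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- local[species]
  lens <- lengths(v)
  if (length(unique(lens[lens > 1L])) > 1L) {
    stop("species concentration vectors have inconsistent lengths",
         call. = FALSE)
  }
  for (nm in species) {
    x <- v[[nm]]
    if (!is.numeric(x) || any(!is.finite(x))) {
      stop("concentration of '", nm, "' must be finite numeric", call. = FALSE)
    }
    if (any(x < 0)) {
      stop("negative concentration of '", nm,
           "' (solver positivity breach)", call. = FALSE)
    }
  }
  n <- max(lens)
  lapply(v, function(x) if (length(x) == n) x else rep(x, length.out = n))
}
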