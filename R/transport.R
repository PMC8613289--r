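#' Nuclear-envelope transfer table
#'
#' One flux law per species present on either side of the nuclear boundary:
#' profilin and cofilin exchange bidirectionally (first-order in the
#' concentration on each side), cofilin-actin is carried one-way into the
#' nucleus (the importin route), profilin-actin one-way into the cytoplasm
#' (the export route), and G-actin, F-actin, phospho-cofilin and the
#' catalytic factor do not cross at all. G-actin itself never crosses the
#' envelope directly — it shuttles only as part of the two carrier
#' complexes.
#'
#' @param params A `nucactin_params` object supplying the transfer
#'   coefficients.
#' @return A tibble with columns `species`, `type` (one of `bidirectional`,
#'   `one_way_into_nucleus`, `one_way_into_cytoplasm`, `no_flux`),
#'   `beta_out` (cytoplasm-side coefficient) and `beta_in` (nucleus-side).
#' @export
transfer_spec <- function(params) {
  stopifnot(inherits(params, "nucactin_params"))
  tibble::tibble(
    species  = c("P", "C", "Xi", "Ups", "G", "F", "Theta", "E"),
    type     = c("bidirectional", "bidirectional", "one_way_into_nucleus",
                 "one_way_into_cytoplasm", "no_flux", "no_flux", "no_flux",
                 "no_flux"),
    beta_out = c(params$beta_Pc, params$beta_Cc, params$beta_Xi_c, 0, 0, 0, 0, 0),
    beta_in  = c(params$beta_Pn, params$beta_Cn, 0, params$beta_Ups_n,
                 0, 0, 0, 0)
  )
}

#' Signed transfer flux density across a nuclear face
#'
#' Flux density (amount per face length per time) for one species at one
#' point of the nuclear boundary; positive values flow into the nucleus.
#' Bidirectional species: `beta_out * c_cyt - beta_in * c_nuc`. Cofilin-actin:
#' `beta_Xi_c * c_cyt` regardless of the nuclear side. Profilin-actin:
#' `-beta_Ups_n * c_nuc` regardless of the cytoplasmic side. No-flux
#' species: 0. The same magnitude leaves one compartment and enters the
#' other.
#'
#' @param species One of `"P"`, `"C"`, `"Xi"`, `"Ups"`, `"G"`, `"F"`,
#'   `"Theta"`, `"E"`.
#' @param c_cyt,c_nuc Concentrations on the cytoplasmic and nuclear side
#'   (vectors allowed, recycled to common length).
#' @param spec A [transfer_spec()] table.
#' @return Numeric vector of signed flux densities.
#' @export
#' @examples
#' p <- default_parameters()
#' sp <- transfer_spec(p)
#' nuclear_face_flux("Ups", c_cyt = 0, c_nuc = 2, sp)
nuclear_face_flux <- function(species, c_cyt, c_nuc, spec) {
  stopifnot(is.character(species), length(species) == 1L)
  row <- spec[spec$species == species, ]
  if (nrow(row) != 1L) {
    stop("unknown species '", species, "' in transfer table", call. = FALSE)
  }
  if (any(c_cyt < 0) || any(c_nuc < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  n <- max(length(c_cyt), length(c_nuc))
  c_cyt <- rep_len(c_cyt, n); c_nuc <- rep_len(c_nuc, n)
  switch(row$type,
    bidirectional          = row$beta_out * c_cyt - row$beta_in * c_nuc,
    one_way_into_nucleus   = row$beta_out * c_cyt,
    one_way_into_cytoplasm = -row$beta_in * c_nuc,
    no_flux                = rep(0, n)
  )
}

# map transfer-table species to (cytoplasmic field, nuclear field)
transfer_field_pairs <- function() {
  list(P = c("P_c", "P_n"), C = c("C_c", "C_n"),
       Xi = c("Xi_c", "Xi_n"), Ups = c("Ups_c", "Ups_n"))
}

#' Explicit membrane-transfer increments for one time step
#'
#' Applies every nuclear-face flux for `dt`: each face moves
#' `flux density * face length * dt` of material, which is removed from the
#' donor cell and added to the acceptor cell after dividing by the cell
#' area, so the exchange conserves each species' total exactly. Outer faces
#' carry no flux (the external boundary is closed), and no-flux species are
#' untouched at the nuclear boundary. If a cell's outgoing transfers would
#' overdraw it within `dt`, that cell's outgoing amounts are scaled to empty
#' it exactly and the event is counted in the `limited` attribute (shipped
#' scenario runs must report zero such events).
#'
#' @param state A `field_state` (see [flat_state()]).
#' @param domain A [build_domain()] result.
#' @param spec A [transfer_spec()] table.
#' @param dt Time step (> 0).
#' @return A named list of increment matrices (one per transferred field),
#'   with attribute `limited` counting flux-limiting events.
#' @export
apply_boundary_fluxes <- function(state, domain, spec, dt) {
  stopifnot(inherits(domain, "simulation_domain"), dt > 0)
  faces <- domain$nuclear_faces
  h <- domain$h
  deltas <- list()
  limited <- 0L
  for (sp in names(transfer_field_pairs())) {
    pair <- transfer_field_pairs()[[sp]]
    f_c <- state$fields[[pair[1]]]
    f_n <- state$fields[[pair[2]]]
    flux <- nuclear_face_flux(sp, f_c[faces$cyt], f_n[faces$nuc], spec)
    amt <- flux * dt / h   # concentration change per face

    # aggregate per donor cell and rescale overdrawn donors
    out_c <- rowsum_by(pmax(amt, 0), faces$cyt)    # leaving cytoplasm cells
    over_c <- out_c$sum > f_c[out_c$cell]
    if (any(over_c)) {
      limited <- limited + sum(over_c)
      scale <- stats::setNames(rep(1, length(out_c$cell)), out_c$cell)
      scale[over_c] <- f_c[out_c$cell[over_c]] / out_c$sum[over_c]
      pos <- amt > 0
      amt[pos] <- amt[pos] * scale[as.character(faces$cyt[pos])]
    }
    out_n <- rowsum_by(pmax(-amt, 0), faces$nuc)   # leaving nucleus cells
    over_n <- out_n$sum > f_n[out_n$cell]
    if (any(over_n)) {
      limited <- limited + sum(over_n)
      scale <- stats::setNames(rep(1, length(out_n$cell)), out_n$cell)
      scale[over_n] <- f_n[out_n$cell[over_n]] / out_n$sum[over_n]
      neg <- amt < 0
      amt[neg] <- amt[neg] * scale[as.character(faces$nuc[neg])]
    }

    d_c <- matrix(0, domain$nx, domain$ny)
    d_n <- matrix(0, domain$nx, domain$ny)
    agg_c <- rowsum_by(-amt, faces$cyt)
    agg_n <- rowsum_by(amt, faces$nuc)
    d_c[agg_c$cell] <- agg_c$sum
    d_n[agg_n$cell] <- agg_n$sum
    deltas[[pair[1]]] <- d_c
    deltas[[pair[2]]] <- d_n
  }
  attr(deltas, "limited") <- limited
  deltas
}

rowsum_by <- function(x, g) {
  s <- rowsum(x, g)
  list(cell = as.integer(rownames(s)), sum = as.numeric(s))
}

# documented explicit-transfer stability check: beta * dt * facelen / area
check_transfer_stability <- function(params, domain, dt) {
  betas <- c(params$beta_Pc, params$beta_Pn, params$beta_Cc, params$beta_Cn,
             params$beta_Xi_c, params$beta_Ups_n)
  max(betas) * dt / domain$h < 0.5
}
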