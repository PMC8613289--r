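#' Species bookkeeping for the two-compartment actin model
#'
#' The model tracks thirteen concentration fields: eight in the cytoplasm
#' (G-actin `G_c`, F-actin `F_c`, cofilin `C_c`, cofilin-actin `Xi_c`,
#' profilin `P_c`, profilin-actin `Ups_c`, phospho-cofilin `Theta_c`, and the
#' catalytic factor `E_c`) and five in the nucleus (`G_n`, `C_n`, `Xi_n`,
#' `P_n`, `Ups_n`). The order returned here is the storage order used
#' throughout the package, including the compiled solver core.
#'
#' @return Character vector of the thirteen species names, in storage order.
#' @export
nucactin_species <- function() {
  c(cytoplasm_species(), nucleus_species())
}

#' @rdname nucactin_species
#' @export
cytoplasm_species <- function() {
  c("G_c", "F_c", "C_c", "Xi_c", "P_c", "Ups_c", "Theta_c", "E_c")
}

#' @rdname nucactin_species
#' @export
nucleus_species <- function() {
  c("G_n", "C_n", "Xi_n", "P_n", "Ups_n")
}

# compartment of each species, in storage order
species_compartment <- function() {
  stats::setNames(
    c(rep("cytoplasm", 8L), rep("nucleus", 5L)),
    nucactin_species()
  )
}

# species that exist on both sides of the nuclear envelope, as (cyt, nuc) pairs
shuttling_pairs <- function() {
  list(
    G   = c("G_c", "G_n"),
    C   = c("C_c", "C_n"),
    Xi  = c("Xi_c", "Xi_n"),
    P   = c("P_c", "P_n"),
    Ups = c("Ups_c", "Ups_n")
  )
}
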