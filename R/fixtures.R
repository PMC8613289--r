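#' Synthetic in-memory fixtures for testing
#'
#' Small, fully deterministic inputs — a toy domain and random positive
#' field states — so every stage of the model can be exercised without any
#' external data or file I/O.
#'
#' @param grid_size Cells per side of the toy grid (>= 8, default 41).
#' @param seed Integer seed for random draws.
#' @param state_scale Upper bound of the uniform concentration draws.
#' @param n_random_states Number of states a caller intends to draw
#'   (bookkeeping only).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(grid_size = 41, seed = 0, state_scale = 1,
                         n_random_states = 10) {
  stopifnot(grid_size >= 8, state_scale > 0)
  structure(list(grid_size = as.integer(grid_size), seed = as.integer(seed),
                 state_scale = state_scale,
                 n_random_states = as.integer(n_random_states)),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @param spec A `fixture_spec`.
#' @return `make_toy_domain()`: a list with `domain` and `geom` — the
#'   default concentric geometry discretized on `grid_size` squared cells.
#' @export
make_toy_domain <- function(spec = fixture_spec()) {
  geom <- cell_geometry()
  list(domain = build_domain(geom, spec$grid_size, spec$grid_size),
       geom = geom)
}

#' @rdname fixture_spec
#' @param domain A [build_domain()] result.
#' @return `make_random_state()`: a `field_state` with independent uniform
#'   draws on `(0, state_scale]` on each species' own compartment cells and
#'   zeros elsewhere; identical seeds give identical states.
#' @export
make_random_state <- function(domain, spec = fixture_spec()) {
  stopifnot(inherits(domain, "simulation_domain"))
  comp <- species_compartment()
  withr::with_seed(spec$seed, {
    fields <- lapply(nucactin_species(), function(sp) {
      m <- matrix(0, domain$nx, domain$ny)
      cells <- if (comp[[sp]] == "cytoplasm") domain$cells_c else domain$cells_n
      m[cells] <- spec$state_scale * stats::runif(length(cells))
      m
    })
  })
  names(fields) <- nucactin_species()
  structure(list(fields = fields, t = 0), class = "field_state")
}

#' A single-compartment rectangular domain
#'
#' Discretizes a plain rectangle in which every cell belongs to the
#' cytoplasm compartment. Used for analytic validation of the diffusion
#' solver (closed-form heat-equation eigenmodes) where no internal boundary
#' should interfere.
#'
#' @param nx,ny Grid resolution.
#' @param xlim,ylim Physical extents.
#' @return A `simulation_domain` whose mask is all-cytoplasm.
#' @export
rectangular_domain <- function(nx, ny = nx, xlim = c(0, 1), ylim = c(0, 1)) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  hx <- diff(xlim) / nx
  hy <- diff(ylim) / ny
  if (abs(hx - hy) > 1e-12 * max(hx, hy)) {
    stop("grid cells must be square", call. = FALSE)
  }
  mask <- matrix(1L, nx, ny)
  faces <- mask_faces(mask)
  structure(
    list(nx = nx, ny = ny, h = hx,
         x = xlim[1] + (seq_len(nx) - 0.5) * hx,
         y = ylim[1] + (seq_len(ny) - 0.5) * hy,
         xlim = xlim, ylim = ylim, mask = mask,
         cells_c = seq_len(nx * ny), cells_n = integer(0),
         nuclear_faces = faces$nuclear, outer_faces = faces$outer,
         area_c = nx * ny * hx^2, area_n = 0, perim_n = 0,
         geom = NULL),
    class = "simulation_domain")
}
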