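#' Cell geometry: two nested circles plus a catalytic region
#'
#' The cell is two static circular compartments: the nucleus, a disc of
#' radius `r1` about `p1`, and the cytoplasm, the part of the disc of radius
#' `r2` about `p2` outside the nucleus. The catalytic factor initially
#' occupies the cytoplasmic part of a third disc (radius `r3` about `p3`,
#' level `Ec_init`), representing the signalling region clustered at the
#' nuclear surface. `xlim`/`ylim` give the extent of the rectangular grid on
#' which the geometry is discretized.
#'
#' @param p1,r1 Nucleus centre (length-2 numeric) and radius.
#' @param p2,r2 Outer cell centre and radius; the nucleus must lie strictly
#'   inside the outer circle.
#' @param p3,r3 Catalytic-region centre and radius (`r3 >= 0`).
#' @param Ec_init Initial catalytic-factor concentration inside the region.
#' @param xlim,ylim Physical extents of the simulation rectangle.
#' @return An object of class `cell_geometry`.
#' @export
#' @examples
#' geom <- cell_geometry()
#' geom$r1 / geom$r2
cell_geometry <- function(p1 = c(0, 0), r1 = 0.15,
                          p2 = c(0, 0), r2 = 0.45,
                          p3 = c(0.225, 0), r3 = 0.075,
                          Ec_init = 50,
                          xlim = c(-0.5, 0.5), ylim = c(-0.5, 0.5)) {
  stopifnot(length(p1) == 2L, length(p2) == 2L, length(p3) == 2L,
            is.numeric(r1), is.numeric(r2), is.numeric(r3),
            length(xlim) == 2L, length(ylim) == 2L)
  if (!(r1 > 0) || !(r2 > 0) || r3 < 0) {
    stop("radii must satisfy r1 > 0, r2 > 0, r3 >= 0", call. = FALSE)
  }
  if (Ec_init < 0) stop("Ec_init must be >= 0", call. = FALSE)
  if (sqrt(sum((p1 - p2)^2)) + r1 >= r2) {
    stop("nucleus disc must lie strictly inside the outer disc ",
         "(||p1 - p2|| + r1 < r2)", call. = FALSE)
  }
  structure(
    list(p1 = as.numeric(p1), r1 = as.numeric(r1),
         p2 = as.numeric(p2), r2 = as.numeric(r2),
         p3 = as.numeric(p3), r3 = as.numeric(r3),
         Ec_init = as.numeric(Ec_init),
         xlim = as.numeric(xlim), ylim = as.numeric(ylim)),
    class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("<cell_geometry>\n")
  cat(sprintf("  nucleus:   centre (%g, %g), radius %g\n", x$p1[1], x$p1[2], x$r1))
  cat(sprintf("  cell:      centre (%g, %g), radius %g\n", x$p2[1], x$p2[2], x$r2))
  cat(sprintf("  catalytic: centre (%g, %g), radius %g, level %g\n",
              x$p3[1], x$p3[2], x$r3, x$Ec_init))
  invisible(x)
}

#' Discretize the cell geometry on a regular Cartesian grid
#'
#' Classifies every cell centre as nucleus (`||x - p1|| < r1`), cytoplasm
#' (not nucleus and `||x - p2|| < r2`) or exterior, using strict inequalities
#' so that centres exactly on a circle fall outside that compartment. The
#' stair-step compartment interfaces are collected as face lists: nuclear
#' faces join one cytoplasm cell to one nucleus cell, outer faces join a
#' cytoplasm cell to an exterior cell. The stair-step boundary error is
#' O(h).
#'
#' @param geom A [cell_geometry()] object.
#' @param nx,ny Number of grid cells in x and y (at least 8 each); cells must
#'   come out square.
#' @return An object of class `simulation_domain`: grid spacing `h`,
#'   cell-centre coordinates, integer mask matrix (0 exterior, 1 cytoplasm,
#'   2 nucleus), compartment cell indices, face tables and discrete
#'   compartment measures.
#' @export
#' @examples
#' dom <- build_domain(cell_geometry(), nx = 41, ny = 41)
#' table(dom$mask)
build_domain <- function(geom, nx, ny = nx) {
  stopifnot(inherits(geom, "cell_geometry"))
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 8L || ny < 8L) stop("grid must be at least 8 x 8", call. = FALSE)
  hx <- diff(geom$xlim) / nx
  hy <- diff(geom$ylim) / ny
  if (abs(hx - hy) > 1e-12 * max(hx, hy)) {
    stop("grid cells must be square; adjust nx/ny or xlim/ylim", call. = FALSE)
  }
  h <- hx
  x <- geom$xlim[1] + (seq_len(nx) - 0.5) * h
  y <- geom$ylim[1] + (seq_len(ny) - 0.5) * h
  cx <- matrix(x, nx, ny)
  cy <- matrix(y, nx, ny, byrow = TRUE)

  d1 <- sqrt((cx - geom$p1[1])^2 + (cy - geom$p1[2])^2)
  d2 <- sqrt((cx - geom$p2[1])^2 + (cy - geom$p2[2])^2)
  mask <- matrix(0L, nx, ny)
  mask[d2 < geom$r2] <- 1L
  mask[d1 < geom$r1] <- 2L

  if (!any(mask == 2L) || !any(mask == 1L)) {
    stop("grid too coarse: each compartment needs at least one cell",
         call. = FALSE)
  }

  faces <- mask_faces(mask)

  structure(
    list(nx = nx, ny = ny, h = h, x = x, y = y,
         xlim = geom$xlim, ylim = geom$ylim,
         mask = mask,
         cells_c = which(mask == 1L), cells_n = which(mask == 2L),
         nuclear_faces = faces$nuclear, outer_faces = faces$outer,
         area_c = sum(mask == 1L) * h^2,
         area_n = sum(mask == 2L) * h^2,
         perim_n = nrow(faces$nuclear) * h,
         geom = geom),
    class = "simulation_domain")
}

# face tables from a mask matrix; each adjacency appears exactly once
mask_faces <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  idx <- matrix(seq_len(nx * ny), nx, ny)

  pair_up <- function(a_idx, b_idx, a_lab, b_lab) {
    # faces between horizontally / vertically adjacent cells
    keep_ab <- a_lab == 1L & b_lab == 2L
    keep_ba <- a_lab == 2L & b_lab == 1L
    out_ab  <- a_lab == 1L & b_lab == 0L
    out_ba  <- a_lab == 0L & b_lab == 1L
    list(
      nuclear = cbind(cyt = c(a_idx[keep_ab], b_idx[keep_ba]),
                      nuc = c(b_idx[keep_ab], a_idx[keep_ba])),
      outer   = cbind(cyt = c(a_idx[out_ab], b_idx[out_ba]),
                      ext = c(b_idx[out_ab], a_idx[out_ba]))
    )
  }

  hz <- pair_up(idx[-nx, , drop = FALSE], idx[-1, , drop = FALSE],
                mask[-nx, , drop = FALSE], mask[-1, , drop = FALSE])
  vt <- pair_up(idx[, -ny, drop = FALSE], idx[, -1, drop = FALSE],
                mask[, -ny, drop = FALSE], mask[, -1, drop = FALSE])

  nuclear <- rbind(hz$nuclear, vt$nuclear)
  outer <- rbind(hz$outer, vt$outer)
  list(
    nuclear = tibble::tibble(cyt = as.integer(nuclear[, "cyt"]),
                             nuc = as.integer(nuclear[, "nuc"])),
    outer = tibble::tibble(cyt = as.integer(outer[, "cyt"]),
                           ext = as.integer(outer[, "ext"]))
  )
}

#' @export
print.simulation_domain <- function(x, ...) {
  cat("<simulation_domain>\n")
  cat(sprintf("  grid: %d x %d, h = %g\n", x$nx, x$ny, x$h))
  cat(sprintf("  cells: %d nucleus, %d cytoplasm, %d exterior\n",
              length(x$cells_n), length(x$cells_c),
              x$nx * x$ny - length(x$cells_n) - length(x$cells_c)))
  cat(sprintf("  nuclear faces: %d (perimeter %.4g); outer faces: %d\n",
              nrow(x$nuclear_faces), x$perim_n, nrow(x$outer_faces)))
  invisible(x)
}

#' Initial catalytic-factor field
#'
#' The catalytic factor starts at `Ec_init` on cytoplasm cells whose centre
#' lies within `r3` of `p3`, and at zero everywhere else — including nucleus
#' cells inside the ball, since the factor lives only in the cytoplasm.
#'
#' @param domain A [build_domain()] result.
#' @param geom The geometry the domain was built from (defaults to
#'   `domain$geom`).
#' @return An `nx` by `ny` matrix.
#' @export
initialize_catalytic_field <- function(domain, geom = domain$geom) {
  stopifnot(inherits(domain, "simulation_domain"), inherits(geom, "cell_geometry"))
  cx <- matrix(domain$x, domain$nx, domain$ny)
  cy <- matrix(domain$y, domain$nx, domain$ny, byrow = TRUE)
  d3 <- sqrt((cx - geom$p3[1])^2 + (cy - geom$p3[2])^2)
  field <- matrix(0, domain$nx, domain$ny)
  field[d3 < geom$r3 & domain$mask == 1L] <- geom$Ec_init
  field
}

#' Relocate the catalytic region to a given distance from the nucleus
#'
#' Returns a copy of the geometry with the catalytic-region centre moved
#' along the ray from the nucleus centre through the original region centre,
#' so that the region's nearest point sits at distance `d` from the nuclear
#' boundary. `d = 0` reproduces the juxta-nuclear (tangent) placement.
#'
#' @param geom A [cell_geometry()] object.
#' @param d Distance (>= 0) between the nuclear surface and the nearest point
#'   of the relocated region.
#' @return A `cell_geometry` with updated `p3`.
#' @seealso [max_region_distance()]
#' @export
place_region_at_distance <- function(geom, d) {
  stopifnot(inherits(geom, "cell_geometry"), is.numeric(d), length(d) == 1L)
  if (d < 0) stop("d must be >= 0 (region may not protrude into the nucleus)",
                  call. = FALSE)
  u <- geom$p3 - geom$p1
  nu <- sqrt(sum(u^2))
  u <- if (nu > 0) u / nu else c(1, 0)
  p3_new <- geom$p1 + (geom$r1 + geom$r3 + d) * u
  if (sqrt(sum((p3_new - geom$p2)^2)) + geom$r3 >= geom$r2) {
    stop("relocated region touches or crosses the outer cell boundary ",
         "(d too large)", call. = FALSE)
  }
  out <- geom
  out$p3 <- p3_new
  out
}

#' Largest admissible catalytic-region distance from the nucleus
#'
#' The supremum distance keeps the relocated region tangent to the outer
#' boundary, which [place_region_at_distance()] rejects; `slack` backs off
#' from it (use about one grid spacing so the discretized region stays clear
#' of the outer stair-step boundary).
#'
#' @param geom A [cell_geometry()] object.
#' @param slack Amount subtracted from the supremum (default `1e-6`).
#' @return The largest usable `d`.
#' @export
max_region_distance <- function(geom, slack = 1e-6) {
  stopifnot(inherits(geom, "cell_geometry"))
  u <- geom$p3 - geom$p1
  nu <- sqrt(sum(u^2))
  u <- if (nu > 0) u / nu else c(1, 0)
  # distance along the ray at which the ball touches the outer circle
  f <- function(d) {
    p3 <- geom$p1 + (geom$r1 + geom$r3 + d) * u
    geom$r2 - geom$r3 - sqrt(sum((p3 - geom$p2)^2))
  }
  lo <- 0
  if (f(lo) <= 0) stop("even the tangent placement violates the outer boundary",
                       call. = FALSE)
  hi <- geom$r2
  while (f(hi) > 0) hi <- hi * 2
  d_sup <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  max(d_sup - slack, 0)
}
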