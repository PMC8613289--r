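# brute-force membership oracle used throughout this file
enumerate_labels <- function(geom, nx, ny) {
  h <- diff(geom$xlim) / nx
  lab <- matrix(0L, nx, ny)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      cx <- geom$xlim[1] + (i - 0.5) * h
      cy <- geom$ylim[1] + (j - 0.5) * h
      if (sqrt((cx - geom$p1[1])^2 + (cy - geom$p1[2])^2) < geom$r1) {
        lab[i, j] <- 2L
      } else if (sqrt((cx - geom$p2[1])^2 + (cy - geom$p2[2])^2) < geom$r2) {
        lab[i, j] <- 1L
      }
    }
  }
  lab
}

test_that("cell-centre classification matches brute-force enumeration", {
  geom <- cell_geometry(r1 = 0.3, r2 = 0.9, p3 = c(0.36, 0), r3 = 0.06,
                        xlim = c(-1, 1), ylim = c(-1, 1))
  dom <- build_domain(geom, 41, 41)
  oracle <- enumerate_labels(geom, 41, 41)
  expect_identical(dom$mask, oracle)
  expect_identical(length(dom$cells_n), sum(oracle == 2L))
  # partition covers the grid exactly
  expect_identical(length(dom$cells_n) + length(dom$cells_c) +
                     sum(dom$mask == 0L), 41L * 41L)
})

test_that("probe points land in the expected compartments", {
  geom <- cell_geometry()
  dom <- build_domain(geom, 41, 41)
  at <- function(x, y) {
    i <- which.min(abs(dom$x - x)); j <- which.min(abs(dom$y - y))
    dom$mask[i, j]
  }
  expect_identical(at(geom$p1[1], geom$p1[2]), 2L)              # centre
  expect_identical(at((geom$r1 + geom$r2) / 2, 0), 1L)          # mid annulus
  expect_identical(at(geom$r2 + 0.02, 0), 0L)                   # outside
})

test_that("nucleus area estimate converges toward pi r1^2 under refinement", {
  geom <- cell_geometry()
  errs <- vapply(c(64, 128, 256, 512), function(n) {
    dom <- build_domain(geom, n, n)
    abs(length(dom$cells_n) * dom$h^2 - pi * geom$r1^2) / (pi * geom$r1^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("face lists join the right compartments without duplicates", {
  dom <- toy_domain()$domain
  nf <- dom$nuclear_faces
  expect_true(all(dom$mask[nf$cyt] == 1L))
  expect_true(all(dom$mask[nf$nuc] == 2L))
  expect_identical(anyDuplicated(paste(nf$cyt, nf$nuc)), 0L)
  of <- dom$outer_faces
  expect_true(all(dom$mask[of$cyt] == 1L))
  expect_true(all(dom$mask[of$ext] == 0L))
  expect_identical(dom$perim_n, nrow(nf) * dom$h)
})

test_that("invalid geometries are rejected", {
  expect_error(cell_geometry(r1 = 0.5, r2 = 0.45), "strictly inside")
  expect_error(cell_geometry(p1 = c(0.35, 0), r1 = 0.15, r2 = 0.45),
               "strictly inside")
  expect_error(build_domain(cell_geometry(), 4, 4), "at least 8")
  # grid so coarse the nucleus vanishes
  expect_error(build_domain(cell_geometry(r1 = 0.01), 8, 8), "too coarse")
})

test_that("catalytic field obeys the region and compartment restriction", {
  geom <- cell_geometry()
  dom <- build_domain(geom, 81, 81)
  field <- initialize_catalytic_field(dom, geom)

  cx <- matrix(dom$x, dom$nx, dom$ny)
  cy <- matrix(dom$y, dom$nx, dom$ny, byrow = TRUE)
  inside <- sqrt((cx - geom$p3[1])^2 + (cy - geom$p3[2])^2) < geom$r3

  # cytoplasm cells inside the ball carry Ec_init, all else zero --
  # including any nucleus cell inside the ball
  expect_true(all(field[inside & dom$mask == 1L] == geom$Ec_init))
  expect_true(all(field[!(inside & dom$mask == 1L)] == 0))
  expect_true(all(field[dom$mask == 2L] == 0))

  # total catalytic mass equals the brute-force qualifying-cell count
  n_qual <- sum(inside & dom$mask == 1L)
  expect_equal(sum(field) * dom$h^2, geom$Ec_init * n_qual * dom$h^2)
  expect_gt(n_qual, 0)
})

test_that("region relocation preserves tangency identity, bounds and mass", {
  geom <- cell_geometry()
  g0 <- place_region_at_distance(geom, 0)
  expect_equal(sqrt(sum((g0$p3 - g0$p1)^2)), geom$r1 + geom$r3)

  expect_error(place_region_at_distance(geom, -0.01), ">= 0")
  d_touch <- geom$r2 - geom$r1 - 2 * geom$r3
  expect_error(place_region_at_distance(geom, d_touch), "outer")

  d_max <- max_region_distance(geom, slack = 1e-6)
  g1 <- place_region_at_distance(geom, d_max)
  expect_s3_class(g1, "cell_geometry")

  # relocated total mass within one cell-area quantum per boundary cell
  dom <- build_domain(geom, 81, 81)
  m0 <- sum(initialize_catalytic_field(dom, g0)) * dom$h^2
  m1 <- sum(initialize_catalytic_field(dom, g1)) * dom$h^2
  n_boundary <- ceiling(2 * pi * geom$r3 / dom$h) + 4
  expect_lt(abs(m1 - m0), n_boundary * geom$Ec_init * dom$h^2)
})
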