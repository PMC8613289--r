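test_that("default parameter set satisfies every stated constraint", {
  p <- default_parameters()
  rep <- validate_parameters(p)
  expect_true(attr(rep, "pass"))
  expect_true(all(rep$pass))
  # validation is pure: repeated calls agree and the input is untouched
  p2 <- default_parameters()
  expect_identical(validate_parameters(p), rep)
  expect_identical(p, p2)
})

test_that("single violations are flagged by the right named check", {
  p <- default_parameters(D = c(F_c = 0.1))
  rep <- validate_parameters(p)
  expect_false(attr(rep, "pass"))
  expect_identical(rep$check[!rep$pass], "F-actin non-diffusing")

  p <- default_parameters(beta_Cc = 1.0, beta_Cn = 2.0)
  rep <- validate_parameters(p)
  expect_false(attr(rep, "pass"))
  expect_identical(rep$check[!rep$pass], "cofilin transfer symmetry")

  p <- default_parameters(gamma_Ec = 0.2)
  rep <- validate_parameters(p)
  expect_identical(rep$check[!rep$pass], "catalytic factor conserved")
})

test_that("malformed parameter sets produce errors naming the field", {
  raw <- unclass(default_parameters())
  raw$gamma_Gc <- NULL
  expect_error(validate_parameters(raw), "gamma_Gc")
  raw <- unclass(default_parameters())
  raw$mu2 <- NaN
  expect_error(validate_parameters(raw), "mu2")
  raw <- unclass(default_parameters())
  raw$D[["C_n"]] <- NA_real_
  expect_error(validate_parameters(raw), "C_n")
  expect_error(default_parameters(not_a_rate = 1), "not_a_rate")
})

test_that("validation reports export to JSON", {
  rep <- validate_parameters(default_parameters(D = c(F_c = 0.1)))
  f <- withr::local_tempfile(fileext = ".json")
  write_validation_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_false(back$pass)
  expect_identical(back$checks$check[!back$checks$pass],
                   "F-actin non-diffusing")
  expect_identical(nrow(back$checks), nrow(rep))
})

test_that("sampler is deterministic per seed and seed-sensitive", {
  p1 <- sample_constrained_parameters(seed = 1)
  p2 <- sample_constrained_parameters(seed = 1)
  p3 <- sample_constrained_parameters(seed = 2)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  # the caller's RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sample_constrained_parameters(seed = 7))
  expect_identical(runif(1), before)
})

test_that("all sampled parameter sets satisfy the constraints", {
  ok <- vapply(seq_len(100), function(s) {
    attr(validate_parameters(sample_constrained_parameters(seed = s)), "pass")
  }, logical(1))
  expect_identical(sum(ok), 100L)
})

test_that("unsatisfiable ranges fail after the documented rejection cap", {
  bad <- default_ranges()
  bad$alpha_Xi_c <- c(0.01, 0.01)
  bad$alpha_Xi_n <- c(0.5, 0.5)
  expect_error(sample_constrained_parameters(seed = 1, ranges = bad,
                                             max_tries = 5),
               "unsatisfiable")
})
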