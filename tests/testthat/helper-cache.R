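# Memoised heavyweight objects shared across test files (computed on first
# use within one test run). `compute` is evaluated lazily.
.nucactin_test_cache <- new.env(parent = emptyenv())

cached <- function(name, compute) {
  if (!exists(name, envir = .nucactin_test_cache, inherits = FALSE)) {
    assign(name, force(compute), envir = .nucactin_test_cache)
  }
  get(name, envir = .nucactin_test_cache, inherits = FALSE)
}

# shared small fixtures
toy_domain <- function() cached("toy_domain", make_toy_domain(fixture_spec()))

# acceptance-scale shared objects -------------------------------------------

acc_base <- function() cached("acc_base", scenario_spec(grid = 101))

acc_equilibrium <- function() cached("acc_equilibrium", {
  b <- acc_base()
  equilibrate(b$params, b$geom, b$cfg, nx = b$grid)
})

acc_knockouts <- function() cached("acc_knockouts", {
  knockout_comparison(acc_base(), equilibrium = acc_equilibrium(),
                      keep_runs = TRUE)
})

acc_full_run <- function() attr(acc_knockouts(), "runs")$both
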