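# brute-force grid oracle for the one-breakpoint model: exact OLS at every
# candidate breakpoint, independent of the package's iterative fitter
grid_oracle_sse <- function(x, y, n_grid = 501) {
  cand <- unique(quantile(x, seq(0.02, 0.98, length.out = n_grid),
                          names = FALSE))
  cand <- cand[cand > min(x) & cand < max(x)]
  min(vapply(cand, function(p) {
    sum(lm(y ~ x + pmax(x - p, 0))$residuals^2)
  }, numeric(1)))
}

# small cohort config for fast unit tests: one planted V, one increasing,
# one null phenotype
small_config <- function(n = 2500, seed = 5, missingness_rate = 0.01) {
  cohort_config(
    n_participants = n,
    missingness_rate = missingness_rate,
    phenotype_specs = list(
      phenotype_spec("vshape", "nonmonotonic", breakpoint = 10,
                     left_slope = -0.013, right_slope = 0.018, base_sd = 1,
                     heteroskedasticity_factor = 1.8),
      phenotype_spec("riser", "increasing", left_slope = 0.012, base_sd = 1,
                     center = 50, heteroskedasticity_factor = 1.4),
      phenotype_spec("inert", "null", base_sd = 1, center = 0)),
    seed = seed)
}

expect_no_na <- function(x) expect_false(anyNA(x))

sample_skewness_for_test <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}
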