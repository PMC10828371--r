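test_that("age residualization is orthogonal to age and preserves alignment", {
  set.seed(8)
  age <- runif(500, 45, 85)
  y <- 0.002 * age + rnorm(500, 0, 0.05)
  y[c(3, 99)] <- NA
  r <- residualize_age(y, age)
  expect_identical(is.na(r), is.na(y))
  ok <- !is.na(r)
  expect_lt(abs(cor(r[ok], age[ok])), 1e-10)
  # zero-slope limit: a response orthogonal to age is just centered
  y0 <- rnorm(200)
  age0 <- runif(200, 45, 85)
  y0 <- unname(residuals(lm(y0 ~ age0))) + 5
  expect_equal(residualize_age(y0, age0), y0 - mean(y0), tolerance = 1e-10)
  expect_error(residualize_age(rnorm(10), rep(50, 10)), "constant")
})

test_that("age slope is recovered from simulated scores", {
  set.seed(9)
  age <- runif(5000, 45, 85)
  y <- 0.002 * age + rnorm(5000, 0, 0.05)
  r <- residualize_age(y, age)
  slope <- coef(lm(I(y - r) ~ age))[2]
  se <- 0.05 / (sd(age) * sqrt(5000))
  expect_lt(abs(slope - 0.002), 2 * se)
})

test_that("noiseless broken-line data is recovered to machine precision", {
  x <- seq(-3, 3, by = 0.1)
  y <- abs(x - 1)
  f <- fit_segmented(x, y)
  expect_true(f$converged)
  expect_equal(unname(f$coefficients["psi"]), 1, tolerance = 1e-8)
  expect_equal(unname(f$coefficients["beta1"]), -1, tolerance = 1e-8)
  expect_equal(unname(f$coefficients["delta"]), 2, tolerance = 1e-8)
  expect_lt(f$sse, 1e-16)
})

test_that("segmented fit never loses to the grid oracle; sse below straight line", {
  set.seed(10)
  for (i in 1:30) {
    n <- sample(40:150, 1)
    x <- rnorm(n)
    kind <- i %% 3
    y <- if (kind == 0) rnorm(n) else
      if (kind == 1) 0.3 * x + rnorm(n, 0, 0.5) else
        -0.4 * (x - 0.3) + 0.9 * pmax(x - 0.3, 0) + rnorm(n, 0, 0.3)
    f <- fit_segmented(x, y)
    expect_lte(f$sse, grid_oracle_sse(x, y) + 1e-6)
    expect_lte(f$sse, f$sse_linear + 1e-10)
  }
})

test_that("breakpoint estimate is equivariant under affine maps of x", {
  set.seed(11)
  x <- runif(400, -2, 4)
  y <- -0.3 * (x - 1) + 0.7 * pmax(x - 1, 0) + rnorm(400, 0, 0.2)
  f0 <- fit_segmented(x, y)
  f1 <- fit_segmented(2.5 * x - 3, y)
  expect_equal(unname(f1$coefficients["psi"]),
               2.5 * unname(f0$coefficients["psi"]) - 3, tolerance = 1e-6)
  expect_equal(f1$sse, f0$sse, tolerance = 1e-8)
})

test_that("score test is affine-invariant in y and detects strong kinks", {
  set.seed(12)
  x <- rnorm(300)
  y <- rnorm(300)
  p0 <- score_test_slope_change(x, y)
  expect_equal(score_test_slope_change(x, y + 3 - 2 * x), p0,
               tolerance = 1e-10)
  xv <- rnorm(1000)
  yv <- abs(xv) + rnorm(1000, 0, 0.1)
  expect_lt(score_test_slope_change(xv, yv), 1e-6)
})

test_that("classification applies the three sweet-spot criteria", {
  set.seed(13)
  x <- runif(600, -2, 4)
  e <- rnorm(600, 0, 0.1)
  # genuine V: opposite slopes, tight CIs
  v <- fit_segmented(x, -0.8 * (x - 1) + 1.5 * pmax(x - 1, 0) + e)
  expect_identical(classify_relationship(v, 0.002)$relationship,
                   "nonmonotonic_sweet_spot")
  cls <- classify_relationship(v, 0.002)
  expect_true(cls$psi_ci95[1] < 1 && 1 < cls$psi_ci95[2])
  # same criteria fail on the adjusted p
  expect_identical(classify_relationship(v, 0.2)$relationship,
                   "nonmonotonic_nonsignificant")
  # convex but same-sign slopes: increasing, never a sweet spot
  up <- fit_segmented(x, 0.5 * x + 2 * pmax(x - 1, 0) + e)
  expect_identical(classify_relationship(up, 1e-9)$relationship,
                   "increasing")
  # right slope indistinguishable from zero: criterion (2) fails
  flatright <- fit_segmented(x, -0.8 * (x - 1) + 0.8 * pmax(x - 1, 0) + e)
  expect_false(identical(classify_relationship(flatright, 0.001)$relationship,
                         "nonmonotonic_sweet_spot"))
})

test_that("scan handles empty selections, filters, and records its denominator", {
  co <- generate_cohort(small_config(n = 2500))
  ins <- build_instruments(co)
  empty <- sweet_spot_scan(co, ins, character())
  expect_identical(nrow(empty$records), 0L)
  scan <- sweet_spot_scan(co, ins, c("vshape", "inert"))
  expect_identical(scan$m, 2L * 2L * 5L)
  expect_identical(nrow(scan$records), 20L)
  expect_equal(scan$records$p_score_bonferroni,
               pmin(1, scan$records$p_score_raw * scan$m))
  # row filter restricts the fitted sample
  half <- sweet_spot_scan(co, ins, "vshape", filter = "age < 65")
  expect_lt(max(half$records$n), max(scan$records$n[
    scan$records$phenotype == "vshape"]))
  # planted V found, null not called a sweet spot
  vrec <- scan$records[scan$records$phenotype == "vshape", ]
  expect_true(any(vrec$relationship == "nonmonotonic_sweet_spot"))
  irec <- scan$records[scan$records$phenotype == "inert", ]
  expect_false(any(irec$relationship == "nonmonotonic_sweet_spot"))
})
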