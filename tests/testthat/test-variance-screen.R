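test_that("Brown-Forsythe statistic matches direct formula evaluation", {
  # 11-point example evaluated step by step from the definition:
  # z_a = |a - 2.5| -> mean 7/3; z_b = |b - 0.2| -> mean 0.12;
  # W = 9 * [6(7/3 - zbar)^2 + 5(0.12 - zbar)^2] / 34.8613...
  bf <- brown_forsythe(c(0, 1, 2, 3, 4, 10), c(0, 0.1, 0.2, 0.3, 0.4))
  expect_equal(bf$statistic, 3.4492187228, tolerance = 1e-9)
  expect_equal(bf$p.value, 0.0962404957, tolerance = 1e-9)
  expect_identical(bf$df, c(1L, 9L))
})

test_that("identical spread gives a null statistic", {
  bf <- brown_forsythe(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(bf$statistic, 0)
  expect_equal(bf$p.value, 1)
  expect_error(brown_forsythe(1, c(1, 2, 3)), "at least 2")
})

test_that("Brown-Forsythe is location-scale invariant", {
  set.seed(4)
  a <- rgamma(40, 2)
  b <- rnorm(25, 3, 2)
  ref <- brown_forsythe(a, b)
  for (cs in list(c(2.5, -1), c(-0.3, 7))) {
    tr <- brown_forsythe(cs[1] * a + cs[2], cs[1] * b + cs[2])
    expect_equal(tr$statistic, ref$statistic, tolerance = 1e-12)
    expect_equal(tr$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("two-group statistic agrees with an independent reference implementation", {
  skip_if_not_installed("car")
  set.seed(5)
  for (i in 1:100) {
    na <- sample(5:60, 1)
    nb <- sample(5:60, 1)
    a <- rnorm(na, sd = runif(1, 0.5, 3))
    b <- rlnorm(nb, sdlog = runif(1, 0.2, 1))
    mine <- brown_forsythe(a, b)
    d <- data.frame(x = c(a, b),
                    g = factor(rep(c("a", "b"), c(na, nb))))
    ref <- car::leveneTest(x ~ g, d, center = median)
    expect_equal(mine$statistic, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(mine$p.value, ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("null p-values are approximately uniform", {
  set.seed(6)
  p <- replicate(1000, brown_forsythe(rnorm(60), rnorm(45))$p.value)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("prefilter drops by missingness and correlation with a drop log", {
  set.seed(7)
  n <- 200
  tab <- data.frame(a = rnorm(n))
  tab$b <- tab$a                                   # duplicate, r = 1
  tab$c <- rnorm(n)
  tab$d <- rnorm(n)
  tab$d[1:60] <- NA                                # 30% missing
  tab$e <- rnorm(n)
  tab$e[1:120] <- NA                               # 60% missing, exempt
  pf <- prefilter_phenotypes(tab, c("a", "b", "c", "d", "e"),
                             exempt = "e")
  expect_identical(pf$kept, c("a", "c", "e"))
  expect_setequal(pf$dropped$phenotype, c("b", "d"))
  expect_identical(sort(unique(pf$dropped$reason)),
                   c("correlation", "missingness"))
  expect_error(prefilter_phenotypes(tab, "nope"), "absent")
})

test_that("screen bookkeeping: fixed denominator, skips, row-order invariance", {
  co <- generate_cohort(small_config(n = 2500))
  ins <- build_instruments(co)
  phen <- co$meta$phenotype_cols
  scr <- run_screen(co, ins, phen)
  expect_identical(scr$m, screen_test_count(length(phen)))
  expect_identical(nrow(scr$records), scr$m)
  # skipped cells keep their slot in the denominator
  run <- scr$records[!scr$records$skipped, ]
  expect_equal(run$p_bonferroni, pmin(1, run$p_raw * scr$m))
  # small cohort: strata with < 30 per group are skipped, not dropped
  tiny <- generate_cohort(small_config(n = 400))
  ins_t <- build_instruments(tiny)
  scr_t <- run_screen(tiny, ins_t, tiny$meta$phenotype_cols)
  expect_gt(sum(scr_t$records$skipped), 0)
  expect_identical(nrow(scr_t$records), scr_t$m)
  # participant order must not matter
  perm <- sample(nrow(co$table))
  co2 <- co
  co2$table <- co$table[perm, ]
  ins2 <- ins
  ins2$scores <- ins$scores[perm, ]
  scr2 <- run_screen(co2, ins2, phen)
  expect_equal(scr2$records$W, scr$records$W, tolerance = 1e-12)
})

test_that("selection requires lower variance in the healthiest group", {
  rec <- data.frame(
    phenotype = c("up", "up", "down"),
    instrument = "I", sex = "F", stratum = "<55",
    n_healthiest = 100, n_least = 100,
    var_healthiest = c(2, 2, 0.5), var_least = c(1, 1, 2),
    W = 20, p_raw = 1e-6,
    p_bonferroni = c(1e-3, 1e-3, 1e-3),
    healthiest_lower = c(FALSE, FALSE, TRUE),
    skipped = FALSE)
  sel <- select_health_related(rec, alpha = 0.05)
  expect_false(sel$selected[sel$phenotype == "up"])
  expect_true(sel$selected[sel$phenotype == "down"])
  expect_equal(sel$min_p_bonferroni, c(1e-3, 1e-3))
})

test_that("planted heteroskedastic phenotype is selected, null is not", {
  cfg <- cohort_config(
    n_participants = 10000, missingness_rate = 0,
    phenotype_specs = list(
      phenotype_spec("hetero", "null", base_sd = 1, center = 0,
                     heteroskedasticity_factor = 2.0),
      phenotype_spec("inert", "null", base_sd = 1, center = 0)),
    seed = 13)
  co <- generate_cohort(cfg)
  ins <- build_instruments(co)
  scr <- run_screen(co, ins, c("hetero", "inert"))
  sel <- select_health_related(scr)
  expect_true(sel$selected[sel$phenotype == "hetero"])
  expect_false(sel$selected[sel$phenotype == "inert"])
})
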