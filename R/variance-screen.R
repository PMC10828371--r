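#' Pre-filter phenotypes by missingness and pairwise correlation
#'
#' Drops phenotypes with more than \code{miss_max} missing values (unless
#' exempt, e.g. sparse inflammatory biomarkers retained for their known
#' relevance) and then, scanning pairs in input order, drops the
#' later-listed member of any pair whose pairwise-complete Pearson
#' correlation exceeds \code{r_max} in absolute value.
#'
#' @param cohort an \code{"ss_cohort"} or a data.frame.
#' @param phenotypes character vector of phenotype column names.
#' @param r_max correlation threshold (default 0.9).
#' @param miss_max missingness threshold as a fraction (default 0.24).
#' @param exempt phenotypes kept regardless of missingness.
#' @return list with \code{kept} (character vector) and \code{dropped}
#'   (data.frame of drops with reasons).
#' @export
prefilter_phenotypes <- function(cohort, phenotypes, r_max = 0.9,
                                 miss_max = 0.24, exempt = character()) {
  tab <- if (inherits(cohort, "ss_cohort")) cohort$table else cohort
  absent <- setdiff(phenotypes, names(tab))
  stop_if(length(absent) > 0, "phenotype '%s' absent from table", absent[1])

  drops <- data.frame(phenotype = character(), reason = character(),
                      detail = character(), stringsAsFactors = FALSE)
  miss <- vapply(phenotypes, function(p) mean(is.na(tab[[p]])), 0)
  out <- phenotypes[miss > miss_max & !phenotypes %in% exempt]
  if (length(out) > 0)
    drops <- rbind(drops, data.frame(
      phenotype = out, reason = "missingness",
      detail = sprintf("%.1f%% missing", 100 * miss[out])))
  kept <- setdiff(phenotypes, out)

  i <- 1
  while (i < length(kept)) {
    x <- tab[[kept[i]]]
    r <- vapply(kept[-seq_len(i)], function(p)
      suppressWarnings(stats::cor(x, tab[[p]],
                                  use = "pairwise.complete.obs")), 0)
    hit <- names(r)[!is.na(r) & abs(r) > r_max]
    if (length(hit) > 0) {
      drops <- rbind(drops, data.frame(
        phenotype = hit, reason = "correlation",
        detail = sprintf("|r| = %.3f with %s", abs(r[hit]), kept[i])))
      kept <- setdiff(kept, hit)
    }
    i <- i + 1
  }
  list(kept = kept, dropped = drops)
}

#' Two-group Brown-Forsythe test of variance homogeneity
#'
#' Levene-type test on absolute deviations from the group medians,
#' robust to skew and unequal group sizes. With z_ij = |x_ij - median_j|,
#' the statistic is W = (N - 2) * sum_j n_j (zbar_j - zbar)^2 /
#' sum_j sum_i (z_ij - zbar_j)^2, referred to F(1, N - 2). If all
#' deviations are identical the statistic is 0 and p = 1.
#'
#' @param group_a,group_b numeric vectors (missing values dropped), each
#'   with at least two non-missing values.
#' @return list with \code{statistic}, \code{p.value}, \code{df} and the
#'   per-group variances \code{var_a}, \code{var_b}.
#' @export
brown_forsythe <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  stop_if(length(a) < 2 || length(b) < 2,
          "each group needs at least 2 non-missing values")
  za <- abs(a - stats::median(a))
  zb <- abs(b - stats::median(b))
  N <- length(za) + length(zb)
  zbar <- mean(c(za, zb))
  num <- length(za) * (mean(za) - zbar)^2 + length(zb) * (mean(zb) - zbar)^2
  den <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  if (den <= 0 || num <= .Machine$double.eps * den) {
    W <- 0
    p <- 1
  } else {
    W <- (N - 2) * num / den
    p <- stats::pf(W, 1, N - 2, lower.tail = FALSE)
  }
  list(statistic = W, p.value = p, df = c(1L, N - 2L),
       var_a = stats::var(a), var_b = stats::var(b))
}

#' Number of planned screen tests (Bonferroni denominator)
#'
#' The screen's multiplicity correction uses the full planned product of
#' phenotypes x instruments x sexes x age strata, whether or not
#' individual strata are skipped for insufficient group size.
#'
#' @param n_phenotypes number of phenotypes screened.
#' @param n_instruments,n_sexes,n_strata design counts (defaults 5, 2, 4).
#' @return integer test count.
#' @export
screen_test_count <- function(n_phenotypes, n_instruments = 5L,
                              n_sexes = 2L, n_strata = 4L) {
  as.integer(n_phenotypes) * as.integer(n_instruments) *
    as.integer(n_sexes) * as.integer(n_strata)
}

age_strata <- function() {
  data.frame(label = c("<55", "55-64", "65-74", ">=75"),
             lo = c(-Inf, 55, 65, 75), hi = c(55, 65, 75, Inf),
             stringsAsFactors = FALSE)
}

#' Variance-heterogeneity screen over phenotypes, instruments and strata
#'
#' For every phenotype x instrument x sex x age stratum, compares the
#' phenotype's variance between the healthiest (level 1) and least-healthy
#' (level 4) groups with the Brown-Forsythe test, restricted to complete
#' cases (non-missing phenotype and non-missing instrument score). Cells
#' where either group has fewer than \code{min_group} complete cases are
#' skipped but still counted in the fixed Bonferroni denominator.
#'
#' @param cohort an \code{"ss_cohort"}.
#' @param instruments an \code{"ss_instruments"} from
#'   \code{\link{build_instruments}}.
#' @param phenotypes phenotype column names to screen.
#' @param alpha significance level for the adjusted p-values (default
#'   0.05).
#' @param min_group minimum complete cases per group (default 30).
#' @return object of class \code{"ss_screen"}: list with \code{records}
#'   (one row per phenotype x instrument x sex x stratum, including
#'   skipped cells flagged in \code{skipped}), \code{m} (Bonferroni
#'   denominator) and \code{alpha}.
#' @export
run_screen <- function(cohort, instruments, phenotypes, alpha = 0.05,
                       min_group = 30L) {
  tab <- cohort$table
  meta <- cohort$meta
  absent <- setdiff(phenotypes, names(tab))
  stop_if(length(absent) > 0, "phenotype '%s' absent from table", absent[1])
  sc <- instruments$scores
  stopifnot(identical(sc$id, tab[[meta$id_col]]))

  strata <- age_strata()
  m <- screen_test_count(length(phenotypes))
  age <- tab[[meta$age_col]]
  sexv <- tab[[meta$sex_col]]

  grid <- expand.grid(phenotype = phenotypes,
                      instrument = instrument_ids(),
                      sex = c("F", "M"),
                      stratum = strata$label,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    st <- strata[strata$label == g$stratum, ]
    level <- sc[[paste0("level_", g$instrument)]]
    score <- sc[[paste0("score_", g$instrument)]]
    x <- tab[[g$phenotype]]
    in_cell <- sexv == g$sex & age >= st$lo & age < st$hi &
      !is.na(x) & !is.na(score) & !is.na(level)
    xa <- x[in_cell & level == 1L]
    xb <- x[in_cell & level == 4L]
    base <- data.frame(g, n_healthiest = length(xa), n_least = length(xb),
                       stringsAsFactors = FALSE)
    if (length(xa) < min_group || length(xb) < min_group)
      return(cbind(base, var_healthiest = NA_real_, var_least = NA_real_,
                   W = NA_real_, p_raw = NA_real_, p_bonferroni = NA_real_,
                   healthiest_lower = NA, skipped = TRUE))
    bf <- brown_forsythe(xa, xb)
    cbind(base, var_healthiest = bf$var_a, var_least = bf$var_b,
          W = bf$statistic, p_raw = bf$p.value,
          p_bonferroni = min(1, bf$p.value * m),
          healthiest_lower = bf$var_a < bf$var_b, skipped = FALSE)
  })
  structure(list(records = do.call(rbind, rows), m = m, alpha = alpha,
                 min_group = min_group),
            class = "ss_screen")
}

#' Select health-related phenotypes from screen records
#'
#' A phenotype is selected when at least one of its (up to 40) tests is
#' Bonferroni-significant with the lower variance in the healthiest group.
#' The per-phenotype summary reports the minimum adjusted p across its
#' records.
#'
#' @param screen an \code{"ss_screen"} (or its \code{records} data.frame,
#'   in which case \code{alpha} must be supplied).
#' @param alpha significance level (default: the screen's).
#' @return data.frame with one row per phenotype: \code{phenotype},
#'   \code{n_tests_run}, \code{min_p_bonferroni}, \code{selected}.
#' @export
select_health_related <- function(screen, alpha = NULL) {
  if (inherits(screen, "ss_screen")) {
    rec <- screen$records
    if (is.null(alpha)) alpha <- screen$alpha
  } else {
    rec <- screen
    stop_if(is.null(alpha), "alpha must be given with raw records")
  }
  out <- do.call(rbind, lapply(split(rec, rec$phenotype), function(d) {
    run <- d[!d$skipped, ]
    hit <- nrow(run) > 0 &&
      any(run$p_bonferroni < alpha & run$healthiest_lower, na.rm = TRUE)
    data.frame(phenotype = d$phenotype[1], n_tests_run = nrow(run),
               min_p_bonferroni = if (nrow(run) > 0)
                 min(run$p_bonferroni) else NA_real_,
               selected = hit, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(match(out$phenotype, unique(rec$phenotype))), ]
}
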