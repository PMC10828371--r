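#' Residualize instrument scores on age
#'
#' Ordinary least squares of the score on continuous age (intercept plus
#' linear term); returns residuals aligned to the input rows, missing
#' wherever either input is missing. Used so that breakpoint estimation
#' is not confounded by the strong age trend of every health instrument.
#'
#' @param scores numeric instrument scores.
#' @param age numeric ages (years).
#' @return numeric residual vector of the same length.
#' @export
residualize_age <- function(scores, age) {
  ok <- !is.na(scores) & !is.na(age)
  stop_if(sum(ok) < 3, "need at least 3 non-missing (score, age) pairs")
  stop_if(stats::var(age[ok]) == 0, "age is constant: degenerate design")
  fit <- stats::lm.fit(cbind(1, age[ok]), scores[ok])
  out <- rep(NA_real_, length(scores))
  out[ok] <- fit$residuals
  out
}

# exact OLS SSE of the broken-line model at a fixed breakpoint
seg_sse_at <- function(x, y, psi) {
  X <- cbind(1, x, pmax(x - psi, 0))
  sum(stats::lm.fit(X, y)$residuals^2)
}

#' Fit a one-breakpoint segmented regression
#'
#' Fits \code{y = b0 + b1*x + delta*(x - psi)_+ + e} with a free
#' breakpoint psi by iterative linearization: at each step the working
#' covariates \code{(x - psi)_+} and the gap indicator \code{-1(x > psi)}
#' are refit by OLS and the breakpoint is updated by
#' \code{psi <- psi + gamma/delta}, with step halving so that the exact
#' profile SSE never increases. Iteration starts from the median of x and
#' declares convergence when \code{|gamma|} falls below \code{tol} or the
#' breakpoint update stalls at machine scale (the profile minimum then
#' sits at a data kink, where the gap coefficient jumps across zero); it
#' is restarted from up to four alternative quantile starts, and psi is
#' kept inside the 2nd-98th percentile of x by projection. A quantile grid
#' search (exact OLS at \code{n_grid} candidate breakpoints) backs up the
#' iteration: if the grid finds a strictly better SSE, the iteration is
#' restarted from the grid optimum and the best solution is kept, so the
#' returned fit is never worse than the grid. The standard error of psi
#' uses the delta method, \code{se(gamma)/|delta|}; slope standard errors
#' come from the OLS covariance at the final breakpoint (conditioning on
#' the estimated psi).
#'
#' @param x phenotype values (numeric).
#' @param y response values (e.g. age-residualized instrument scores).
#' @param tol convergence tolerance on the gap coefficient (default 1e-8).
#' @param max_iter maximum iterations per start (default 50).
#' @param n_grid number of quantile grid candidates (default 501).
#' @param min_n minimum complete pairs (default 20).
#' @return object of class \code{"segfit"}: list with \code{coefficients}
#'   (\code{beta0}, \code{beta1}, \code{delta}, \code{psi}), \code{se},
#'   \code{ci95} (rows beta1, right_slope, psi), \code{right_slope},
#'   \code{n}, \code{converged}, \code{iterations}, \code{sse},
#'   \code{sse_linear}, \code{linear} (straight-line fit summary) and
#'   \code{x_range}.
#' @export
fit_segmented <- function(x, y, tol = 1e-8, max_iter = 50L, n_grid = 501L,
                          min_n = 20L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stop_if(n < min_n, "need at least %d complete pairs, got %d", min_n, n)
  stop_if(stats::var(x) == 0, "x is constant: breakpoint not identifiable")

  bounds <- stats::quantile(x, c(0.02, 0.98), names = FALSE, type = 7)
  lin <- stats::lm(y ~ x)
  sse_lin <- sum(stats::residuals(lin)^2)

  span <- diff(range(x))
  run_from <- function(psi0) {
    psi <- clamp(psi0, bounds[1], bounds[2])
    sse_cur <- seg_sse_at(x, y, psi)
    for (it in seq_len(max_iter)) {
      U <- pmax(x - psi, 0)
      V <- -(x > psi)
      fit <- stats::lm(y ~ x + U + V)
      cf <- stats::coef(fit)
      if (any(is.na(cf))) return(NULL)            # collinear working design
      gam <- cf[["V"]]; del <- cf[["U"]]
      if (abs(gam) < tol)
        return(list(psi = psi, converged = TRUE, iterations = it))
      if (abs(del) < .Machine$double.eps^0.5) return(NULL)
      # damped update: halve the step until the exact SSE improves; a
      # stalled or machine-small step means the profile minimum is at a
      # data kink, where the gap coefficient cannot shrink further
      step <- gam / del
      h <- 1
      moved <- FALSE
      for (j in 1:10) {
        cand <- clamp(psi + h * step, bounds[1], bounds[2])
        s2 <- seg_sse_at(x, y, cand)
        if (s2 < sse_cur) {
          psi <- cand
          sse_cur <- s2
          moved <- TRUE
          break
        }
        h <- h / 2
      }
      if (!moved || abs(h * step) < 1e-10 * span)
        return(list(psi = psi, converged = TRUE, iterations = it))
    }
    list(psi = psi, converged = FALSE, iterations = max_iter)
  }

  starts <- stats::quantile(x, c(0.5, 0.1, 0.3, 0.7, 0.9), names = FALSE)
  best <- NULL
  for (s in starts) {
    r <- run_from(s)
    if (is.null(r) || !r$converged) next
    r$sse <- seg_sse_at(x, y, r$psi)
    if (is.null(best) || r$sse < best$sse) best <- r
  }

  # grid backup / safeguard: exact OLS at quantile candidates
  cand <- unique(stats::quantile(x, seq(0.02, 0.98, length.out = n_grid),
                                 names = FALSE, type = 7))
  cand <- cand[cand > min(x) & cand < max(x)]
  gsse <- vapply(cand, function(p) seg_sse_at(x, y, p), 0)
  gbest <- cand[which.min(gsse)]
  if (is.null(best) || min(gsse) < best$sse - 1e-12) {
    r <- run_from(gbest)
    if (!is.null(r) && r$converged) {
      r$sse <- seg_sse_at(x, y, r$psi)
      if (is.null(best) || r$sse <= best$sse) best <- r
    }
    if (is.null(best) || min(gsse) < best$sse)
      best <- list(psi = gbest, converged = FALSE, iterations = max_iter,
                   fit = NULL, sse = min(gsse))
  }

  psi <- best$psi
  # a noiseless broken line is a legitimate input; summary.lm warns about
  # the exact fit, which is expected rather than suspicious here
  quiet_summary <- function(fit) withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  # final working fit at psi for the delta-method se of the breakpoint
  U <- pmax(x - psi, 0); V <- -(x > psi)
  wfit <- stats::lm(y ~ x + U + V)
  wcf <- quiet_summary(wfit)$coefficients
  # slope inference conditioning on the final breakpoint
  sfit <- stats::lm(y ~ x + U)
  cf <- stats::coef(sfit)
  ssum <- quiet_summary(sfit)
  vc <- ssum$cov.unscaled * ssum$sigma^2
  beta1 <- cf[["x"]]; delta <- cf[["U"]]
  se_b1 <- sqrt(vc["x", "x"])
  se_right <- sqrt(vc["x", "x"] + vc["U", "U"] + 2 * vc["x", "U"])
  se_delta <- sqrt(vc["U", "U"])
  se_psi <- if (all(c("U", "V") %in% rownames(wcf)) && abs(wcf["U", 1]) > 0)
    wcf["V", 2] / abs(wcf["U", 1]) else NA_real_
  tq <- stats::qt(0.975, n - 4)
  ci <- rbind(beta1 = beta1 + c(-1, 1) * tq * se_b1,
              right_slope = beta1 + delta + c(-1, 1) * tq * se_right,
              psi = psi + c(-1, 1) * tq * se_psi)
  colnames(ci) <- c("lo", "hi")
  sse <- seg_sse_at(x, y, psi)

  lcf <- quiet_summary(lin)$coefficients
  structure(list(
    coefficients = c(beta0 = cf[["(Intercept)"]], beta1 = beta1,
                     delta = delta, psi = psi),
    right_slope = beta1 + delta,
    se = c(beta1 = se_b1, right_slope = se_right, delta = se_delta,
           psi = se_psi),
    ci95 = ci, n = n, converged = isTRUE(best$converged),
    iterations = best$iterations, sse = sse, sse_linear = sse_lin,
    linear = list(slope = lcf["x", 1], se = lcf["x", 2],
                  ci95 = lcf["x", 1] + c(-1, 1) *
                    stats::qt(0.975, n - 2) * lcf["x", 2]),
    x_range = range(x)), class = "segfit")
}

#' @export
print.segfit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(paste0("segmented fit (n = %d, %s, %d iter)\n",
                     "  psi = %.4g [%.4g, %.4g]\n",
                     "  left slope = %.4g, right slope = %.4g, sse = %.4g\n"),
              x$n, if (x$converged) "converged" else "grid fallback",
              x$iterations, cf["psi"], x$ci95["psi", 1], x$ci95["psi", 2],
              cf["beta1"], x$right_slope, x$sse))
  invisible(x)
}

#' Pseudo-score test for a change in slope
#'
#' Tests H0: no change in slope (straight line) against a one-breakpoint
#' alternative. The score-type statistic contrasts the straight-line OLS
#' residuals with the mean of the working covariates \code{(x - psi_k)_+}
#' over \code{k_eval} fixed evaluation points placed at equally spaced
#' interior quantiles of x; the studentized statistic is referred to the
#' t distribution with n - 3 degrees of freedom, two-sided. Because the
#' evaluation points are fixed under the null, the test is exact for
#' Gaussian errors and does not require the breakpoint to be estimable.
#'
#' @param x,y numeric vectors (missing pairs dropped).
#' @param k_eval number of evaluation points (default 10).
#' @return two-sided p-value.
#' @export
score_test_slope_change <- function(x, y, k_eval = 10L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stop_if(n < 20, "need at least 20 complete pairs, got %d", n)
  stop_if(stats::var(x) == 0, "x is constant")
  ks <- stats::quantile(x, seq_len(k_eval) / (k_eval + 1), names = FALSE,
                        type = 7)
  M <- rowMeans(vapply(ks, function(k) pmax(x - k, 0), numeric(n)))
  fit <- stats::lm(y ~ x + M)
  cf <- summary(fit)$coefficients
  if (!"M" %in% rownames(cf)) return(1)            # M collinear with {1, x}
  unname(cf["M", 4])
}

#' Classify a phenotype-instrument relationship
#'
#' Applies the three sweet-spot criteria to a segmented fit: (1) the two
#' slopes have opposite signs, (2) both slope 95\% CIs exclude zero, and
#' (3) the slope difference is significant (Bonferroni-adjusted score-test
#' p below \code{alpha}). If all three hold the relationship is a sweet
#' spot and the breakpoint with its 95\% CI is reported. Otherwise: both
#' slope CIs excluding zero with a common sign gives
#' \code{increasing}/\code{decreasing}; opposite-sign point estimates
#' failing the criteria give \code{nonmonotonic_nonsignificant}; anything
#' else is \code{flat}. Fits that did not converge (grid fallback) are
#' classified from the straight-line slope only.
#'
#' @param fit a \code{"segfit"}.
#' @param p_bonferroni Bonferroni-adjusted score-test p-value.
#' @param alpha significance level (default 0.05).
#' @return list with \code{relationship}, \code{psi}, \code{psi_ci95},
#'   \code{p_bonferroni}.
#' @export
classify_relationship <- function(fit, p_bonferroni, alpha = 0.05) {
  out <- list(relationship = "flat", psi = NA_real_,
              psi_ci95 = c(NA_real_, NA_real_), p_bonferroni = p_bonferroni)
  line_class <- function(slope, ci) {
    if (ci[1] > 0 || ci[2] < 0) {
      if (slope > 0) "increasing" else "decreasing"
    } else "flat"
  }
  if (!fit$converged) {
    out$relationship <- line_class(fit$linear$slope, fit$linear$ci95)
    return(out)
  }
  b1 <- fit$coefficients[["beta1"]]
  b2 <- fit$right_slope
  ci1 <- fit$ci95["beta1", ]
  ci2 <- fit$ci95["right_slope", ]
  excl1 <- ci1[1] > 0 || ci1[2] < 0
  excl2 <- ci2[1] > 0 || ci2[2] < 0
  opposite <- sign(b1) * sign(b2) < 0
  if (opposite && excl1 && excl2 && !is.na(p_bonferroni) &&
      p_bonferroni < alpha) {
    out$relationship <- "nonmonotonic_sweet_spot"
    out$psi <- fit$coefficients[["psi"]]
    out$psi_ci95 <- unname(fit$ci95["psi", ])
  } else if (excl1 && excl2 && !opposite) {
    out$relationship <- if (b1 > 0) "increasing" else "decreasing"
  } else if (opposite) {
    out$relationship <- "nonmonotonic_nonsignificant"
  } else {
    out$relationship <- line_class(fit$linear$slope, fit$linear$ci95)
  }
  out
}

#' Scan selected phenotypes for sweet spots
#'
#' For every sex x instrument x selected phenotype: residualizes the
#' instrument score on age within sex (optionally also on lifestyle
#' covariates, one-hot coded with the first level as reference), fits the
#' one-breakpoint segmented model, runs the pseudo-score test for the
#' slope change, Bonferroni-adjusts it over the full scan (#phenotypes x
#' 2 sexes x 5 instruments) and classifies the relationship.
#'
#' @param cohort an \code{"ss_cohort"}.
#' @param instruments an \code{"ss_instruments"}.
#' @param phenotypes character vector of selected phenotype names.
#' @param covariate_set optional character vector of covariate column
#'   names to adjust for in addition to age.
#' @param filter optional one-sided formula or character expression
#'   evaluated in the cohort table selecting rows to keep (e.g.
#'   \code{"disease_diabetes == 0"} for a medication-sensitivity re-run).
#' @param alpha significance level for classification (default 0.05).
#' @param k_eval evaluation points for the score test (default 10).
#' @param min_n minimum complete pairs per fit (default 30).
#' @return object of class \code{"ss_scan"}: list with \code{records}
#'   (one row per phenotype x instrument x sex, with slopes, breakpoint,
#'   CI bounds, raw and adjusted p, classification, the phenotype sd and
#'   the standardized slope difference \code{delta_std}) and \code{m}
#'   (Bonferroni denominator).
#' @export
sweet_spot_scan <- function(cohort, instruments, phenotypes,
                            covariate_set = NULL, filter = NULL,
                            alpha = 0.05, k_eval = 10L, min_n = 30L) {
  tab <- cohort$table
  meta <- cohort$meta
  sc <- instruments$scores
  stopifnot(identical(sc$id, tab[[meta$id_col]]))
  if (length(phenotypes) == 0)
    return(structure(list(records = empty_scan_records(), m = 0L,
                          alpha = alpha), class = "ss_scan"))
  absent <- setdiff(phenotypes, names(tab))
  stop_if(length(absent) > 0, "phenotype '%s' absent from table", absent[1])

  keep <- rep(TRUE, nrow(tab))
  if (!is.null(filter)) {
    expr <- if (inherits(filter, "formula")) filter[[2]] else
      str2lang(filter)
    keep <- eval(expr, tab, parent.frame())
    keep[is.na(keep)] <- FALSE
  }
  m <- length(phenotypes) * 2L * length(instrument_ids())
  age <- tab[[meta$age_col]]
  sexv <- tab[[meta$sex_col]]

  rows <- list()
  for (sx in c("F", "M")) {
    sel_sex <- keep & !is.na(sexv) & sexv == sx
    for (ins in instrument_ids()) {
      score <- sc[[paste0("score_", ins)]]
      resid <- rep(NA_real_, nrow(tab))
      ok <- sel_sex & !is.na(score) & !is.na(age)
      if (!is.null(covariate_set) && length(covariate_set) > 0) {
        cv <- tab[covariate_set]
        ok <- ok & stats::complete.cases(cv)
        if (sum(ok) >= min_n) {
          dd <- data.frame(score = score[ok], age = age[ok],
                           cv[ok, , drop = FALSE])
          resid[ok] <- stats::residuals(
            stats::lm(score ~ ., data = dd))
        }
      } else if (sum(ok) >= 3) {
        resid[ok] <- residualize_age(score[ok], age[ok])
      }
      for (ph in phenotypes) {
        x <- tab[[ph]]
        use <- ok & !is.na(x) & !is.na(resid)
        n_use <- sum(use)
        if (n_use < min_n || stats::var(x[use]) == 0) {
          rows[[length(rows) + 1]] <- scan_row(
            ph, ins, sx, n_use, fit = NULL, p_raw = NA_real_,
            p_bonf = NA_real_, cls = list(relationship = "insufficient_data",
                                          psi = NA_real_,
                                          psi_ci95 = c(NA_real_, NA_real_)),
            x_sd = NA_real_)
          next
        }
        fit <- fit_segmented(x[use], resid[use], min_n = min_n)
        p_raw <- score_test_slope_change(x[use], resid[use],
                                         k_eval = k_eval)
        p_bonf <- min(1, p_raw * m)
        cls <- classify_relationship(fit, p_bonf, alpha = alpha)
        rows[[length(rows) + 1]] <- scan_row(
          ph, ins, sx, n_use, fit, p_raw, p_bonf, cls,
          x_sd = stats::sd(x[use]))
      }
    }
  }
  structure(list(records = do.call(rbind, rows), m = m, alpha = alpha),
            class = "ss_scan")
}

scan_row <- function(ph, ins, sx, n, fit, p_raw, p_bonf, cls, x_sd) {
  data.frame(
    phenotype = ph, instrument = ins, sex = sx, n = n,
    beta1 = if (is.null(fit)) NA_real_ else fit$coefficients[["beta1"]],
    right_slope = if (is.null(fit)) NA_real_ else fit$right_slope,
    delta = if (is.null(fit)) NA_real_ else fit$coefficients[["delta"]],
    delta_std = if (is.null(fit)) NA_real_ else
      fit$coefficients[["delta"]] * x_sd,
    psi = if (is.null(fit)) NA_real_ else fit$coefficients[["psi"]],
    psi_lo = cls$psi_ci95[1], psi_hi = cls$psi_ci95[2],
    x_sd = x_sd,
    p_score_raw = p_raw, p_score_bonferroni = p_bonf,
    converged = if (is.null(fit)) NA else fit$converged,
    relationship = cls$relationship,
    stringsAsFactors = FALSE)
}

empty_scan_records <- function() {
  scan_row("x", "I", "F", 0L, NULL, NA_real_, NA_real_,
           list(relationship = "insufficient_data", psi = NA_real_,
                psi_ci95 = c(NA_real_, NA_real_)), NA_real_)[0, ]
}

#' Squared correlation between two scans' breakpoint estimates
#'
#' Compares sweet-spot positions between two runs (e.g. age-only versus
#' covariate-adjusted) over the records classified as sweet spots in both.
#'
#' @param scan_a,scan_b \code{"ss_scan"} objects.
#' @return list with \code{r_squared} and \code{n_common}.
#' @export
compare_breakpoints <- function(scan_a, scan_b) {
  key <- function(r) paste(r$phenotype, r$instrument, r$sex)
  a <- scan_a$records[scan_a$records$relationship == "nonmonotonic_sweet_spot", ]
  b <- scan_b$records[scan_b$records$relationship == "nonmonotonic_sweet_spot", ]
  common <- intersect(key(a), key(b))
  if (length(common) < 3)
    return(list(r_squared = NA_real_, n_common = length(common)))
  pa <- a$psi[match(common, key(a))]
  pb <- b$psi[match(common, key(b))]
  list(r_squared = stats::cor(pa, pb)^2, n_common = length(common))
}
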