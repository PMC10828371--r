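# closed-form moments of the hinge U_a = (X - a)_+ under X ~ N(0,1)
norm_hinge_mean <- function(a) stats::dnorm(a) - a * stats::pnorm(a, lower.tail = FALSE)
norm_hinge_x <- function(a) stats::pnorm(a, lower.tail = FALSE)  # E[X U_a]
# E[(X - a)(X - b); X > b] for b >= a
norm_hinge_cross <- function(a, b) {
  s <- stats::pnorm(b, lower.tail = FALSE)
  b * stats::dnorm(b) + s - (a + b) * stats::dnorm(b) + a * b * s
}

#' Analytic power of the slope-change pseudo-score test
#'
#' Computes the asymptotic rejection probability of the two-sided level
#' alpha pseudo-score test (\code{\link{score_test_slope_change}}) under a
#' one-breakpoint alternative with slope difference \code{slope_diff} at
#' breakpoint \code{psi_std}, for a standard-normal covariate and response
#' standard deviation \code{sigma}. All working-covariate moments --
#' \code{E[(X - a)_+]}, cross-products and \code{E[X (X - a)_+]} -- have
#' closed forms under the normal covariate; after projecting out the
#' intercept and linear term, the test statistic is asymptotically normal
#' with unit variance and noncentrality proportional to
#' \code{sqrt(n) * slope_diff / sigma}. Power is
#' \code{pnorm(-z + |ncp|) + pnorm(-z - |ncp|)}, which equals alpha
#' exactly at \code{slope_diff = 0}.
#'
#' @param n group sample size (>= 10).
#' @param sigma response standard deviation (score units), > 0.
#' @param psi_std breakpoint on the standardized covariate scale.
#' @param slope_diff slope difference on the standardized covariate scale.
#' @param alpha two-sided type-I error (default 0.05).
#' @param k_eval evaluation points of the test being powered (default 10,
#'   matching \code{\link{score_test_slope_change}}).
#' @return rejection probability in [0, 1].
#' @export
segmented_power <- function(n, sigma, psi_std, slope_diff, alpha = 0.05,
                            k_eval = 10L) {
  stop_if(n < 10, "group sample size must be at least 10")
  stop_if(sigma <= 0, "sigma must be positive")
  stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0,1)")
  ks <- stats::qnorm(seq_len(k_eval) / (k_eval + 1))
  mU <- vapply(ks, norm_hinge_mean, 0)
  cU <- vapply(ks, norm_hinge_x, 0)
  cross <- outer(seq_along(ks), seq_along(ks),
                 Vectorize(function(i, j)
                   norm_hinge_cross(min(ks[i], ks[j]), max(ks[i], ks[j]))))
  # test covariate M = mean_k U_k; signal covariate S = U_psi
  mM <- mean(mU); cM <- mean(cU); EMM <- mean(cross)
  mS <- norm_hinge_mean(psi_std); cS <- norm_hinge_x(psi_std)
  ESM <- mean(vapply(ks, function(k)
    norm_hinge_cross(min(psi_std, k), max(psi_std, k)), 0))
  # residual inner products after projecting onto {1, X}
  vM <- EMM - mM^2 - cM^2
  sSM <- ESM - mS * mM - cS * cM
  ncp <- sqrt(n) * abs(slope_diff) * sSM / (sigma * sqrt(vM))
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-z + ncp) + stats::pnorm(-z - ncp)
}

#' Minimal detectable slope difference at a target power
#'
#' Inverts \code{\link{segmented_power}} by root-finding: the smallest
#' slope difference (standardized covariate scale) for which the
#' slope-change score test reaches \code{target_power} at the given group
#' size, response sd and breakpoint position.
#'
#' @inheritParams segmented_power
#' @param target_power desired power, in (alpha, 1).
#' @param tol root-finding tolerance (default 1e-5).
#' @return the minimal detectable slope difference.
#' @export
min_detectable_slope_diff <- function(n, sigma, psi_std, alpha = 0.05,
                                      target_power = 0.8, tol = 1e-5) {
  stop_if(target_power <= alpha || target_power >= 1,
          "target_power must be in (alpha, 1)")
  f <- function(d) segmented_power(n, sigma, psi_std, d, alpha) - target_power
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 4
  stop_if(f(hi) < 0, "no root: target power unreachable in bracket")
  stats::uniroot(f, c(0, hi), tol = tol)$root
}

#' Select phenotypes with sufficient power for replication
#'
#' Given a primary-analysis scan, keeps the phenotypes whose largest
#' absolute standardized slope difference (across instruments and sexes)
#' exceeds the minimal detectable slope difference at the replication
#' sample size -- the phenotypes for which the replication cohort has the
#' target power.
#'
#' @param primary_scan an \code{"ss_scan"} from the primary analysis (or
#'   its \code{records} data.frame with columns \code{phenotype} and
#'   \code{delta_std}).
#' @inheritParams min_detectable_slope_diff
#' @param n_replication replication group sample size.
#' @return list with \code{phenotypes} (character vector),
#'   \code{threshold} (the minimal detectable slope difference) and
#'   \code{delta_by_phenotype}.
#' @export
select_replication_subset <- function(primary_scan, n_replication, sigma,
                                      psi_std, alpha = 0.05,
                                      target_power = 0.8) {
  rec <- if (inherits(primary_scan, "ss_scan")) primary_scan$records
         else primary_scan
  thr <- min_detectable_slope_diff(n_replication, sigma, psi_std, alpha,
                                   target_power)
  if (is.null(rec) || nrow(rec) == 0)
    return(list(phenotypes = character(), threshold = thr,
                delta_by_phenotype = numeric()))
  dmax <- tapply(abs(rec$delta_std), rec$phenotype, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else max(v)
  })
  sel <- names(dmax)[!is.na(dmax) & dmax > thr]
  list(phenotypes = sel[order(match(sel, rec$phenotype))], threshold = thr,
       delta_by_phenotype = dmax)
}
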