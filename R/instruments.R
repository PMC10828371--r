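#' Orient a test score so that higher means less healthy
#'
#' Test batteries mix scores where higher is worse (e.g. reaction time)
#' with scores where higher is better (e.g. recall). Scores with
#' \code{direction = "risk_decreases"} are negated so that every oriented
#' score increases with decline; because all composites are rank-based
#' downstream, the particular monotone inversion is immaterial.
#'
#' @param values numeric vector.
#' @param direction \code{"risk_increases"} or \code{"risk_decreases"}.
#' @return numeric vector oriented so that larger values indicate decline.
#' @export
invert_risk_direction <- function(values, direction) {
  stop_if(length(direction) != 1 ||
            !direction %in% c("risk_increases", "risk_decreases"),
          "unknown direction label '%s'", paste(direction, collapse = ","))
  if (direction == "risk_decreases") -values else values
}

#' Rank-normalize a vector to the open unit interval
#'
#' Non-missing value with average rank r among the n non-missing entries
#' maps to (r - 0.5)/n; missing entries stay missing. The transform is
#' invariant under strictly monotone transformations of the input, which
#' is what makes composites of heterogeneous tests comparable.
#'
#' @param values numeric vector, possibly with missing entries.
#' @return vector of the same length with values in (0, 1).
#' @export
rank_normalize <- function(values) {
  stop_if(all(is.na(values)), "cannot rank-normalize an all-missing vector")
  percentile_rank(values)
}

#' Deficit-accumulation frailty index
#'
#' Per participant, the mean of the non-missing deficit values (each coded
#' in [0, 1]). Participants with fewer than \code{min_prop} of the deficits
#' observed get a missing index rather than an estimate from too few items.
#'
#' @param deficit_matrix numeric matrix or data.frame, participants x
#'   deficits, entries in [0, 1] or missing.
#' @param min_prop minimum fraction of deficits that must be non-missing
#'   (default 0.8).
#' @return numeric vector of frailty-index scores in [0, 1].
#' @export
frailty_index <- function(deficit_matrix, min_prop = 0.8) {
  m <- as.matrix(deficit_matrix)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  stop_if(nrow(bad) > 0,
          "deficit value out of [0,1] at row %d, column %d",
          bad[1, 1], bad[1, 2])
  k <- rowSums(!is.na(m))
  fi <- rowSums(m, na.rm = TRUE) / k
  fi[k < min_prop * ncol(m)] <- NA_real_
  fi
}

#' Five-major-disease instrument
#'
#' Effective disease status is the disease flag OR the matching
#' medication/treatment flag (being treated for a disease confirms it).
#' The score is the number of effective diseases divided by five. Health
#' levels follow the categorical rule: no disease = healthiest (1), two
#' or more = least healthy (4), exactly one = intermediate (2, excluded
#' from two-group variance comparisons).
#'
#' @param flags matrix/data.frame of five binary disease indicators.
#' @param med_flags optional matrix/data.frame of medication/treatment
#'   indicators, one column per disease column (use a column of \code{NA}
#'   or omit columns via 0 for diseases without a medication flag).
#' @return data.frame with columns \code{score} and \code{level}.
#' @export
disease_instrument <- function(flags, med_flags = NULL) {
  f <- as.matrix(flags)
  stop_if(ncol(f) != 5, "expected five disease flags, got %d", ncol(f))
  bad <- which(!is.na(f) & !f %in% c(0, 1))
  stop_if(length(bad) > 0, "non-binary disease flag at position %d", bad[1])
  if (!is.null(med_flags)) {
    mm <- as.matrix(med_flags)
    stop_if(ncol(mm) != 5, "med_flags must have one column per disease")
    f <- pmax(f, ifelse(is.na(mm), 0, mm))        # treated => confirmed
  }
  cnt <- rowSums(f)                                # NA if any flag missing
  level <- ifelse(cnt == 0, 1L, ifelse(cnt >= 2, 4L, 2L))
  data.frame(score = cnt / 5, level = level)
}

#' Composite instrument from rank-normalized tests
#'
#' Each test is rank-normalized (tests must already be oriented so higher
#' = less healthy), tests are averaged within their domain, and domain
#' means are averaged with equal weight per domain. A participant's
#' composite is missing if any domain has no observed test for them.
#'
#' @param test_table data.frame/matrix of oriented test scores.
#' @param domain_map named character vector mapping each test column to a
#'   domain; for a flat composite map all tests to one domain.
#' @return numeric composite score vector in (0, 1).
#' @export
composite_instrument <- function(test_table, domain_map) {
  tests <- colnames(test_table)
  missing_map <- setdiff(tests, names(domain_map))
  stop_if(length(missing_map) > 0, "test '%s' absent from domain_map",
          missing_map[1])
  rn <- vapply(tests, function(tn) rank_normalize(test_table[[tn]]),
               numeric(nrow(test_table)))
  domains <- unique(domain_map[tests])
  dm <- vapply(domains, function(d) {
    cols <- tests[domain_map[tests] == d]
    rowMeans(rn[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(test_table)))
  dm[is.nan(dm)] <- NA_real_                       # domain fully missing
  out <- rowMeans(dm)                              # NA if any domain missing
  out
}

#' Pooled quartile cutoffs for a continuous instrument
#'
#' Cutoffs are the 25th, 50th and 75th percentiles of the pooled
#' non-missing scores (all ages and sexes together), using the inclusive
#' linear-interpolation quantile definition (type 7).
#'
#' @param scores numeric instrument scores.
#' @return named numeric vector \code{c(q1, q2, q3)}.
#' @export
quartile_cutoffs <- function(scores) {
  stop_if(all(is.na(scores)), "no non-missing scores")
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), na.rm = TRUE,
                       names = FALSE, type = 7)
  c(q1 = q[1], q2 = q[2], q3 = q[3])
}

#' Assign four ordinal health levels from quartile cutoffs
#'
#' Level 1 (healthiest): score < q1; level 2: q1 <= score < q2; level 3:
#' q2 <= score < q3; level 4 (least healthy): score >= q3. Ties at a
#' cutoff therefore go to the less-healthy side except below q1, matching
#' the convention that only scores strictly below the first quartile count
#' as healthiest.
#'
#' @param scores numeric instrument scores.
#' @param cutoffs numeric \code{c(q1, q2, q3)} from
#'   \code{\link{quartile_cutoffs}}.
#' @return integer vector of levels 1-4 (missing where the score is).
#' @export
assign_health_levels <- function(scores, cutoffs) {
  stop_if(length(cutoffs) != 3 || is.unsorted(cutoffs),
          "cutoffs must be three non-decreasing values")
  lv <- findInterval(scores, cutoffs, left.open = FALSE) + 1L
  lv[is.na(scores)] <- NA_integer_
  as.integer(lv)
}

#' Compute all five health instruments on a cohort
#'
#' Builds the five unit-interval health-deficit instruments and their
#' health levels: I frailty index (normalized deficit sum), II five major
#' diseases (count/5 with the categorical level rule), III other chronic
#' conditions (normalized count), IV composite cognitive score (domain
#' mean of rank-normalized tests), V physical functioning (flat mean of
#' rank-normalized tests). Levels for I, III, IV and V come from pooled
#' quartile cutoffs; Instrument II uses its categorical rule.
#'
#' @param cohort an \code{"ss_cohort"} (or a list with \code{table} and
#'   \code{meta} in the same layout).
#' @return a list of class \code{"ss_instruments"} with elements
#'   \code{scores} (data.frame \code{id}, \code{score_I..score_V},
#'   \code{level_I..level_V}) and \code{cutoffs} (per-instrument quartile
#'   cutoffs).
#' @export
build_instruments <- function(cohort) {
  tab <- cohort$table
  meta <- cohort$meta

  s1 <- frailty_index(tab[, meta$deficit_cols])
  dis <- disease_instrument(
    tab[, meta$diseases$disease_col],
    med_flags = as.data.frame(lapply(meta$diseases$med_col, function(mc)
      if (is.na(mc)) rep(NA_real_, nrow(tab)) else tab[[mc]])))
  s3 <- frailty_index(tab[, meta$chronic_cols])

  ct <- meta$cognitive_tests
  cog_oriented <- as.data.frame(lapply(seq_len(nrow(ct)), function(i)
    invert_risk_direction(tab[[ct$name[i]]], ct$direction[i])))
  names(cog_oriented) <- ct$name
  s4 <- composite_instrument(cog_oriented,
                             stats::setNames(ct$domain, ct$name))

  pt <- meta$physical_tests
  phys_oriented <- as.data.frame(lapply(seq_len(nrow(pt)), function(i)
    invert_risk_direction(tab[[pt$name[i]]], pt$direction[i])))
  names(phys_oriented) <- pt$name
  s5 <- composite_instrument(phys_oriented,
                             stats::setNames(rep("physical", nrow(pt)),
                                             pt$name))

  cont <- list(I = s1, III = s3, IV = s4, V = s5)
  cutoffs <- lapply(cont, quartile_cutoffs)
  levels <- lapply(names(cont), function(k)
    assign_health_levels(cont[[k]], cutoffs[[k]]))
  names(levels) <- names(cont)

  scores <- data.frame(id = tab[[meta$id_col]],
                       score_I = s1, score_II = dis$score, score_III = s3,
                       score_IV = s4, score_V = s5,
                       level_I = levels$I, level_II = dis$level,
                       level_III = levels$III, level_IV = levels$IV,
                       level_V = levels$V)
  structure(list(scores = scores, cutoffs = cutoffs),
            class = "ss_instruments")
}

instrument_ids <- function() c("I", "II", "III", "IV", "V")
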