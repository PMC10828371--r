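#' Generate a synthetic aging cohort with planted ground truth
#'
#' Simulates a participant table whose structure mirrors a comprehensive
#' aging-cohort assessment: demographics, binary health deficits, major
#' disease and medication flags, other chronic-condition flags, cognitive
#' and physical test scores with declared directions of risk, lifestyle
#' covariates, and continuous phenotypes with known (planted)
#' relationships to health.
#'
#' A single latent health-deficit propensity drives everything: it rises
#' linearly with age, differs by sex, and carries individual Gaussian
#' variation. Deficits and condition flags are independent Bernoulli draws
#' with probabilities increasing in the propensity, which produces the
#' right-skewed deficit scores and monotone age trends typical of
#' deficit-accumulation indices. Phenotypes are drawn around their centers
#' and feed back into the propensity according to their
#' \code{\link{phenotype_spec}}: V-shaped phenotypes raise the expected
#' deficit score linearly on either side of the planted breakpoint, so the
#' age-residualized deficit score is exactly piecewise-linear in the
#' phenotype. Phenotype noise is scaled by the latent-health percentile so
#' that the residual sd ratio between the least-healthy and healthiest
#' latent tertiles equals the spec's heteroskedasticity factor.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return an object of class \code{"ss_cohort"}: a list with elements
#'   \code{table} (data.frame, one row per participant), \code{truth}
#'   (data.frame registry of planted relationships per phenotype and sex),
#'   \code{meta} (column-role metadata used by all downstream stages) and
#'   \code{latent} (the generating latent health propensity and its
#'   percentile, kept for validation; not part of the written cohort).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants

  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- ifelse(runif(n) < config$sex_ratio, "F", "M")

  # latent health-deficit propensity (expected per-deficit probability)
  eps <- rnorm(n, 0, 0.035)
  p_base <- 0.092 - 0.011 * (sex == "M") + 0.0022 * (age - 65) + eps
  w <- percentile_rank(p_base)            # 0 = healthiest

  # lifestyle covariates (categorical, with small planted health effects)
  covs <- list(
    smoking = list(levels = c("never", "former", "current"),
                   prob = c(0.5, 0.3, 0.2),
                   effect = c(0, 0.004, 0.012)),
    alcohol = list(levels = c("never", "light_moderate", "heavy"),
                   prob = c(0.2, 0.6, 0.2),
                   effect = c(0.002, 0, 0.008)),
    education = list(levels = c("less_secondary", "secondary", "diploma",
                                "university"),
                     prob = c(0.15, 0.30, 0.30, 0.25),
                     effect = c(0.006, 0.002, 0, -0.002)),
    nutrition_risk = list(levels = c("low", "high"),
                          prob = c(0.7, 0.3),
                          effect = c(0, 0.010)))
  cov_cols <- lapply(covs, function(cv)
    sample(cv$levels, n, replace = TRUE, prob = cv$prob))
  cov_effect <- rowSums(vapply(names(covs), function(nm) {
    e <- covs[[nm]]$effect[match(cov_cols[[nm]], covs[[nm]]$levels)]
    e - mean(e)
  }, numeric(n)))

  # phenotypes: values drawn around their centers with latent-health-scaled
  # noise; their (centered) deficit contribution feeds back into the
  # propensity
  specs <- config$phenotype_specs
  phen <- matrix(NA_real_, n, length(specs),
                 dimnames = list(NULL, vapply(specs, `[[`, "", "name")))
  contrib <- numeric(n)
  truth <- do.call(rbind, lapply(specs, function(sp) {
    psi <- c(F = sp$breakpoint, M = sp$breakpoint)
    ctr <- c(F = sp$center, M = sp$center)
    if (sp$sex_specific && sp$relationship == "nonmonotonic") {
      psi["M"] <- sp$breakpoint + 0.5 * sp$base_sd
      ctr["M"] <- ctr["M"] + 0.5 * sp$base_sd
    }
    # sd interpolates across the middle latent tertile so the extreme-tertile
    # sd ratio equals the heteroskedasticity factor exactly
    sdw <- sp$base_sd *
      (1 + (sp$heteroskedasticity_factor - 1) * clamp(3 * w - 1, 0, 1))
    x <- ctr[sex] + sdw * rnorm(n)
    # the hinge contribution is centered conditionally on latent health
    # (E[(x - psi)+ | w] = sdw/sqrt(2*pi)); otherwise every phenotype whose
    # noise scales with w would inherit a spurious U-shaped conditional
    # mean from its correlation with the V-shaped phenotypes
    cc <- switch(sp$relationship,
      null = numeric(n),
      increasing = ,
      decreasing = sp$left_slope * (x - ctr[sex]),
      nonmonotonic = sp$left_slope * (x - psi[sex]) +
        (sp$right_slope - sp$left_slope) * (pmax(x - psi[sex], 0) -
          sdw / sqrt(2 * pi)))
    phen[, sp$name] <<- x
    contrib <<- contrib + (cc - mean(cc))
    data.frame(phenotype = sp$name, sex = c("F", "M"),
               relationship = sp$relationship, psi_true = unname(psi),
               left_slope = sp$left_slope, right_slope = sp$right_slope,
               heteroskedasticity_factor = sp$heteroskedasticity_factor,
               row.names = NULL)
  }))

  p <- clamp(p_base + contrib + cov_effect, 0.001, 0.95)

  draw_flags <- function(k, prob, prefix) {
    m <- matrix(rbinom(n * k, 1L, rep(prob, k)), n, k)
    colnames(m) <- sprintf("%s%02d", prefix, seq_len(k))
    m
  }
  deficits <- draw_flags(config$n_deficits, p, "deficit_")
  disease_names <- c("cancer", "cvd", "pulmonary", "dementia", "diabetes")
  p_dis <- clamp(1.37 * p, 0, 0.9)
  diseases <- matrix(rbinom(n * 5L, 1L, rep(p_dis, 5L)), n, 5L,
                     dimnames = list(NULL, paste0("disease_", disease_names)))
  med <- cbind(med_diabetes = rbinom(n, 1L, clamp(0.5 * p_dis, 0, 1)),
               med_cvd = rbinom(n, 1L, clamp(0.5 * p_dis, 0, 1)))
  chronic <- draw_flags(config$n_chronic_flags, clamp(1.3 * p, 0, 0.9),
                        "chronic_")

  # test scores: latent decline + unit noise, sign per direction of risk
  zdecline <- (p - mean(p)) / sd(p)
  gen_tests <- function(tests) {
    m <- vapply(seq_len(nrow(tests)), function(i) {
      raw <- 0.8 * zdecline + rnorm(n)       # increases with decline
      if (tests$direction[i] == "risk_decreases") -raw else raw
    }, numeric(n))
    colnames(m) <- tests$name
    m
  }
  cog <- gen_tests(config$cognitive_tests)
  phys <- gen_tests(config$physical_tests)

  tab <- data.frame(id = seq_len(n), age = age, sex = sex,
                    as.data.frame(cov_cols, stringsAsFactors = FALSE),
                    deficits, diseases, med, chronic, cog, phys, phen,
                    check.names = FALSE)

  # missingness, completely at random, per non-demographic column
  if (config$missingness_rate > 0) {
    miss_cols <- c(colnames(deficits), colnames(diseases), colnames(med),
                   colnames(chronic), colnames(cog), colnames(phys),
                   colnames(phen))
    for (cl in miss_cols)
      tab[[cl]][runif(n) < config$missingness_rate] <- NA
  }

  meta <- list(
    id_col = "id", age_col = "age", sex_col = "sex",
    covariate_cols = names(covs),
    deficit_cols = colnames(deficits),
    diseases = data.frame(
      disease_col = colnames(diseases),
      med_col = c(NA, "med_cvd", NA, NA, "med_diabetes"),
      stringsAsFactors = FALSE),
    chronic_cols = colnames(chronic),
    cognitive_tests = config$cognitive_tests,
    physical_tests = config$physical_tests,
    phenotype_cols = colnames(phen))

  structure(list(table = tab, truth = truth, meta = meta,
                 latent = data.frame(id = tab$id, propensity = p_base,
                                     percentile = w)),
            class = "ss_cohort")
}

#' @export
print.ss_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d participants, %d deficits, %d phenotypes\n",
              nrow(x$table), length(x$meta$deficit_cols),
              length(x$meta$phenotype_cols)))
  cat(sprintf("planted relationships: %s\n",
              paste(names(table(x$truth$relationship[x$truth$sex == "F"])),
                    table(x$truth$relationship[x$truth$sex == "F"]),
                    collapse = ", ")))
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' \code{write_cohort} writes \code{cohort.csv} (RFC-4180, missing values
#' as empty cells), \code{truth.json} and \code{meta.json} into \code{path};
#' \code{read_cohort} reads them back. The round trip preserves values and
#' missingness.
#'
#' @param cohort an \code{"ss_cohort"}.
#' @param path directory to write to / read from.
#' @return \code{write_cohort}: \code{path}, invisibly. \code{read_cohort}:
#'   an \code{"ss_cohort"}.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ss_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$table, file.path(path, "cohort.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(cohort$truth, file.path(path, "truth.json"),
                       digits = NA)
  jsonlite::write_json(cohort$meta, file.path(path, "meta.json"),
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  f <- file.path(path, "cohort.csv")
  stop_if(!file.exists(f), "no cohort.csv under '%s'", path)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  truth <- jsonlite::read_json(file.path(path, "truth.json"),
                               simplifyVector = TRUE)
  raw <- utils::read.csv(f, colClasses = "character", check.names = FALSE)
  need <- c(meta$id_col, meta$age_col, meta$sex_col)
  miss <- setdiff(need, names(raw))
  stop_if(length(miss) > 0, "malformed header: missing column(s) %s",
          paste(miss, collapse = ", "))
  char_cols <- c(meta$sex_col, meta$covariate_cols)
  tab <- raw
  for (cl in setdiff(names(raw), char_cols)) {
    v <- raw[[cl]]
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    stop_if(length(bad) > 0,
            "non-numeric value '%s' at row %d, column '%s'",
            v[bad[1]], bad[1], cl)
    tab[[cl]] <- num
  }
  for (cl in char_cols) tab[[cl]][tab[[cl]] == ""] <- NA
  structure(list(table = tab, truth = truth, meta = meta),
            class = "ss_cohort")
}
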