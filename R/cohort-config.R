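#' Specify a synthetic phenotype
#'
#' Describes how one continuous phenotype relates to latent health in the
#' synthetic cohort. Four relationship types are supported: \code{"null"}
#' (no mean relationship), \code{"increasing"} / \code{"decreasing"}
#' (linear association between the phenotype and the health-deficit level)
#' and \code{"nonmonotonic"} (a V-shaped relationship whose vertex -- the
#' planted sweet spot -- sits at \code{breakpoint}).
#'
#' @param name phenotype name (column name in the cohort table).
#' @param relationship one of \code{"null"}, \code{"increasing"},
#'   \code{"decreasing"}, \code{"nonmonotonic"}.
#' @param breakpoint planted sweet spot, in phenotype units
#'   (nonmonotonic only).
#' @param left_slope,right_slope deficit-score units per phenotype unit.
#'   For monotone relationships only \code{left_slope} is used (the single
#'   slope); for nonmonotonic relationships the two slopes must have
#'   opposite signs.
#' @param base_sd phenotype dispersion (sd of the generated values in the
#'   healthiest latent-health tertile), phenotype units.
#' @param center location of the phenotype distribution; defaults to
#'   \code{breakpoint} for nonmonotonic phenotypes and must be given
#'   otherwise.
#' @param heteroskedasticity_factor ratio of the residual phenotype sd in
#'   the least-healthy versus healthiest latent-health tertile (>= 1; 1 =
#'   homoskedastic).
#' @param sex_specific if \code{TRUE} the male breakpoint is shifted by
#'   half a \code{base_sd} relative to the female one.
#' @return an object of class \code{"phenotype_spec"}.
#' @export
phenotype_spec <- function(name, relationship = c("null", "increasing",
                                                  "decreasing", "nonmonotonic"),
                           breakpoint = NA_real_, left_slope = 0,
                           right_slope = 0, base_sd = 1, center = NULL,
                           heteroskedasticity_factor = 1,
                           sex_specific = FALSE) {
  relationship <- match.arg(relationship)
  stop_if(!nzchar(name), "phenotype name must be non-empty")
  stop_if(base_sd <= 0, "base_sd must be positive for '%s'", name)
  stop_if(heteroskedasticity_factor < 1,
          "heteroskedasticity_factor must be >= 1 for '%s'", name)
  if (relationship == "nonmonotonic") {
    stop_if(!is.finite(breakpoint),
            "nonmonotonic phenotype '%s' needs a finite breakpoint", name)
    stop_if(sign(left_slope) * sign(right_slope) >= 0,
            "nonmonotonic phenotype '%s' needs slopes of opposite signs", name)
    if (is.null(center)) center <- breakpoint
  } else {
    stop_if(is.null(center), "phenotype '%s' needs a center", name)
  }
  structure(list(name = name, relationship = relationship,
                 breakpoint = breakpoint, left_slope = left_slope,
                 right_slope = right_slope, base_sd = base_sd,
                 center = center,
                 heteroskedasticity_factor = heteroskedasticity_factor,
                 sex_specific = isTRUE(sex_specific)),
            class = "phenotype_spec")
}

default_cognitive_tests <- function() {
  data.frame(
    name = c("rey_recall", "mental_alternation", "animal_fluency",
             "word_association", "stroop_time", "prospective_memory",
             "reaction_time"),
    domain = c("memory", "executive", "executive", "executive", "executive",
               "executive", "psychomotor"),
    direction = c("risk_decreases", "risk_decreases", "risk_decreases",
                  "risk_decreases", "risk_increases", "risk_decreases",
                  "risk_increases"),
    stringsAsFactors = FALSE)
}

default_physical_tests <- function() {
  data.frame(
    name = c("walk_time", "tug_time", "balance_time", "chair_rise_time",
             "grip_strength"),
    direction = c("risk_increases", "risk_increases", "risk_decreases",
                  "risk_increases", "risk_decreases"),
    stringsAsFactors = FALSE)
}

#' Default phenotype panel for the synthetic cohort
#'
#' Eighteen phenotypes on realistic clinical scales: six with a planted
#' V-shaped (sweet spot) relationship to latent health, six monotone
#' (three increasing, three decreasing in health deficit) and six null.
#' Health-related phenotypes carry heteroskedasticity factors of 1.8
#' (V-shaped) and 1.4 (monotone); null phenotypes are homoskedastic, so a
#' correctly calibrated variance screen keeps the first twelve and rejects
#' the rest. Slopes are scaled per phenotype unit so that each relationship
#' moves the expected deficit score by a few hundredths across +/- 2 sd of
#' the phenotype -- comparable to the age trend, and small enough that the
#' twelve planted effects together leave the deficit-score distribution
#' (mean, spread, right skew) near its empirical calibration.
#'
#' @return a list of \code{\link{phenotype_spec}} objects.
#' @export
default_phenotype_specs <- function() {
  v <- function(name, psi, sd, sex_specific = FALSE)
    phenotype_spec(name, "nonmonotonic", breakpoint = psi,
                   left_slope = -0.0065 / sd, right_slope = 0.009 / sd,
                   base_sd = sd, heteroskedasticity_factor = 1.8,
                   sex_specific = sex_specific)
  mono <- function(name, center, sd, slope)
    phenotype_spec(name, if (slope > 0) "increasing" else "decreasing",
                   left_slope = slope / sd, base_sd = sd, center = center,
                   heteroskedasticity_factor = 1.4)
  nul <- function(name, center, sd)
    phenotype_spec(name, "null", base_sd = sd, center = center)
  list(
    v("free_thyroxine", 14.6, 2.2),
    v("albumin", 38.3, 3.0),
    v("mean_corpuscular_volume", 94, 4.5),
    v("hemoglobin", 140, 12, sex_specific = TRUE),
    v("pulse_rate", 71, 10),
    v("ldl", 2.5, 0.9),
    mono("hba1c", 5.6, 0.5, 0.012),
    mono("bmi", 27, 5, 0.012),
    mono("crp", 3, 2, 0.012),
    mono("egfr", 85, 15, -0.012),
    mono("hdl", 1.4, 0.4, -0.012),
    mono("lean_mass_index", 7.5, 1.2, -0.012),
    nul("vitamin_d", 70, 25),
    nul("sodium", 140, 2.5),
    nul("platelets", 250, 60),
    nul("tsh", 2.0, 0.9),
    nul("bone_area_rib", 120, 15),
    nul("q_onset", 436, 8))
}

#' Configure a synthetic aging cohort
#'
#' Bundles all tunables of the synthetic-cohort generator. Defaults emulate
#' the structure of a community-dwelling cohort aged 45-85: a slight female
#' majority, 51 binary deficits driving a right-skewed frailty index with a
#' female mean near 0.092, five major-disease flags plus medication flags,
#' 28 other chronic-condition flags, seven cognitive tests in three domains
#' and five physical tests with declared directions of risk.
#'
#' @param n_participants number of participants (> 0).
#' @param age_range numeric length-2, years (default 45-85).
#' @param sex_ratio fraction female (default 0.523).
#' @param n_deficits number of frailty-index deficits (default 51).
#' @param n_chronic_flags number of other chronic-condition flags
#'   (default 28).
#' @param cognitive_tests data.frame with columns \code{name},
#'   \code{domain}, \code{direction}.
#' @param physical_tests data.frame with columns \code{name},
#'   \code{direction}.
#' @param phenotype_specs list of \code{\link{phenotype_spec}} objects.
#' @param missingness_rate fraction of values set missing completely at
#'   random per deficit/test/phenotype column (default 0.02).
#' @param seed integer seed; a fixed seed yields byte-identical cohorts.
#' @return an object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_participants = 10000,
                          age_range = c(45, 85),
                          sex_ratio = 0.523,
                          n_deficits = 51,
                          n_chronic_flags = 28,
                          cognitive_tests = default_cognitive_tests(),
                          physical_tests = default_physical_tests(),
                          phenotype_specs = default_phenotype_specs(),
                          missingness_rate = 0.02,
                          seed = 1L) {
  stop_if(n_participants <= 0, "n_participants must be positive")
  stop_if(length(age_range) != 2 || age_range[1] >= age_range[2],
          "age_range must be (lo, hi) with lo < hi")
  stop_if(sex_ratio < 0 || sex_ratio > 1, "sex_ratio must be in [0,1]")
  stop_if(n_deficits <= 0, "n_deficits must be positive")
  stop_if(n_chronic_flags <= 0, "n_chronic_flags must be positive")
  stop_if(missingness_rate < 0 || missingness_rate >= 1,
          "missingness_rate must be in [0,1)")
  if (inherits(phenotype_specs, "phenotype_spec"))
    phenotype_specs <- list(phenotype_specs)
  ok <- vapply(phenotype_specs, inherits, logical(1), "phenotype_spec")
  stop_if(!all(ok), "phenotype_specs must be phenotype_spec objects")
  nm <- vapply(phenotype_specs, `[[`, character(1), "name")
  stop_if(anyDuplicated(nm) > 0, "duplicate phenotype name '%s'",
          nm[duplicated(nm)][1])
  # a planted breakpoint far outside the generated support is unrecoverable
  for (sp in phenotype_specs)
    if (sp$relationship == "nonmonotonic")
      stop_if(abs(sp$breakpoint - sp$center) > 3 * sp$base_sd,
              "breakpoint of '%s' lies outside the generated support", sp$name)
  structure(list(n_participants = as.integer(n_participants),
                 age_range = age_range, sex_ratio = sex_ratio,
                 n_deficits = as.integer(n_deficits),
                 n_disease_flags = 5L,
                 n_chronic_flags = as.integer(n_chronic_flags),
                 cognitive_tests = cognitive_tests,
                 physical_tests = physical_tests,
                 phenotype_specs = phenotype_specs,
                 missingness_rate = missingness_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}
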