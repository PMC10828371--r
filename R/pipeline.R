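#' Run the full sweet-spot discovery pipeline
#'
#' Orchestrates simulate/load -> instruments -> prefilter -> variance
#' screen -> segmented scan (-> optional covariate-adjusted scan and
#' replication plan) as one reproducible run. Each stage writes a
#' plain-text CSV; a JSON manifest records every tunable, the seed, the
#' filter counts that make the Bonferroni denominators auditable, and the
#' MD5 digest of each output file.
#'
#' The YAML config has an optional \code{simulation} block (arguments to
#' \code{\link{cohort_config}} other than \code{phenotype_specs}, which
#' uses the default panel) or a \code{cohort} entry naming a directory
#' readable by \code{\link{read_cohort}}; optional \code{prefilter}
#' (\code{r_max}, \code{miss_max}, \code{exempt}), \code{screen}
#' (\code{alpha}, \code{min_group}), \code{fit} (\code{alpha},
#' \code{k_eval}), \code{covariates} (character vector for the adjusted
#' re-run) and \code{replication} (\code{n}, \code{sigma},
#' \code{psi_std}, \code{target_power}) blocks; and a top-level
#' \code{seed}.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory stage results:
#'   \code{cohort}, \code{instruments}, \code{prefilter}, \code{screen},
#'   \code{selection}, \code{scan}, optionally \code{scan_adjusted},
#'   \code{breakpoint_comparison} and \code{replication}, plus
#'   \code{manifest}.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  log_lines <- character()
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- cohort ---------------------------------------------------------
  cohort <- stage("cohort", {
    if (!is.null(cfg$cohort)) {
      say("loading cohort from %s", cfg$cohort)
      read_cohort(cfg$cohort)
    } else {
      sim <- cfg$simulation
      if (is.null(sim)) sim <- list()
      if (is.null(sim$seed)) sim$seed <- seed + 101L
      say("simulating cohort (n = %s, seed = %d)",
          sim$n_participants %||% formals(cohort_config)$n_participants,
          sim$seed)
      generate_cohort(do.call(cohort_config, sim))
    }
  })
  phen_all <- cohort$meta$phenotype_cols

  # --- instruments ----------------------------------------------------
  instruments <- stage("instruments", build_instruments(cohort))
  utils::write.csv(instruments$scores,
                   file.path(out_dir, "instrument_scores.csv"),
                   row.names = FALSE, na = "")

  # --- prefilter ------------------------------------------------------
  pf_cfg <- cfg$prefilter %||% list()
  pf <- stage("prefilter", prefilter_phenotypes(
    cohort, phen_all,
    r_max = pf_cfg$r_max %||% 0.9,
    miss_max = pf_cfg$miss_max %||% 0.24,
    exempt = as.character(pf_cfg$exempt %||% character())))
  say("prefilter: %d of %d phenotypes kept (%d dropped)",
      length(pf$kept), length(phen_all), nrow(pf$dropped))
  utils::write.csv(pf$dropped, file.path(out_dir, "prefilter_drops.csv"),
                   row.names = FALSE)

  # --- variance screen ------------------------------------------------
  sc_cfg <- cfg$screen %||% list()
  screen <- stage("screen", run_screen(
    cohort, instruments, pf$kept,
    alpha = sc_cfg$alpha %||% 0.05,
    min_group = sc_cfg$min_group %||% 30L))
  n_skip <- sum(screen$records$skipped)
  say("screen: %d planned tests (Bonferroni m = %d), %d skipped for group size",
      nrow(screen$records), screen$m, n_skip)
  utils::write.csv(screen$records, file.path(out_dir, "screen_records.csv"),
                   row.names = FALSE, na = "")
  selection <- select_health_related(screen)
  utils::write.csv(selection, file.path(out_dir, "screen_summary.csv"),
                   row.names = FALSE, na = "")
  selected <- selection$phenotype[selection$selected]
  say("screen: %d phenotypes selected as health-related", length(selected))

  # --- segmented scan -------------------------------------------------
  fit_cfg <- cfg$fit %||% list()
  scan <- stage("fit", sweet_spot_scan(
    cohort, instruments, selected,
    alpha = fit_cfg$alpha %||% 0.05,
    k_eval = fit_cfg$k_eval %||% 10L))
  utils::write.csv(scan$records, file.path(out_dir, "scan_records.csv"),
                   row.names = FALSE, na = "")
  ss <- scan$records[scan$records$relationship == "nonmonotonic_sweet_spot", ,
                     drop = FALSE]
  bp_table <- ss[order(ss$phenotype, ss$instrument, ss$sex),
                 c("phenotype", "instrument", "sex", "psi", "psi_lo",
                   "psi_hi", "p_score_bonferroni")]
  utils::write.csv(bp_table, file.path(out_dir, "breakpoints.csv"),
                   row.names = FALSE, na = "")
  say("fit: %d fits (Bonferroni m = %d), %d sweet spots, %d non-convergent",
      nrow(scan$records), scan$m, nrow(ss),
      sum(!scan$records$converged, na.rm = TRUE))

  out <- list(cohort = cohort, instruments = instruments, prefilter = pf,
              screen = screen, selection = selection, scan = scan)

  # --- optional covariate-adjusted re-run -----------------------------
  if (!is.null(cfg$covariates)) {
    out$scan_adjusted <- stage("fit_adjusted", sweet_spot_scan(
      cohort, instruments, selected,
      covariate_set = as.character(cfg$covariates),
      alpha = fit_cfg$alpha %||% 0.05,
      k_eval = fit_cfg$k_eval %||% 10L))
    utils::write.csv(out$scan_adjusted$records,
                     file.path(out_dir, "scan_records_adjusted.csv"),
                     row.names = FALSE, na = "")
    out$breakpoint_comparison <- compare_breakpoints(scan, out$scan_adjusted)
    say("adjusted scan: r^2(adjusted, unadjusted psi) = %.3f over %d pairs",
        out$breakpoint_comparison$r_squared,
        out$breakpoint_comparison$n_common)
  }

  # --- optional replication plan --------------------------------------
  if (!is.null(cfg$replication)) {
    rp <- cfg$replication
    out$replication <- stage("replication", select_replication_subset(
      scan, n_replication = rp$n,
      sigma = rp$sigma %||% 0.07,
      psi_std = rp$psi_std %||% -0.24,
      alpha = rp$alpha %||% 0.05,
      target_power = rp$target_power %||% 0.8))
    say("replication: threshold %.4f, %d phenotypes powered",
        out$replication$threshold, length(out$replication$phenotypes))
    utils::write.csv(
      data.frame(phenotype = out$replication$phenotypes),
      file.path(out_dir, "replication_subset.csv"), row.names = FALSE)
  }

  # --- manifest -------------------------------------------------------
  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("sweetspot")),
    timestamp = format(Sys.time(), tz = "UTC"),
    tunables = list(
      quantile_type = 7L,
      prefilter = list(r_max = pf_cfg$r_max %||% 0.9,
                       miss_max = pf_cfg$miss_max %||% 0.24),
      screen = list(alpha = screen$alpha, min_group = screen$min_group,
                    bonferroni_m = screen$m),
      fit = list(alpha = fit_cfg$alpha %||% 0.05,
                 k_eval = fit_cfg$k_eval %||% 10L,
                 tol = 1e-8, bonferroni_m = scan$m)),
    counts = list(
      n_participants = nrow(cohort$table),
      phenotypes_total = length(phen_all),
      phenotypes_kept = length(pf$kept),
      phenotypes_selected = length(selected),
      screen_tests_skipped = n_skip,
      fits_nonconvergent = sum(!scan$records$converged, na.rm = TRUE),
      sweet_spots = nrow(ss)),
    file_md5 = as.list(stats::setNames(unname(tools::md5sum(files)),
                                       basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  out$manifest <- manifest
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
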