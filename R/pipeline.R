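# End-to-end orchestration: simulate/ingest -> exclusions -> segment
# metrics -> circadian profiles -> dipping + hourly tests -> (optional)
# propensity matching -> nested-CV outcome models with/without nocturnal HR.

#' Pipeline run configuration
#'
#' Defaults follow the analysis conventions used throughout the package:
#' a 48 h window after admission, 5-min segments, an hourly quorum of 3
#' segments, night 22:00-05:00 vs day 10:00-17:00, AF exclusion on, and
#' propensity matching on age and NIHSS with caliper 0.2.
#'
#' @param cohort_spec A [cohort_spec()] to simulate from, or `NULL` when
#'   reading files.
#' @param beats_csv,covariates_csv Input paths (used when `cohort_spec` is
#'   `NULL`); the covariate CSV must carry the columns of the cohort
#'   covariate table.
#' @param window_hours,segment_minutes,hourly_quorum,min_normal_beats,
#'   exclude_af,night_hours,day_hours Analysis constants.
#' @param metrics Metrics to profile (`"hr"` always included).
#' @param matching `"age_nihss"`, `"age"` or `"none"` (robustness presets).
#' @param caliper Propensity caliper multiplier.
#' @param model_families Subset of `c("logistic", "boosting")`.
#' @param model_specs Optional named list of [model_spec()] overrides.
#' @param n_shuffles Shuffle count for nested CV.
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory (created); `NULL` for no file output.
#' @return A list of class `circdip_config`.
#' @export
pipeline_config <- function(cohort_spec = NULL, beats_csv = NULL,
                            covariates_csv = NULL, window_hours = 48,
                            segment_minutes = 5, hourly_quorum = 3,
                            min_normal_beats = 5000, exclude_af = TRUE,
                            night_hours = c(22, 23, 0, 1, 2, 3, 4),
                            day_hours = 10:16,
                            metrics = c("hr", "sdnn", "rmssd", "lf", "hf"),
                            matching = c("age_nihss", "age", "none"),
                            caliper = 0.2,
                            model_families = "logistic",
                            model_specs = NULL,
                            n_shuffles = 50, seed = 1, out_dir = NULL) {
  matching <- match.arg(matching)
  structure(list(cohort_spec = cohort_spec, beats_csv = beats_csv,
                 covariates_csv = covariates_csv,
                 window_hours = window_hours,
                 segment_minutes = segment_minutes,
                 hourly_quorum = hourly_quorum,
                 min_normal_beats = min_normal_beats,
                 exclude_af = exclude_af, night_hours = night_hours,
                 day_hours = day_hours, metrics = unique(c("hr", metrics)),
                 matching = matching, caliper = caliper,
                 model_families = model_families, model_specs = model_specs,
                 n_shuffles = n_shuffles, seed = seed, out_dir = out_dir),
            class = "circdip_config")
}

write_stage <- function(obj, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.csv(obj, file.path(out_dir, paste0(name, ".csv")),
                   row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes ingest/simulate, the exclusion cascade, segment metrics,
#' circadian profiles, dipping statistics, per-hour group tests, optional
#' propensity matching, and nested-CV outcome prediction with and without
#' the nocturnal HR feature, writing every artifact (plus a manifest with
#' the seed and configuration) to `out_dir` when given.
#'
#' @param config A [pipeline_config()].
#' @return A list with all stage results (`flow`, `segments`, `profiles`,
#'   `dips`, `dip_summary`, `hourly_tests`, `match`, `cv_without_hr`,
#'   `cv_with_hr`, `comparison`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "circdip_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "ingest"
  res <- tryCatch({
    cohort <- if (!is.null(config$cohort_spec)) {
      generate_cohort(config$cohort_spec)
    } else {
      beats <- read_beat_csv(config$beats_csv)
      cov <- utils::read.csv(config$covariates_csv, stringsAsFactors = FALSE)
      cov$admission_time <- as_time(cov$admission_time)
      trop <- data.frame(patient_id = character(), sample_idx = integer(),
                         value = numeric())
      structure(list(covariates = cov, beats = beats, troponin = trop),
                class = "circdip_cohort")
    }

    stage <- "exclusions"
    excl <- apply_exclusions(cohort,
                             min_normal_beats = config$min_normal_beats,
                             exclude_af = config$exclude_af,
                             window_hours = config$window_hours)
    ana <- excl$cohort
    cohort <- NULL  # release the raw beat table
    write_stage(excl$flow, out_dir, "flow_report")
    groups <- data.frame(
      patient_id = ana$covariates$patient_id,
      group = dichotomize_outcome(ana$covariates$mrs_discharge),
      stringsAsFactors = FALSE)

    stage <- "segment_metrics"
    segments <- compute_segment_metrics(
      ana$beats, segment_minutes = config$segment_minutes,
      metrics = config$metrics)
    write_stage(segments, out_dir, "segment_metrics")

    stage <- "profiles"
    prof_metrics <- intersect(c(config$metrics,
                                if (all(c("lf", "hf") %in% config$metrics)) "lf_hf"),
                              names(metric_column))
    profiles <- lapply(stats::setNames(prof_metrics, prof_metrics),
                       function(m) cohort_profiles(segments, m,
                                                   config$hourly_quorum))
    for (m in prof_metrics) write_stage(profiles[[m]], out_dir,
                                        paste0("profile_", m))

    stage <- "dipping"
    dips <- cohort_dips(profiles$hr, config$night_hours, config$day_hours)
    dip_summary <- group_dip_summary(dips, groups)
    write_stage(dips, out_dir, "dip_results")
    write_stage(dip_summary, out_dir, "dip_summary")

    stage <- "hourly_tests"
    hourly <- lapply(profiles, hourly_group_test, groups = groups)
    for (m in names(hourly)) write_stage(hourly[[m]], out_dir,
                                         paste0("hourly_tests_", m))

    stage <- "matching"
    match_res <- NULL
    ml_cov <- ana$covariates
    if (config$matching != "none") {
      vars <- if (config$matching == "age_nihss") c("age", "nihss") else "age"
      cov_g <- ana$covariates
      cov_g$group <- groups$group[match(cov_g$patient_id, groups$patient_id)]
      cc <- stats::complete.cases(cov_g[, vars, drop = FALSE])
      cov_g <- cov_g[cc, , drop = FALSE]
      prop <- estimate_propensity(cov_g, vars = vars)
      match_res <- match_pairs(cov_g, prop, caliper = config$caliper,
                               seed = config$seed, match_vars = vars)
      write_stage(match_res$pairs, out_dir, "match_pairs")
      write_stage(match_res$balance, out_dir, "balance_table")
      ml_cov <- ana$covariates[ana$covariates$patient_id %in%
                                 match_res$matched_ids, , drop = FALSE]
    }

    stage <- "outcome_model"
    noc <- do.call(rbind, lapply(split(profiles$hr, profiles$hr$patient_id),
      function(p) data.frame(patient_id = p$patient_id[1],
                             nocturnal_hr = nocturnal_hr_feature(
                               p, config$night_hours))))
    tab_without <- feature_table(ml_cov, ana$troponin)
    tab_with <- feature_table(ml_cov, ana$troponin, nocturnal_hr = noc)
    cv_without <- cv_with <- comparison <- NULL
    if (length(config$model_families) &&
        nrow(tab_without) >= 20 && min(table(tab_without$label)) >= 10) {
      cv_without <- list(); cv_with <- list(); comparison <- list()
      for (fam in config$model_families) {
        ms <- config$model_specs[[fam]] %||%
          model_spec(if (fam == "logistic") "logistic" else "boosting")
        cv_without[[fam]] <- nested_cv_evaluate(tab_without, ms,
                                                n_shuffles = config$n_shuffles,
                                                seed = config$seed)
        cv_with[[fam]] <- nested_cv_evaluate(tab_with, ms,
                                             n_shuffles = config$n_shuffles,
                                             seed = config$seed)
        comparison[[fam]] <- compare_feature_sets(cv_without[[fam]],
                                                  cv_with[[fam]])
        write_stage(cv_without[[fam]]$folds, out_dir,
                    paste0("cv_", fam, "_without_hr"))
        write_stage(cv_with[[fam]]$folds, out_dir,
                    paste0("cv_", fam, "_with_hr"))
      }
    }

    if (!is.null(out_dir)) {
      manifest <- list(
        seed = config$seed, window_hours = config$window_hours,
        segment_minutes = config$segment_minutes,
        hourly_quorum = config$hourly_quorum,
        min_normal_beats = config$min_normal_beats,
        exclude_af = config$exclude_af, matching = config$matching,
        caliper = config$caliper, n_shuffles = config$n_shuffles,
        metrics = config$metrics,
        comparison = comparison)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
    }

    list(flow = excl$flow, cohort = ana, groups = groups,
         segments = segments, profiles = profiles, dips = dips,
         dip_summary = dip_summary, hourly_tests = hourly,
         match = match_res, nocturnal_hr = noc,
         feature_table_without_hr = tab_without,
         feature_table_with_hr = tab_with,
         cv_without_hr = cv_without, cv_with_hr = cv_with,
         comparison = comparison)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
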