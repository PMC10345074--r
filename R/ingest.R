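# Reading/writing beat-annotation and covariate tables, the exclusion
# cascade, the 48 h window trim, and derived covariate encodings.

label_codes <- c(N = "normal", P = "paced", E = "ectopic", O = "other")

#' Read a beat-annotation CSV
#'
#' Expected columns: `patient_id,time_iso8601,rr_ms,label` with labels in
#' {N, P, E, O}. Rows are validated: timestamps must parse and be strictly
#' increasing within each patient, `rr_ms` must be finite and positive,
#' labels must be known. Offending rows are reported by row number.
#'
#' @param path Path to the CSV file.
#' @return A beat-series data frame (`patient_id`, `time`, `rr_ms`, `label`).
#' @export
read_beat_csv <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character",
                                        time_iso8601 = "character",
                                        rr_ms = "numeric",
                                        label = "character"))
  need <- c("patient_id", "time_iso8601", "rr_ms", "label")
  if (!all(need %in% names(raw)))
    stop("beat CSV must have columns ", paste(need, collapse = ","), call. = FALSE)
  time <- as.POSIXct(raw$time_iso8601, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  bad <- list()
  if (any(is.na(time)))
    bad$time <- which(is.na(time))
  bad_rr <- which(!is.finite(raw$rr_ms) | raw$rr_ms <= 0)
  if (length(bad_rr)) bad$rr <- bad_rr
  bad_lab <- which(!(raw$label %in% names(label_codes)))
  if (length(bad_lab)) bad$label <- bad_lab
  mono <- unlist(lapply(split(seq_len(nrow(raw)), raw$patient_id), function(idx) {
    d <- diff(as.numeric(time[idx]))
    idx[-1][!is.na(d) & d <= 0]
  }), use.names = FALSE)
  if (length(mono)) bad$monotone <- mono
  if (length(bad)) {
    msg <- paste(vapply(names(bad), function(k)
      sprintf("%s: rows %s", c(time = "unparseable timestamp",
                               rr = "non-positive or non-finite rr_ms",
                               label = "unknown label",
                               monotone = "non-monotone time")[[k]],
              paste(utils::head(bad[[k]], 10), collapse = ",")), ""),
      collapse = "; ")
    stop("invalid beat CSV: ", msg, call. = FALSE)
  }
  data.frame(patient_id = raw$patient_id, time = time, rr_ms = raw$rr_ms,
             label = unname(label_codes[raw$label]), stringsAsFactors = FALSE)
}

#' Write a beat series to the beat-annotation CSV dialect
#'
#' @param series A beat-series data frame.
#' @param path Output path.
#' @export
write_beat_csv <- function(series, path) {
  rev_codes <- stats::setNames(names(label_codes), label_codes)
  out <- data.frame(patient_id = series$patient_id,
                    time_iso8601 = format(series$time, "%Y-%m-%dT%H:%M:%OS3",
                                          tz = "UTC"),
                    rr_ms = series$rr_ms,
                    label = unname(rev_codes[series$label]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trim a beat series to the analysis window after admission
#'
#' Keeps beats with `admission_time <= time < admission_time + hours`
#' (half-open interval).
#'
#' @param series A beat-series data frame.
#' @param admission_time Admission timestamp.
#' @param hours Window length in hours (default 48).
#' @return The trimmed series.
#' @export
trim_to_window <- function(series, admission_time, hours = 48) {
  a <- as.numeric(as_time(admission_time))
  tnum <- as.numeric(series$time)
  out <- series[tnum >= a & tnum < a + hours * 3600, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only beats annotated as normal (sinus) beats
#'
#' Paced, ectopic and other-labelled beats are dropped; surviving `rr_ms`
#' values are kept as annotated. Successive-difference statistics downstream
#' skip pairs that straddle a removed beat (detected via the time-jump rule
#' in [compute_segment_metrics()]).
#'
#' @param series A beat-series data frame.
#' @return The filtered series.
#' @export
select_normal_beats <- function(series) {
  out <- series[series$label == "normal", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Categorize serial troponin measurements
#'
#' Coding (high-sensitivity cardiac troponin, upper reference limit
#' 14 ng/l): 0 = no elevation (all samples below 14 ng/l); 1 = at least one
#' elevated sample; 2 = acute elevation — one sample above 14 ng/l and a
#' second sample differing from it by at least 20% (relative to the elevated
#' sample). Category 2 requires at least two samples.
#'
#' @param samples Ordered numeric vector of troponin values in ng/l; an
#'   empty vector yields `NA` (missing, not category 0).
#' @return Integer 0, 1 or 2, or `NA`.
#' @export
categorize_troponin <- function(samples) {
  if (length(samples) == 0L) return(NA_integer_)
  stopifnot(all(is.finite(samples)), all(samples >= 0))
  elevated <- which(samples > 14)
  if (length(elevated) == 0L) return(0L)
  if (length(samples) >= 2L) {
    for (i in elevated) {
      rel <- abs(samples[-i] - samples[i]) / samples[i]
      if (any(rel >= 0.2)) return(2L)
    }
  }
  1L
}

#' Dichotomize discharge mRS into functional outcome groups
#'
#' mRS 0-2 (able to live independently) is `good`; mRS 3-6 (any degree of
#' dependency, including death) is `unfavorable`.
#'
#' @param mrs Integer modified Rankin Scale value(s) in 0..6.
#' @return Character vector of `"good"` / `"unfavorable"`.
#' @export
dichotomize_outcome <- function(mrs) {
  if (any(!is.finite(mrs) | mrs < 0 | mrs > 6 | mrs != round(mrs)))
    stop("mrs must be integers in 0..6", call. = FALSE)
  ifelse(mrs <= 2, "good", "unfavorable")
}

#' Apply the patient exclusion cascade
#'
#' Excludes patients in the fixed order: insufficient normal beats in the
#' analysis window, then missing required covariates, then known AF
#' diagnosis, then majority-paced recordings. Each patient is counted under
#' the first criterion it fails, so the flow-report counts always sum to the
#' initial count.
#'
#' @param cohort A `circdip_cohort` (or compatible list with `covariates`,
#'   `beats`, `troponin`).
#' @param min_normal_beats Minimum number of normal-labelled beats within
#'   the window (default 5000; the insufficiency threshold is site-specific
#'   and therefore configurable).
#' @param required_fields Covariate columns that must be non-missing.
#' @param exclude_af Apply the AF exclusion (disable for the
#'   AF-included robustness preset).
#' @param window_hours Analysis window after admission used for beat counts.
#' @return A list with `cohort` (the analyzable subset, beats trimmed to the
#'   window and restricted to normal beats) and `flow` (a one-row flow
#'   report data frame).
#' @export
apply_exclusions <- function(cohort, min_normal_beats = 5000,
                             required_fields = c("age", "nihss", "gfr",
                                                 "mrs_discharge"),
                             exclude_af = TRUE, window_hours = 48) {
  cov <- cohort$covariates
  n0 <- nrow(cov)
  reason <- rep(NA_character_, n0)

  # index-based bookkeeping: the (possibly very large) beat table is
  # subset exactly once at the end
  tnum <- as.numeric(cohort$beats$time)
  lab <- cohort$beats$label
  idx_by_pat <- split(seq_along(tnum), cohort$beats$patient_id)
  kept_idx <- vector("list", n0)
  for (i in seq_len(n0)) {
    pid <- cov$patient_id[i]
    ii <- idx_by_pat[[pid]]
    a <- as.numeric(as_time(cov$admission_time[i]))
    in_win <- if (is.null(ii)) logical(0) else
      tnum[ii] >= a & tnum[ii] < a + window_hours * 3600
    ii <- ii[in_win]
    n_normal <- sum(lab[ii] == "normal")
    frac_paced <- if (length(ii) > 0) mean(lab[ii] == "paced") else 0
    if (is.na(reason[i]) && n_normal < min_normal_beats)
      reason[i] <- "insufficient_beats"
    if (is.na(reason[i]) &&
        anyNA(unlist(cov[i, required_fields], use.names = FALSE)))
      reason[i] <- "missing_fields"
    if (is.na(reason[i]) && exclude_af && isTRUE(cov$af_diagnosis[i]))
      reason[i] <- "af"
    if (is.na(reason[i]) && frac_paced > 0.5)
      reason[i] <- "paced"
    if (is.na(reason[i])) kept_idx[[i]] <- ii[lab[ii] == "normal"]
  }
  keep <- is.na(reason)
  flow <- data.frame(
    initial = n0,
    excluded_insufficient_beats = sum(reason == "insufficient_beats", na.rm = TRUE),
    excluded_missing_fields = sum(reason == "missing_fields", na.rm = TRUE),
    excluded_af = sum(reason == "af", na.rm = TRUE),
    excluded_paced = sum(reason == "paced", na.rm = TRUE),
    analyzable = sum(keep))
  kept_ids <- cov$patient_id[keep]
  beats <- cohort$beats[unlist(kept_idx), , drop = FALSE]
  rownames(beats) <- NULL
  out <- list(covariates = cov[keep, , drop = FALSE],
              beats = beats,
              troponin = cohort$troponin[
                cohort$troponin$patient_id %in% kept_ids, , drop = FALSE])
  rownames(out$covariates) <- NULL
  structure(list(cohort = structure(out, class = "circdip_cohort"),
                 flow = flow), class = "circdip_exclusion")
}
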