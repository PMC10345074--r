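# Nocturnal dipping statistic, group summaries and per-hour group tests.

night_hours_default <- c(22, 23, 0, 1, 2, 3, 4)   # 22:00-05:00
day_hours_default <- 10:16                        # 10:00-17:00

#' Nocturnal heart-rate dip of one circadian profile
#'
#' Compares the unweighted mean of available hourly HR values during night
#' hours (22:00-05:00) with the daytime average (10:00-17:00);
#' `percent_decline = 100 * (day - night) / day`. Negative values indicate
#' reverse dipping (nocturnal risers).
#'
#' @param profile One patient's HR profile (from [build_profile()]).
#' @param night_hours,day_hours Clock-hour sets defining the windows.
#' @return One-row data frame: `patient_id`, `day_mean_hr`, `night_mean_hr`,
#'   `percent_decline`, `n_day_slots`, `n_night_slots`, `available`.
#' @export
nocturnal_dip <- function(profile, night_hours = night_hours_default,
                          day_hours = day_hours_default) {
  dvals <- profile$value[profile$hour %in% day_hours]
  nvals <- profile$value[profile$hour %in% night_hours]
  dvals <- dvals[!is.na(dvals)]; nvals <- nvals[!is.na(nvals)]
  ok <- length(dvals) >= 1L && length(nvals) >= 1L
  day <- if (ok) mean(dvals) else NA_real_
  night <- if (ok) mean(nvals) else NA_real_
  data.frame(patient_id = profile$patient_id[1],
             day_mean_hr = day, night_mean_hr = night,
             percent_decline = if (ok) 100 * (day - night) / day else NA_real_,
             n_day_slots = length(dvals), n_night_slots = length(nvals),
             available = ok, stringsAsFactors = FALSE)
}

#' Nocturnal dips for every patient in a profile table
#'
#' @param profiles Long HR profile table (from [cohort_profiles()]).
#' @inheritParams nocturnal_dip
#' @return Data frame of per-patient dip results.
#' @export
cohort_dips <- function(profiles, night_hours = night_hours_default,
                        day_hours = day_hours_default) {
  out <- do.call(rbind, lapply(split(profiles, profiles$patient_id),
                               nocturnal_dip, night_hours = night_hours,
                               day_hours = day_hours))
  rownames(out) <- NULL
  out
}

#' Group mean and standard error of the nocturnal dip
#'
#' @param dips Per-patient dip results (from [cohort_dips()]).
#' @param groups Data frame `patient_id`, `group`.
#' @return Data frame `group`, `mean_percent_decline`, `sem`, `n`.
#' @export
group_dip_summary <- function(dips, groups) {
  m <- merge(dips, groups, by = "patient_id")
  m <- m[m$available & !is.na(m$percent_decline), , drop = FALSE]
  out <- do.call(rbind, lapply(split(m, m$group), function(d)
    data.frame(group = d$group[1],
               mean_percent_decline = mean(d$percent_decline),
               sem = sem(d$percent_decline), n = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Per-hour two-group Mann-Whitney tests with Bonferroni correction
#'
#' For each clock hour, compares patient-level hourly values between the two
#' groups with a two-sided Mann-Whitney U test. The Bonferroni factor is
#' fixed at 24 (the number of clock hours) regardless of how many hours were
#' testable, a conservative convention. Hours where either group contributes
#' fewer than 2 values are reported untested.
#'
#' @param profiles Long profile table for one metric.
#' @param groups Data frame `patient_id`, `group` (exactly two groups).
#' @param alpha Family-wise significance level (default 0.05).
#' @return 24-row data frame: `hour`, `n_group1`, `n_group2`, `u_statistic`,
#'   `p_raw`, `p_bonferroni`, `significant`, `tested`.
#' @export
hourly_group_test <- function(profiles, groups, alpha = 0.05) {
  m <- merge(profiles, groups, by = "patient_id")
  glev <- sort(unique(m$group))
  stopifnot(length(glev) == 2L)
  res <- lapply(0:23, function(h) {
    d <- m[m$hour == h & !is.na(m$value), , drop = FALSE]
    x <- d$value[d$group == glev[1]]
    y <- d$value[d$group == glev[2]]
    if (length(x) < 2L || length(y) < 2L)
      return(data.frame(hour = h, n_group1 = length(x), n_group2 = length(y),
                        u_statistic = NA_real_, p_raw = NA_real_,
                        p_bonferroni = NA_real_, significant = FALSE,
                        tested = FALSE))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    pb <- min(1, 24 * wt$p.value)
    data.frame(hour = h, n_group1 = length(x), n_group2 = length(y),
               u_statistic = unname(wt$statistic), p_raw = wt$p.value,
               p_bonferroni = pb, significant = pb < alpha, tested = TRUE)
  })
  out <- do.call(rbind, res)
  attr(out, "groups") <- glev
  out
}

#' Nocturnal HR feature for outcome prediction
#'
#' The mean HR from 22:00 to 05:00 (unweighted over available hourly
#' slots); fed to the outcome models as an independent parameter.
#'
#' @param profile One patient's HR profile.
#' @param night_hours Clock hours of the night window.
#' @return Mean nocturnal HR in bpm, or `NA` when no night slot is
#'   available (such patients are dropped from the ML stage with a logged
#'   count).
#' @export
nocturnal_hr_feature <- function(profile, night_hours = night_hours_default) {
  v <- profile$value[profile$hour %in% night_hours]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}
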