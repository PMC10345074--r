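# 5-min segment metrics (HR, SDNN, RMSSD, LF, HF, LF/HF) and hour-of-day
# circadian profiles.

#' Assign beats to wall-clock 5-minute segments
#'
#' Beats are binned on the wall-clock grid (hh:00, hh:05, ...), half-open;
#' each beat falls in exactly one segment. The grid is clock-aligned rather
#' than admission-aligned because hour-of-day profiling is clock-relative.
#'
#' @param series A beat-series data frame (already trimmed to the analysis
#'   window).
#' @param segment_minutes Segment length in minutes (default 5).
#' @return The series with a `segment_start` POSIXct column added.
#' @export
segment_series <- function(series, segment_minutes = 5) {
  step <- segment_minutes * 60
  series$segment_start <- as.POSIXct(
    floor(as.numeric(series$time) / step) * step,
    origin = "1970-01-01", tz = "UTC")
  series
}

# Population SD (the segment is the full population of its beats).
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# RMSSD over valid successive pairs: a pair is skipped when the time jump
# between the two beats exceeds 2x the segment's median RR (it then straddles
# a removed beat or gap and would inflate the statistic artifactually).
rmssd_valid <- function(rr, time_s) {
  if (length(rr) < 3L) return(NA_real_)
  dt_ms <- diff(time_s) * 1000
  valid <- dt_ms <= 2 * stats::median(rr)
  d <- diff(rr)[valid]
  if (length(d) < 2L) return(NA_real_)
  sqrt(mean(d^2))
}

#' Spectral band power of one segment's RR tachogram
#'
#' Builds the tachogram (cumulative beat time vs RR), interpolates it with a
#' cubic smoothing spline, resamples on a uniform grid (default 4 Hz),
#' removes the grid mean, estimates the one-sided periodogram PSD (ms^2/Hz)
#' and integrates it over the LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands
#' by the rectangle rule.
#'
#' @param time_s Beat times in seconds (any origin).
#' @param rr_ms RR intervals in ms.
#' @param resample_hz Uniform resampling rate in Hz; 4 Hz gives a Nyquist
#'   frequency of 2 Hz, far above the 0.4 Hz band edge.
#' @param spline_spar Smoothing parameter for [stats::smooth.spline()];
#'   `0` requests a near-interpolating spline (the default), larger values
#'   smooth more.
#' @param min_beats,min_span_s Minimum beats and minimum spanned seconds
#'   required to resolve the 0.04 Hz band edge; below these the result is
#'   missing.
#' @return Named vector `c(lf_ms2, hf_ms2)` (or `NA`s).
#' @export
segment_spectral <- function(time_s, rr_ms, resample_hz = 4,
                             spline_spar = 0, min_beats = 16,
                             min_span_s = 150) {
  n <- length(rr_ms)
  if (n < min_beats || (time_s[n] - time_s[1]) < min_span_s)
    return(c(lf_ms2 = NA_real_, hf_ms2 = NA_real_))
  if (stats::var(rr_ms) < 1e-12)
    return(c(lf_ms2 = 0, hf_ms2 = 0))
  x <- time_s - time_s[1]
  interp <- if (spline_spar > 0) {
    fit <- stats::smooth.spline(x, rr_ms, spar = spline_spar)
    function(g) stats::predict(fit, g)$y
  } else {
    stats::splinefun(x, rr_ms, method = "fmm")
  }
  grid <- seq(0, x[length(x)], by = 1 / resample_hz)
  y <- interp(grid)
  y <- y - mean(y)
  m <- length(y)
  # one-sided periodogram PSD: sum(psd) * df equals the grid variance
  spec <- Mod(stats::fft(y))^2 / (m * resample_hz)
  nf <- floor(m / 2)
  freq <- (1:nf) * resample_hz / m
  psd <- 2 * spec[2:(nf + 1)]
  if (m %% 2 == 0) psd[nf] <- psd[nf] / 2
  df <- resample_hz / m
  lf <- sum(psd[freq >= 0.04 & freq < 0.15]) * df
  hf <- sum(psd[freq >= 0.15 & freq < 0.4]) * df
  c(lf_ms2 = lf, hf_ms2 = hf)
}

#' Compute per-segment HR and HRV metrics
#'
#' Splits a (trimmed, normal-beats-only) series into wall-clock 5-min
#' segments and computes, per segment: HR as the median of the per-beat
#' instantaneous rates 60000/RR; SDNN as the population SD of RR; RMSSD over
#' valid successive pairs; and LF/HF band powers via
#' [segment_spectral()]. Metrics are missing below the per-segment quorum.
#'
#' @param series A beat-series data frame for one or more patients.
#' @param segment_minutes Segment length (default 5 min).
#' @param min_beats Per-segment minimum beat count for HR/SDNN/RMSSD
#'   (default 30, roughly a 10% duty cycle at 60 bpm).
#' @param metrics Character subset of `c("hr","sdnn","rmssd","lf","hf")`;
#'   restricting to `"hr"` skips the costly spectral step for HR-only runs.
#' @param spectral_min_beats,spectral_min_span_s,resample_hz,spline_spar
#'   Passed to [segment_spectral()].
#' @return A data frame, one row per patient x non-empty segment, with
#'   columns `patient_id`, `segment_start`, `n_beats`, `hr_bpm`, `sdnn_ms`,
#'   `rmssd_ms`, `lf_ms2`, `hf_ms2`, `lf_hf_ratio`.
#' @export
compute_segment_metrics <- function(series, segment_minutes = 5,
                                    min_beats = 30,
                                    metrics = c("hr", "sdnn", "rmssd",
                                                "lf", "hf"),
                                    spectral_min_beats = 16,
                                    spectral_min_span_s = 150,
                                    resample_hz = 4, spline_spar = 0) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (nrow(series) == 0L)
    return(data.frame(patient_id = character(), segment_start = as_time(character()),
                      n_beats = integer(), hr_bpm = numeric(), sdnn_ms = numeric(),
                      rmssd_ms = numeric(), lf_ms2 = numeric(), hf_ms2 = numeric(),
                      lf_hf_ratio = numeric()))
  step <- segment_minutes * 60
  tnum <- as.numeric(series$time)
  ord <- order(series$patient_id, tnum)
  pids <- series$patient_id[ord]
  tnum <- tnum[ord]
  rr_all <- series$rr_ms[ord]
  seg_all <- floor(tnum / step) * step
  # run-length group boundaries on the sorted (patient, segment) keys
  n_row <- length(tnum)
  new_grp <- c(TRUE, pids[-1] != pids[-n_row] | seg_all[-1] != seg_all[-n_row])
  starts <- which(new_grp)
  ends <- c(starts[-1] - 1L, n_row)
  want_spec <- any(c("lf", "hf") %in% metrics)
  ns <- length(starts)
  pid <- character(ns); seg_start <- numeric(ns); nb <- integer(ns)
  hr <- sdnn <- rmssd <- lf <- hf <- rep(NA_real_, ns)
  for (j in seq_len(ns)) {
    ii <- starts[j]:ends[j]
    rr <- rr_all[ii]
    ts <- tnum[ii]
    pid[j] <- pids[starts[j]]
    seg_start[j] <- seg_all[starts[j]]
    nb[j] <- length(ii)
    if (nb[j] >= min_beats) {
      if ("hr" %in% metrics) hr[j] <- stats::median(60000 / rr)
      if ("sdnn" %in% metrics) sdnn[j] <- sd_pop(rr)
      if ("rmssd" %in% metrics) rmssd[j] <- rmssd_valid(rr, ts)
      if (want_spec) {
        sp <- segment_spectral(ts, rr, resample_hz, spline_spar,
                               spectral_min_beats, spectral_min_span_s)
        lf[j] <- sp[["lf_ms2"]]; hf[j] <- sp[["hf_ms2"]]
      }
    }
  }
  data.frame(patient_id = pid,
             segment_start = as.POSIXct(seg_start, origin = "1970-01-01",
                                        tz = "UTC"),
             n_beats = nb, hr_bpm = hr, sdnn_ms = sdnn, rmssd_ms = rmssd,
             lf_ms2 = lf, hf_ms2 = hf,
             lf_hf_ratio = ifelse(!is.na(hf) & hf > 0, lf / hf, NA_real_),
             stringsAsFactors = FALSE)
}

metric_column <- c(hr = "hr_bpm", sdnn = "sdnn_ms", rmssd = "rmssd_ms",
                   lf = "lf_ms2", hf = "hf_ms2", lf_hf = "lf_hf_ratio")

#' Build an hour-of-day circadian profile for one metric
#'
#' Aggregates segment values into 24 clock-hour slots (both recording days
#' pooled): the hourly value is the median over contributing segments, and a
#' slot is emitted only when at least `quorum` of the possible 24 5-min
#' segments for that hour are available.
#'
#' @param segments Segment metrics for one patient
#'   (from [compute_segment_metrics()]).
#' @param metric One of `"hr"`, `"sdnn"`, `"rmssd"`, `"lf"`, `"hf"`,
#'   `"lf_hf"`.
#' @param quorum Minimum contributing segments per hour (default 3).
#' @return A data frame with 24 rows: `patient_id`, `metric`, `hour` (0-23),
#'   `value` (NA when below quorum), `n_segments`.
#' @export
build_profile <- function(segments, metric = "hr", quorum = 3) {
  metric <- match.arg(metric, names(metric_column))
  stopifnot(length(unique(segments$patient_id)) <= 1L)
  col <- metric_column[[metric]]
  hour <- clock_hour(segments$segment_start)
  ok <- !is.na(segments[[col]])
  counts <- tabulate(hour[ok] + 1L, nbins = 24L)
  vals <- rep(NA_real_, 24)
  for (h in which(counts >= quorum)) {
    vals[h] <- stats::median(segments[[col]][ok & hour == h - 1L])
  }
  data.frame(patient_id = if (nrow(segments)) segments$patient_id[1] else NA_character_,
             metric = metric, hour = 0:23, value = vals,
             n_segments = counts, stringsAsFactors = FALSE)
}

#' Circadian profiles for every patient in a segment table
#'
#' @param segments Segment metrics for multiple patients.
#' @param metric,quorum As in [build_profile()].
#' @return Long data frame of per-patient hourly profiles.
#' @export
cohort_profiles <- function(segments, metric = "hr", quorum = 3) {
  parts <- lapply(split(segments, segments$patient_id), build_profile,
                  metric = metric, quorum = quorum)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Per-hour group mean and SD of circadian profiles
#'
#' @param profiles Long profile table (from [cohort_profiles()]).
#' @param groups Data frame `patient_id`, `group`.
#' @return Data frame `group`, `hour`, `mean`, `sd`, `n_patients` (patients
#'   contributing that hour slot).
#' @export
cohort_profile_summary <- function(profiles, groups) {
  m <- merge(profiles, groups, by = "patient_id")
  m <- m[!is.na(m$value), , drop = FALSE]
  agg <- do.call(rbind, lapply(split(m, list(m$group, m$hour), drop = TRUE),
    function(d) data.frame(group = d$group[1], hour = d$hour[1],
                           mean = mean(d$value),
                           sd = if (nrow(d) > 1) stats::sd(d$value) else 0,
                           n_patients = nrow(d))))
  agg <- agg[order(agg$group, agg$hour), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
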