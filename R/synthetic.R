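# Synthetic cohort generator: RR-interval series with circadian HR
# modulation, LF/HF oscillations, beat-label noise, gaps, AF-like rhythms,
# and clinical covariates with a logistic outcome link. Everything is
# seed-deterministic so downstream stages are testable without patient data.

#' Specification of a circadian heart-rate generator
#'
#' Describes one patient's (or one group's) generative heart-rate process:
#' a daytime baseline HR with a smooth nocturnal dip, two in-band sinusoidal
#' RR oscillations (one in the LF band 0.04-0.15 Hz, one in the HF band
#' 0.15-0.4 Hz) and additive Gaussian RR noise.
#'
#' @param baseline_day_hr Daytime heart rate in beats/min (> 0).
#' @param dip_fraction Relative nocturnal HR reduction in `[0, 1)`; night HR
#'   is `baseline_day_hr * (1 - dip_fraction)`.
#' @param night_window Pair of clock hours `c(start, end)`; default `c(22, 5)`
#'   (crosses midnight).
#' @param transition_minutes Minutes of smooth (raised-cosine) ramp between
#'   day and night HR levels.
#' @param lf_amplitude_ms,lf_freq_hz Amplitude (ms) and frequency (Hz) of the
#'   low-frequency RR oscillation; the frequency must lie strictly inside
#'   `[0.04, 0.15)`.
#' @param hf_amplitude_ms,hf_freq_hz Amplitude (ms) and frequency (Hz) of the
#'   high-frequency RR oscillation; the frequency must lie strictly inside
#'   `[0.15, 0.4)`.
#' @param noise_sd_ms Standard deviation (ms) of additive Gaussian RR noise.
#' @return An object of class `circadian_hr_spec`.
#' @export
circadian_hr_spec <- function(baseline_day_hr = 76, dip_fraction = 0.105,
                              night_window = c(22, 5), transition_minutes = 60,
                              lf_amplitude_ms = 37, lf_freq_hz = 0.10,
                              hf_amplitude_ms = 45, hf_freq_hz = 0.25,
                              noise_sd_ms = 24) {
  check_number(baseline_day_hr, "baseline_day_hr", lower = 0, strict_lower = TRUE)
  check_number(dip_fraction, "dip_fraction", lower = 0, upper = 1, strict_upper = TRUE)
  if (length(night_window) != 2L || any(!is.finite(night_window)) ||
      any(night_window < 0) || any(night_window >= 24))
    stop_field("night_window", "must be two clock hours in [0, 24)")
  check_number(transition_minutes, "transition_minutes", lower = 0)
  check_number(lf_amplitude_ms, "lf_amplitude_ms", lower = 0)
  check_number(hf_amplitude_ms, "hf_amplitude_ms", lower = 0)
  check_number(noise_sd_ms, "noise_sd_ms", lower = 0)
  check_number(lf_freq_hz, "lf_freq_hz", lower = 0.04, upper = 0.15,
               strict_upper = TRUE)
  check_number(hf_freq_hz, "hf_freq_hz", lower = 0.15, upper = 0.4,
               strict_upper = TRUE)
  structure(list(baseline_day_hr = baseline_day_hr, dip_fraction = dip_fraction,
                 night_window = as.numeric(night_window),
                 transition_minutes = transition_minutes,
                 lf_amplitude_ms = lf_amplitude_ms, lf_freq_hz = lf_freq_hz,
                 hf_amplitude_ms = hf_amplitude_ms, hf_freq_hz = hf_freq_hz,
                 noise_sd_ms = noise_sd_ms),
            class = "circadian_hr_spec")
}

# Night weight w(hod) in [0,1]: 0 by day, 1 on the nocturnal plateau, with
# raised-cosine ramps of `transition_minutes` centred on each window edge
# (so the ramp midpoint sits exactly at the stated clock boundary and hourly
# medians are not systematically shifted by the transition).
night_weight <- function(hod, night_window = c(22, 5), transition_minutes = 60) {
  n0 <- night_window[1]; n1 <- night_window[2]
  len <- (n1 - n0) %% 24
  tt <- transition_minutes / 60
  s <- (hod - n0) %% 24
  w <- numeric(length(s))
  if (tt > 0) {
    h <- tt / 2
    u <- ((hod - n0 + 12) %% 24) - 12   # signed offset from night start
    v <- ((hod - n1 + 12) %% 24) - 12   # signed offset from night end
    up <- abs(u) <= h
    down <- abs(v) <= h
    w[s < len] <- 1
    w[up] <- (1 - cos(pi * (u[up] + h) / tt)) / 2
    w[down] <- (1 + cos(pi * (v[down] + h) / tt)) / 2
  } else {
    w[s < len] <- 1
  }
  w
}

#' Generate a synthetic beat-annotation series
#'
#' Simulates a timestamped RR-interval series whose instantaneous target
#' heart rate is `baseline_day_hr * (1 - dip_fraction * w(t))`, where `w(t)`
#' ramps smoothly into and out of the night window. Each interval is
#' `60000 / h(t_i)` plus the LF and HF sinusoids evaluated at the beat time
#' plus Gaussian noise, floored at 300 ms and capped at 2000 ms; beat times
#' are the cumulative sum of the intervals. All beats are labelled `normal`.
#'
#' The mutual dependence of beat times and intervals is resolved by a
#' vectorized fixed-point iteration (the modulations are slow and small
#' relative to the beat period, so a handful of sweeps converge to a
#' self-consistent series).
#'
#' @param spec A [circadian_hr_spec()].
#' @param start_clock_time Timestamp of the series start (clock time drives
#'   the circadian modulation).
#' @param duration_hours Length of the recording in hours (> 0).
#' @param seed Integer seed; identical inputs give identical series.
#' @param patient_id Identifier stored on the series.
#' @return A beat-series data frame with columns `patient_id`, `time`
#'   (POSIXct), `rr_ms`, `label`.
#' @export
generate_rr_series <- function(spec, start_clock_time, duration_hours, seed,
                               patient_id = "sim") {
  stopifnot(inherits(spec, "circadian_hr_spec"))
  check_number(duration_hours, "duration_hours", lower = 0, strict_lower = TRUE)
  start <- as_time(start_clock_time)
  dur_s <- duration_hours * 3600
  n_max <- ceiling(dur_s * spec$baseline_day_hr / 60 * 1.2) + 16L

  set.seed(seed)
  noise <- if (spec$noise_sd_ms > 0) stats::rnorm(n_max, 0, spec$noise_sd_ms)
           else numeric(n_max)

  start_hod <- hour_of_day(start)
  # 4 sweeps: the circadian/oscillatory modulation is slow and small
  # relative to the beat period, so the fixed point converges to well below
  # 1e-6 relative error by the fourth sweep
  rr <- rep(60000 / spec$baseline_day_hr, n_max)
  for (k in seq_len(4L)) {
    t_s <- cumsum(rr) / 1000
    hod <- (start_hod + t_s / 3600) %% 24
    w <- night_weight(hod, spec$night_window, spec$transition_minutes)
    h <- spec$baseline_day_hr * (1 - spec$dip_fraction * w)
    rr_new <- 60000 / h +
      spec$lf_amplitude_ms * sin(2 * pi * spec$lf_freq_hz * t_s) +
      spec$hf_amplitude_ms * sin(2 * pi * spec$hf_freq_hz * t_s) +
      noise
    rr <- pmin(pmax(rr_new, 300), 2000)
  }
  t_s <- cumsum(rr) / 1000
  # strict half-open window; the microsecond guard keeps beats whose exact
  # cumulative time equals the boundary from leaking in via rounding
  keep <- t_s < dur_s - 1e-6
  data.frame(patient_id = patient_id,
             time = start + t_s[keep],
             rr_ms = rr[keep],
             label = "normal",
             stringsAsFactors = FALSE)
}

# AF-like series: irregularly irregular RR as exp of a Gaussian AR(1),
# rescaled to a target mean; no circadian structure.
generate_af_series <- function(start_clock_time, duration_hours, seed,
                               patient_id = "sim", mean_rr_ms = 800,
                               ar_phi = 0.4, log_sd = 0.25) {
  start <- as_time(start_clock_time)
  dur_s <- duration_hours * 3600
  n_max <- ceiling(dur_s * 1000 / mean_rr_ms * 1.6) + 16L
  set.seed(seed)
  innov <- stats::rnorm(n_max, 0, log_sd * sqrt(1 - ar_phi^2))
  x <- as.numeric(stats::filter(innov, ar_phi, method = "recursive"))
  rr <- exp(x)
  rr <- rr * (mean_rr_ms / mean(rr))
  rr <- pmin(pmax(rr, 300), 2000)
  t_s <- cumsum(rr) / 1000
  keep <- t_s < dur_s
  data.frame(patient_id = patient_id, time = start + t_s[keep],
             rr_ms = rr[keep], label = "normal", stringsAsFactors = FALSE)
}

#' Inject beat-label artifacts and recording gaps into a series
#'
#' Relabels a random fraction of beats as ectopic — the annotated interval is
#' shortened to 0.6x (premature beat) and the following beat lengthened to
#' 1.4x (compensatory pause) — and removes all beats inside the given gaps.
#' Timestamps are left untouched (the series emulates monitor annotations,
#' not a re-synthesized rhythm).
#'
#' @param series A beat-series data frame.
#' @param ectopic_fraction Per-beat probability of ectopic relabelling.
#' @param gaps A data frame with columns `start` (timestamp) and
#'   `duration_min`, or `NULL`; gaps must not overlap.
#' @param seed Integer seed for the ectopic sampler.
#' @return The modified beat-series data frame.
#' @export
inject_artifacts <- function(series, ectopic_fraction = 0, gaps = NULL,
                             seed = 1) {
  stopifnot(nrow(series) > 0)
  check_number(ectopic_fraction, "ectopic_fraction", lower = 0, upper = 1)
  if (ectopic_fraction > 0) {
    set.seed(seed)
    hit <- which(stats::runif(nrow(series)) < ectopic_fraction)
    if (length(hit)) {
      series$label[hit] <- "ectopic"
      series$rr_ms[hit] <- series$rr_ms[hit] * 0.6
      nxt <- hit + 1L
      nxt <- nxt[nxt <= nrow(series)]
      series$rr_ms[nxt] <- series$rr_ms[nxt] * 1.4
    }
  }
  if (!is.null(gaps) && nrow(gaps) > 0) {
    gs <- as.numeric(as_time(gaps$start))
    ge <- gs + gaps$duration_min * 60
    o <- order(gs)
    if (any(ge[o][-length(o)] > gs[o][-1]))
      stop("overlapping gaps", call. = FALSE)
    tnum <- as.numeric(series$time)
    drop <- rep(FALSE, nrow(series))
    for (i in seq_along(gs)) drop <- drop | (tnum >= gs[i] & tnum < ge[i])
    series <- series[!drop, , drop = FALSE]
    rownames(series) <- NULL
  }
  series
}

#' Specification of a synthetic stroke cohort
#'
#' Bundles the generative parameters for a two-group cohort: per-group
#' circadian HR specs, covariate distributions, a logistic outcome link,
#' missingness and artifact rates, and a master seed. Defaults emulate an
#' elderly stroke-unit population with covariate imbalance between outcome
#' groups (mean age ~72 vs ~77 years, median NIHSS ~5 vs ~6) and a more
#' pronounced nocturnal HR dip in the good-outcome group.
#'
#' The logistic outcome link applies `outcome_coefficients` to centred and
#' scaled versions of age ((age-74)/10), NIHSS ((nihss-5)/5), the patient's
#' generative dip fraction ((dip-0.08)/0.05), generative nocturnal HR
#' ((hr_night-68)/8) and the comorbidity count, so coefficients are on
#' comparable scales.
#'
#' @param n_good,n_unfavorable Group sizes before exclusions.
#' @param hr_spec_good,hr_spec_unfavorable [circadian_hr_spec()] per group.
#' @param covariate_params Named list of distribution parameters; see
#'   defaults in the function definition.
#' @param outcome_coefficients Named vector: `intercept`, `age`, `nihss`,
#'   `dip`, `nocturnal_hr`, `comorbidity`.
#' @param missingness_rates Named per-field missing-data probabilities
#'   (`nihss`, `gfr`, `troponin`).
#' @param artifact_rates Named list: `ectopic_fraction`, `paced_fraction`,
#'   `af_fraction`, `mean_gaps` (expected number of 30-min gaps per patient).
#' @param duration_hours Recording length per patient.
#' @param seed Master seed; identical spec implies identical cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_good = 100, n_unfavorable = 100,
                        hr_spec_good = circadian_hr_spec(baseline_day_hr = 76,
                                                         dip_fraction = 0.105),
                        hr_spec_unfavorable = circadian_hr_spec(baseline_day_hr = 78,
                                                                dip_fraction = 0.063),
                        covariate_params = list(
                          age_mean = c(good = 71.8, unfavorable = 76.6),
                          age_sd = 10,
                          nihss_lambda = c(good = 5, unfavorable = 6),
                          prop_female = c(good = 0.39, unfavorable = 0.51),
                          hypertension = c(good = 0.74, unfavorable = 0.91),
                          diabetes = c(good = 0.28, unfavorable = 0.30),
                          prior_mi = c(good = 0.01, unfavorable = 0.01),
                          cad = c(good = 0.10, unfavorable = 0.08),
                          pneumonia = c(good = 0.01, unfavorable = 0.08),
                          prop_hemorrhagic = c(good = 0.06, unfavorable = 0.15),
                          gfr_mean = 74, gfr_sd = 20,
                          troponin_meanlog = c(good = log(10), unfavorable = log(14)),
                          troponin_sdlog = 0.6),
                        outcome_coefficients = c(intercept = 0, age = 0.5,
                                                 nihss = 0.8, dip = -1.2,
                                                 nocturnal_hr = 1.0,
                                                 comorbidity = 0.2),
                        missingness_rates = c(nihss = 0, gfr = 0, troponin = 0),
                        artifact_rates = list(ectopic_fraction = 0.01,
                                              paced_fraction = 0.0,
                                              af_fraction = 0.0,
                                              mean_gaps = 1),
                        duration_hours = 48, seed = 1L) {
  stopifnot(n_good >= 0, n_unfavorable >= 0,
            inherits(hr_spec_good, "circadian_hr_spec"),
            inherits(hr_spec_unfavorable, "circadian_hr_spec"))
  for (p in c(artifact_rates$ectopic_fraction, artifact_rates$paced_fraction,
              artifact_rates$af_fraction, missingness_rates))
    check_number(p, "rate", lower = 0, upper = 1)
  structure(list(n_good = n_good, n_unfavorable = n_unfavorable,
                 hr_spec_good = hr_spec_good,
                 hr_spec_unfavorable = hr_spec_unfavorable,
                 covariate_params = covariate_params,
                 outcome_coefficients = outcome_coefficients,
                 missingness_rates = missingness_rates,
                 artifact_rates = artifact_rates,
                 duration_hours = duration_hours,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

group_par <- function(p, grp) if (length(p) > 1L) unname(p[[grp]]) else unname(p)

#' Generate a synthetic cohort of patient records
#'
#' Draws `n_good + n_unfavorable` patients. Each gets covariates from the
#' group's distributions, an RR series from a per-patient jitter of the
#' group's circadian spec (AF-designated patients instead get a serially
#' correlated irregular series and an AF diagnosis flag; paced patients get
#' majority paced-labelled beats), serial troponin samples, and a discharge
#' mRS drawn so that P(mRS > 2) follows the logistic outcome link.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `circdip_cohort` with elements `covariates`
#'   (one row per patient), `beats` (all beat annotations), `troponin`
#'   (long table of serial samples).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_good + spec$n_unfavorable
  if (n == 0L)
    return(structure(list(covariates = data.frame(), beats = data.frame(),
                          troponin = data.frame()), class = "circdip_cohort"))
  grp <- rep(c("good", "unfavorable"), c(spec$n_good, spec$n_unfavorable))
  cp <- spec$covariate_params
  ar <- spec$artifact_rates

  set.seed(spec$seed)
  seeds <- matrix(sample.int(.Machine$integer.max %/% 2L, 3L * n), ncol = 3L)

  age <- stats::rnorm(n, vapply(grp, function(g) group_par(cp$age_mean, g), 0),
                      cp$age_sd)
  age <- pmin(pmax(round(age, 1), 18), 100)
  nihss <- stats::rpois(n, vapply(grp, function(g) group_par(cp$nihss_lambda, g), 0))
  sex <- ifelse(stats::runif(n) <
                  vapply(grp, function(g) group_par(cp$prop_female, g), 0),
                "female", "male")
  draw_bin <- function(par) stats::runif(n) <
    vapply(grp, function(g) group_par(par, g), 0)
  hypertension <- draw_bin(cp$hypertension)
  diabetes <- draw_bin(cp$diabetes)
  prior_mi <- draw_bin(cp$prior_mi)
  cad <- draw_bin(cp$cad)
  pneumonia <- draw_bin(cp$pneumonia)
  hemorrhagic <- draw_bin(cp$prop_hemorrhagic)
  gfr <- round(pmax(stats::rnorm(n, cp$gfr_mean, cp$gfr_sd), 5), 1)
  af <- stats::runif(n) < ar$af_fraction
  paced <- !af & (stats::runif(n) < ar$paced_fraction)

  # Per-patient jitter of the group circadian spec.
  base_hr <- vapply(grp, function(g)
    group_par(c(good = spec$hr_spec_good$baseline_day_hr,
                unfavorable = spec$hr_spec_unfavorable$baseline_day_hr), g), 0) +
    stats::rnorm(n, 0, 3)
  # multiplicative dip heterogeneity (mean-corrected lognormal) keeps the
  # group mean at the specified dip fraction and leaves dip = 0 exactly 0
  dip <- vapply(grp, function(g)
    group_par(c(good = spec$hr_spec_good$dip_fraction,
                unfavorable = spec$hr_spec_unfavorable$dip_fraction), g), 0) *
    exp(stats::rnorm(n, -0.02, 0.2))
  dip <- pmin(dip, 0.5)
  hr_night <- base_hr * (1 - dip)

  # Logistic outcome link on centred/scaled generative quantities.
  b <- spec$outcome_coefficients
  comorb <- hypertension + diabetes + prior_mi + cad + pneumonia
  lp <- b[["intercept"]] + b[["age"]] * (age - 74) / 10 +
    b[["nihss"]] * (nihss - 5) / 5 + b[["dip"]] * (dip - 0.08) / 0.05 +
    b[["nocturnal_hr"]] * (hr_night - 68) / 8 + b[["comorbidity"]] * comorb
  p_unfav <- stats::plogis(lp)
  if (all(p_unfav > 1 - 1e-12) || all(p_unfav < 1e-12))
    warning("degenerate logistic outcome specification: all probabilities 0 or 1")
  unfav <- stats::runif(n) < p_unfav
  mrs <- ifelse(unfav, sample(3:6, n, replace = TRUE), sample(0:2, n, replace = TRUE))

  # Troponin: 1-3 serial samples, lognormal with group-shifted location.
  n_trop <- sample(1:3, n, replace = TRUE)
  admission <- as_time("2021-03-01 00:00:00") +
    round(stats::runif(n, 0, 86400))

  mr <- spec$missingness_rates
  nihss_na <- stats::runif(n) < (mr[["nihss"]] %||% 0)
  gfr_na <- stats::runif(n) < (mr[["gfr"]] %||% 0)
  trop_na <- stats::runif(n) < (mr[["troponin"]] %||% 0)

  ids <- sprintf("P%04d", seq_len(n))
  beats_list <- vector("list", n)
  trop_list <- vector("list", n)
  for (i in seq_len(n)) {
    if (af[i]) {
      ser <- generate_af_series(admission[i], spec$duration_hours, seeds[i, 1],
                                patient_id = ids[i])
    } else {
      psi <- circadian_hr_spec(
        baseline_day_hr = max(base_hr[i], 40),
        dip_fraction = dip[i],
        night_window = spec$hr_spec_good$night_window,
        transition_minutes = spec$hr_spec_good$transition_minutes,
        lf_amplitude_ms = spec$hr_spec_good$lf_amplitude_ms,
        lf_freq_hz = spec$hr_spec_good$lf_freq_hz,
        hf_amplitude_ms = spec$hr_spec_good$hf_amplitude_ms,
        hf_freq_hz = spec$hr_spec_good$hf_freq_hz,
        noise_sd_ms = spec$hr_spec_good$noise_sd_ms)
      ser <- generate_rr_series(psi, admission[i], spec$duration_hours,
                                seeds[i, 1], patient_id = ids[i])
    }
    set.seed(seeds[i, 2])
    n_gaps <- stats::rpois(1, ar$mean_gaps)
    gaps <- NULL
    if (n_gaps > 0 && spec$duration_hours * 3600 > 2 * 1800) {
      starts <- sort(stats::runif(n_gaps, 0, spec$duration_hours * 3600 - 1800))
      # keep gaps disjoint: drop any start within 30 min of the previous
      keep <- c(TRUE, diff(starts) > 1800)
      gaps <- data.frame(start = admission[i] + starts[keep], duration_min = 30)
    }
    ser <- inject_artifacts(ser, ar$ectopic_fraction, gaps, seed = seeds[i, 3])
    if (paced[i]) {
      set.seed(seeds[i, 3] + 1L)
      pace_idx <- stats::runif(nrow(ser)) < 0.9
      ser$label[pace_idx] <- "paced"
    }
    beats_list[[i]] <- ser
    if (!trop_na[i]) {
      set.seed(seeds[i, 3] + 2L)
      vals <- round(stats::rlnorm(n_trop[i],
                                  group_par(cp$troponin_meanlog, grp[i]),
                                  cp$troponin_sdlog), 1)
      trop_list[[i]] <- data.frame(patient_id = ids[i],
                                   sample_idx = seq_along(vals), value = vals)
    }
  }

  covariates <- data.frame(
    patient_id = ids, admission_time = admission,
    age = age, sex = sex,
    nihss = ifelse(nihss_na, NA_integer_, nihss),
    hypertension = hypertension, diabetes = diabetes, prior_mi = prior_mi,
    cad = cad, pneumonia = pneumonia,
    stroke_type = ifelse(hemorrhagic, "hemorrhagic", "ischemic"),
    af_diagnosis = af,
    gfr = ifelse(gfr_na, NA_real_, gfr),
    mrs_discharge = mrs,
    sim_group = grp, sim_dip_fraction = dip, sim_nocturnal_hr = hr_night,
    stringsAsFactors = FALSE)

  structure(list(covariates = covariates,
                 beats = do.call(rbind, beats_list),
                 troponin = if (length(trop_list))
                   do.call(rbind, trop_list) else
                   data.frame(patient_id = character(), sample_idx = integer(),
                              value = numeric())),
            class = "circdip_cohort")
}
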