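# Shared fixtures and independent brute-force oracles.

# Brute-force time-domain oracles (deliberately naive, kept independent of
# the package implementation).
oracle_sdnn <- function(rr) sqrt(sum((rr - sum(rr) / length(rr))^2) / length(rr))
oracle_rmssd <- function(rr) {
  d <- rr[-1] - rr[-length(rr)]
  sqrt(sum(d^2) / length(d))
}

# Build a beat series directly from RR intervals (ms), beats at the
# cumulative sum of intervals after `start`.
make_series <- function(rr_ms, start = "2021-06-01 00:00:00",
                        patient_id = "T1", label = "normal") {
  start <- as.POSIXct(start, tz = "UTC")
  data.frame(patient_id = patient_id, time = start + cumsum(rr_ms) / 1000,
             rr_ms = rr_ms, label = label, stringsAsFactors = FALSE)
}

# A complete hourly HR profile data frame for one patient.
make_profile <- function(values, patient_id = "T1", metric = "hr",
                         n_segments = 12L) {
  data.frame(patient_id = patient_id, metric = metric, hour = 0:23,
             value = values, n_segments = n_segments,
             stringsAsFactors = FALSE)
}

# Long profile table for a two-group cohort from a matrix of hourly values
# (rows = patients).
make_cohort_profiles <- function(value_matrix, ids) {
  do.call(rbind, lapply(seq_len(nrow(value_matrix)), function(i)
    make_profile(value_matrix[i, ], patient_id = ids[i])))
}

# Minimal covariate table for matching tests.
make_match_cohort <- function(age_good, age_unf, nihss_good, nihss_unf) {
  n1 <- length(age_good); n2 <- length(age_unf)
  data.frame(patient_id = sprintf("M%03d", seq_len(n1 + n2)),
             group = rep(c("good", "unfavorable"), c(n1, n2)),
             age = c(age_good, age_unf),
             nihss = c(nihss_good, nihss_unf),
             stringsAsFactors = FALSE)
}

# Synthetic feature table at the ML stage (bypasses the signal pipeline):
# standard covariates plus an optional informative column driving the label.
make_feature_table <- function(n = 300, seed = 1, signal_col = NULL,
                               signal_beta = 0) {
  set.seed(seed)
  tab <- data.frame(
    patient_id = sprintf("F%04d", seq_len(n)),
    age = rnorm(n, 74, 10), sex = rbinom(n, 1, 0.5),
    nihss = rpois(n, 5), hypertension = rbinom(n, 1, 0.8),
    diabetes = rbinom(n, 1, 0.3), prior_mi = rbinom(n, 1, 0.05),
    cad = rbinom(n, 1, 0.1), pneumonia = rbinom(n, 1, 0.05),
    troponin_category = sample(0:2, n, replace = TRUE),
    gfr = rnorm(n, 74, 20), stringsAsFactors = FALSE)
  lp <- rep(0, n)
  if (!is.null(signal_col)) {
    tab[[signal_col]] <- rnorm(n, 65, 8)
    lp <- signal_beta * scale(tab[[signal_col]])[, 1]
  }
  tab$label <- rbinom(n, 1, plogis(lp))
  tab
}
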