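test_that("degenerate constant generator gives exactly 1000 ms intervals", {
  s <- circadian_hr_spec(baseline_day_hr = 60, dip_fraction = 0,
                         lf_amplitude_ms = 0, hf_amplitude_ms = 0,
                         noise_sd_ms = 0)
  ser <- generate_rr_series(s, "2021-01-01 12:00:00", 1, seed = 1)
  expect_true(all(ser$rr_ms == 1000))
  expect_true(all(ser$label == "normal"))
  # beat times are the cumulative sum of the intervals
  expect_equal(as.numeric(diff(ser$time)), rep(1, nrow(ser) - 1))
})

test_that("nocturnal plateau matches the closed-form day/night HR ratio", {
  s <- circadian_hr_spec(baseline_day_hr = 60, dip_fraction = 0.10,
                         lf_amplitude_ms = 0, hf_amplitude_ms = 0,
                         noise_sd_ms = 0)
  ser <- generate_rr_series(s, "2021-01-01 12:00:00", 24, seed = 1)
  hod <- (as.numeric(ser$time) %% 86400) / 3600
  plateau <- hod >= 0 & hod < 4          # inside the night, clear of ramps
  day <- hod >= 12.5 & hod < 21          # clear of the 22:00 ramp
  expect_equal(mean(ser$rr_ms[plateau]), 60000 / (0.9 * 60), tolerance = 1e-9)
  expect_equal(mean(ser$rr_ms[day]), 1000, tolerance = 1e-9)
})

test_that("identical spec and seed give identical series", {
  s <- circadian_hr_spec()
  a <- generate_rr_series(s, "2021-01-01 00:00:00", 2, seed = 42)
  b <- generate_rr_series(s, "2021-01-01 00:00:00", 2, seed = 42)
  expect_identical(a, b)
})

test_that("spec validation names the offending field", {
  expect_error(circadian_hr_spec(baseline_day_hr = -1), "baseline_day_hr")
  expect_error(circadian_hr_spec(dip_fraction = 1), "dip_fraction")
  expect_error(circadian_hr_spec(lf_freq_hz = 0.2), "lf_freq_hz")
  expect_error(circadian_hr_spec(hf_freq_hz = 0.1), "hf_freq_hz")
  expect_error(circadian_hr_spec(noise_sd_ms = -3), "noise_sd_ms")
})

test_that("artifact injection is the identity at zero rates", {
  ser <- make_series(rep(800, 1000))
  expect_identical(inject_artifacts(ser, 0, NULL, seed = 1), ser)
})

test_that("ectopic relabelling matches a binomial count and perturbs RR", {
  ser <- make_series(rep(800, 10000))
  out <- inject_artifacts(ser, 0.05, NULL, seed = 99)
  n_ect <- sum(out$label == "ectopic")
  expect_lt(abs(n_ect - 500), 4 * sqrt(10000 * 0.05 * 0.95))
  ect <- out$label == "ectopic"
  expect_true(all(out$rr_ms[ect] == 0.6 * 800 |
                    out$rr_ms[ect] == 0.6 * 1.4 * 800))
})

test_that("gaps remove beats and overlapping gaps are rejected", {
  ser <- make_series(rep(1000, 7200))  # 2 h of beats
  g <- data.frame(start = as.POSIXct("2021-06-01 00:30:00", tz = "UTC"),
                  duration_min = 10)
  out <- inject_artifacts(ser, 0, g, seed = 1)
  expect_equal(nrow(ser) - nrow(out), 600)
  tnum <- as.numeric(out$time) - as.numeric(as.POSIXct("2021-06-01", tz = "UTC"))
  expect_false(any(tnum >= 1800 & tnum < 2400))
  bad <- data.frame(start = as.POSIXct("2021-06-01 00:30:00", tz = "UTC") +
                      c(0, 300), duration_min = c(10, 10))
  expect_error(inject_artifacts(ser, 0, bad, seed = 1), "overlap")
})

test_that("a gap covering a full clock hour leaves that hour without segments", {
  s <- circadian_hr_spec(noise_sd_ms = 0, lf_amplitude_ms = 0,
                         hf_amplitude_ms = 0, dip_fraction = 0)
  ser <- generate_rr_series(s, "2021-01-01 00:00:00", 6, seed = 1)
  g <- data.frame(start = as.POSIXct("2021-01-01 02:00:00", tz = "UTC"),
                  duration_min = 60)
  out <- inject_artifacts(ser, 0, g, seed = 1)
  sm <- compute_segment_metrics(out, metrics = "hr")
  hrs <- as.integer(format(sm$segment_start, "%H"))
  expect_false(2L %in% hrs)
  expect_true(all(c(0L, 1L, 3L, 4L, 5L) %in% hrs))
})

test_that("neutral outcome link yields ~50% unfavorable and cohorts are reproducible", {
  spec <- cohort_spec(n_good = 150, n_unfavorable = 150, duration_hours = 0.2,
                      outcome_coefficients = c(intercept = 0, age = 0,
                                               nihss = 0, dip = 0,
                                               nocturnal_hr = 0,
                                               comorbidity = 0),
                      artifact_rates = list(ectopic_fraction = 0,
                                            paced_fraction = 0,
                                            af_fraction = 0, mean_gaps = 0),
                      seed = 5)
  coh <- generate_cohort(spec)
  p_unf <- mean(coh$covariates$mrs_discharge > 2)
  expect_lt(abs(p_unf - 0.5), 3 * sqrt(0.25 / 300))
  coh2 <- generate_cohort(spec)
  expect_identical(serialize(coh, NULL), serialize(coh2, NULL))
})

test_that("all-AF cohorts are fully removed by the AF exclusion", {
  spec <- cohort_spec(n_good = 5, n_unfavorable = 5, duration_hours = 2,
                      artifact_rates = list(ectopic_fraction = 0,
                                            paced_fraction = 0,
                                            af_fraction = 1, mean_gaps = 0),
                      seed = 3)
  coh <- generate_cohort(spec)
  expect_true(all(coh$covariates$af_diagnosis))
  res <- apply_exclusions(coh, min_normal_beats = 100, window_hours = 2)
  expect_equal(res$flow$analyzable, 0)
  expect_equal(res$flow$excluded_af, 10)
})

test_that("single-tone series put their power in the right band", {
  base <- list(baseline_day_hr = 60, dip_fraction = 0, noise_sd_ms = 0)
  hf_only <- do.call(circadian_hr_spec,
                     c(base, lf_amplitude_ms = 0, hf_amplitude_ms = 40,
                       hf_freq_hz = 0.25))
  lf_only <- do.call(circadian_hr_spec,
                     c(base, lf_amplitude_ms = 40, lf_freq_hz = 0.10,
                       hf_amplitude_ms = 0))
  for (cfg in list(list(s = hf_only, hi = "hf_ms2", lo = "lf_ms2"),
                   list(s = lf_only, hi = "lf_ms2", lo = "hf_ms2"))) {
    ser <- generate_rr_series(cfg$s, "2021-01-01 12:00:00", 0.5, seed = 2)
    sm <- compute_segment_metrics(ser)
    sm <- sm[!is.na(sm[[cfg$hi]]), ]
    expect_true(all(sm[[cfg$hi]] >= 10 * sm[[cfg$lo]]))
  }
})
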