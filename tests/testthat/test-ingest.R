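test_that("beat CSV writer/reader round-trips a generated series", {
  ser <- generate_rr_series(circadian_hr_spec(), "2021-02-03 08:00:00", 0.5,
                            seed = 4, patient_id = "RT1")
  ser <- inject_artifacts(ser, 0.05, NULL, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_beat_csv(ser, path)
  back <- read_beat_csv(path)
  expect_equal(back$patient_id, ser$patient_id)
  expect_equal(back$label, ser$label)
  expect_equal(back$rr_ms, ser$rr_ms, tolerance = 1e-6)
  expect_equal(as.numeric(back$time), as.numeric(ser$time), tolerance = 1e-3)
})

test_that("beat CSV validation reports offending rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,time_iso8601,rr_ms,label",
               "A,2021-01-01T00:00:01,800,N",
               "A,2021-01-01T00:00:02,-5,N",
               "A,2021-01-01T00:00:03,900,N"), path)
  expect_error(read_beat_csv(path), "rows 2")
  writeLines(c("patient_id,time_iso8601,rr_ms,label",
               "A,2021-01-01T00:00:02,800,N",
               "A,2021-01-01T00:00:01,900,N"), path)
  expect_error(read_beat_csv(path), "non-monotone")
  writeLines(c("patient_id,time_iso8601,rr_ms,label",
               "A,2021-01-01T00:00:01,800,Q"), path)
  expect_error(read_beat_csv(path), "unknown label")
})

test_that("window trim is half-open at 48 h and empty results are allowed", {
  adm <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  # beats every second for 72 h starting 1 s after admission
  n <- 72 * 3600
  ser <- data.frame(patient_id = "W", time = adm + seq_len(n) - 1,
                    rr_ms = 1000, label = "normal", stringsAsFactors = FALSE)
  out <- trim_to_window(ser, adm, 48)
  expect_equal(nrow(out), 48 * 3600)  # 172,800 beats at 1 Hz
  expect_true(max(as.numeric(out$time) - as.numeric(adm)) < 48 * 3600)
  # boundary beat at exactly +48 h is excluded
  expect_false((adm + 48 * 3600) %in% out$time)
  before <- trim_to_window(ser, adm + 80 * 3600, 48)
  expect_equal(nrow(before), 0)
  # idempotence
  expect_equal(trim_to_window(out, adm, 48), out)
})

test_that("normal-beat selection keeps only sinus beats and is idempotent", {
  ser <- make_series(rep(800, 2000))
  expect_identical(select_normal_beats(ser), ser)
  pac <- ser; pac$label <- "paced"
  expect_equal(nrow(select_normal_beats(pac)), 0)
  mix <- inject_artifacts(ser, 0.05, NULL, seed = 8)
  kept <- select_normal_beats(mix)
  expect_equal(nrow(kept), sum(mix$label == "normal"))
  expect_lt(abs(nrow(kept) - 0.95 * 2000), 4 * sqrt(2000 * 0.05 * 0.95))
  expect_identical(select_normal_beats(kept), kept)
})

test_that("troponin categorization follows the 14 ng/l / 20% rule", {
  expect_equal(categorize_troponin(c(10, 12)), 0L)
  expect_equal(categorize_troponin(c(20, 20)), 1L)
  expect_equal(categorize_troponin(c(20, 25)), 2L)  # 25% change vs 20
  expect_equal(categorize_troponin(c(20, 16)), 2L)  # 20% decrease
  expect_equal(categorize_troponin(c(20, 17)), 1L)  # 15% change only
  expect_equal(categorize_troponin(20), 1L)          # single sample never cat 2
  expect_equal(categorize_troponin(c(13, 10)), 0L)
  expect_true(is.na(categorize_troponin(numeric(0)))) # missing, not 0
})

test_that("mRS dichotomization splits at 2/3 and validates range", {
  expect_equal(dichotomize_outcome(0:2), rep("good", 3))
  expect_equal(dichotomize_outcome(3:6), rep("unfavorable", 4))
  expect_error(dichotomize_outcome(7), "0..6")
  expect_error(dichotomize_outcome(-1), "0..6")
})

test_that("exclusion cascade counts each patient once, in fixed order", {
  adm <- as.POSIXct("2021-04-01 00:00:00", tz = "UTC")
  mk <- function(id, n_beats, label = "normal") {
    data.frame(patient_id = id, time = adm + seq_len(n_beats),
               rr_ms = 1000, label = label, stringsAsFactors = FALSE)
  }
  cov <- data.frame(
    patient_id = c("ok", "few", "miss", "af", "few_af"),
    admission_time = adm,
    age = c(70, 70, 70, 70, 70), nihss = c(4, 4, NA, 4, 4),
    gfr = 75, mrs_discharge = c(1, 1, 1, 4, 4),
    af_diagnosis = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  beats <- rbind(mk("ok", 2000), mk("few", 50), mk("miss", 2000),
                 mk("af", 2000), mk("few_af", 50))
  coh <- list(covariates = cov, beats = beats,
              troponin = data.frame(patient_id = character(),
                                    sample_idx = integer(), value = numeric()))
  res <- apply_exclusions(coh, min_normal_beats = 1000,
                          required_fields = c("age", "nihss", "gfr",
                                              "mrs_discharge"))
  fl <- res$flow
  expect_equal(fl$initial, 5)
  expect_equal(fl$excluded_insufficient_beats, 2)  # few and few_af (first failure)
  expect_equal(fl$excluded_missing_fields, 1)
  expect_equal(fl$excluded_af, 1)
  expect_equal(fl$analyzable, 1)
  # conservation
  expect_equal(fl$initial,
               fl$analyzable + fl$excluded_insufficient_beats +
                 fl$excluded_missing_fields + fl$excluded_af + fl$excluded_paced)
  # disabling the AF rule admits the AF patient
  res2 <- apply_exclusions(coh, min_normal_beats = 1000, exclude_af = FALSE)
  expect_equal(res2$flow$analyzable, 2)
  # idempotence on its own output
  res3 <- apply_exclusions(res$cohort, min_normal_beats = 1000)
  expect_equal(res3$flow$analyzable, res$flow$analyzable)
  expect_equal(sum(res3$flow[grep("excluded", names(res3$flow))]), 0)
})

test_that("flow conservation holds across random cohorts", {
  for (sd in 1:3) {
    spec <- cohort_spec(n_good = 8, n_unfavorable = 8, duration_hours = 1,
                        missingness_rates = c(nihss = 0.2, gfr = 0.2,
                                              troponin = 0.1),
                        artifact_rates = list(ectopic_fraction = 0.02,
                                              paced_fraction = 0.2,
                                              af_fraction = 0.2,
                                              mean_gaps = 1),
                        seed = sd)
    coh <- generate_cohort(spec)
    fl <- apply_exclusions(coh, min_normal_beats = 500, window_hours = 1)$flow
    expect_equal(fl$initial,
                 fl$analyzable + fl$excluded_insufficient_beats +
                   fl$excluded_missing_fields + fl$excluded_af +
                   fl$excluded_paced)
  }
})
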