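test_that("wall-clock 5-min binning: one beat lands in exactly one segment", {
  ser <- data.frame(patient_id = "B",
                    time = as.POSIXct("2021-01-01 10:02:11", tz = "UTC"),
                    rr_ms = 900, label = "normal", stringsAsFactors = FALSE)
  seg <- segment_series(ser)
  expect_equal(format(seg$segment_start, "%H:%M:%S"), "10:00:00")
})

test_that("gap-free series accumulate 24 segments per clock hour over 48 h, 12 over 24 h", {
  s <- circadian_hr_spec(dip_fraction = 0, lf_amplitude_ms = 0,
                         hf_amplitude_ms = 0, noise_sd_ms = 0)
  for (cfg in list(list(h = 48, per_hour = 24), list(h = 24, per_hour = 12))) {
    ser <- generate_rr_series(s, "2021-01-01 00:00:00", cfg$h, seed = 1)
    sm <- compute_segment_metrics(ser, metrics = "hr")
    hrs <- as.integer(format(sm$segment_start, "%H"))
    expect_equal(unname(tabulate(hrs + 1L, 24)), rep(cfg$per_hour, 24))
  }
})

test_that("segment HR is the median instantaneous rate (midpoint convention)", {
  # constant 1000 ms -> 60 bpm; constant 800 -> 75 bpm
  sm <- compute_segment_metrics(make_series(rep(1000, 60)))
  expect_equal(sm$hr_bpm, 60)
  sm <- compute_segment_metrics(make_series(rep(800, 60)))
  expect_equal(sm$hr_bpm, 75)
  # alternating 500/1500: rates {120, 40}, even-count median = 80
  sm <- compute_segment_metrics(make_series(rep(c(500, 1500), 30)))
  expect_equal(sm$hr_bpm[1], 80)
})

test_that("SDNN/RMSSD match closed forms and the brute-force oracle", {
  rr <- rep(c(950, 1050), 30)  # every successive difference is +/-100
  sm <- compute_segment_metrics(make_series(rr))
  expect_equal(sm$sdnn_ms[1], 50)
  expect_equal(sm$rmssd_ms[1], 100)
  # constant segment (long enough to clear the spectral span quorum)
  smc <- compute_segment_metrics(make_series(rep(1000, 200)))
  expect_equal(smc$sdnn_ms, 0)
  expect_equal(smc$rmssd_ms, 0)
  expect_equal(smc$lf_ms2, 0)
  expect_equal(smc$hf_ms2, 0)
  # random segments against the naive oracle
  set.seed(7)
  for (i in 1:25) {
    rr <- runif(sample(30:200, 1), 700, 1300)
    sm <- compute_segment_metrics(make_series(rr), metrics = c("sdnn", "rmssd"))
    expect_equal(sm$sdnn_ms[1], oracle_sdnn(rr), tolerance = 1e-12)
    expect_equal(sm$rmssd_ms[1], oracle_rmssd(rr), tolerance = 1e-12)
  }
})

test_that("time-domain metrics are scale-equivariant and shift-invariant", {
  set.seed(11)
  rr <- runif(120, 700, 1300)
  base <- compute_segment_metrics(make_series(rr))
  scaled <- compute_segment_metrics(make_series(rr * 1.3))
  shifted <- compute_segment_metrics(make_series(rr + 200))
  expect_equal(scaled$sdnn_ms, base$sdnn_ms * 1.3, tolerance = 1e-9)
  expect_equal(scaled$rmssd_ms, base$rmssd_ms * 1.3, tolerance = 1e-9)
  expect_equal(shifted$sdnn_ms, base$sdnn_ms, tolerance = 1e-9)
  expect_equal(shifted$rmssd_ms, base$rmssd_ms, tolerance = 1e-9)
})

test_that("successive pairs straddling a gap are skipped by RMSSD", {
  # two constant blocks at different RR levels, 10 s apart: the only
  # nonzero difference pair straddles the gap and must be excluded
  start <- as.POSIXct("2021-06-01 00:00:00", tz = "UTC")
  t1 <- cumsum(rep(1, 60))          # 1000 ms beats
  t2 <- max(t1) + 10 + cumsum(rep(0.8, 60))  # 800 ms beats after a 10 s hole
  ser <- data.frame(patient_id = "G", time = start + c(t1, t2),
                    rr_ms = c(rep(1000, 60), rep(800, 60)), label = "normal",
                    stringsAsFactors = FALSE)
  sm <- compute_segment_metrics(ser)
  expect_equal(sm$rmssd_ms[1], 0)
  # the SDNN still sees both levels
  expect_gt(sm$sdnn_ms[1], 90)
})

test_that("in-band tones dominate the correct spectral band", {
  # directly constructed tachogram: beats ~1 Hz, rr modulated by a tone
  tone_series <- function(freq) {
    t <- 0; rr <- numeric(0)
    while (t < 300) {
      r <- 1000 + 50 * sin(2 * pi * freq * t)
      rr <- c(rr, r); t <- t + r / 1000
    }
    make_series(rr)
  }
  hf <- compute_segment_metrics(tone_series(0.25))
  expect_true(all(hf$hf_ms2 >= 10 * hf$lf_ms2, na.rm = TRUE))
  lf <- compute_segment_metrics(tone_series(0.10))
  expect_true(all(lf$lf_ms2 >= 10 * lf$hf_ms2, na.rm = TRUE))
})

test_that("an in-band tone captures >= 90% of nonzero-frequency power", {
  t <- 0; rr <- numeric(0)
  while (t < 300) {
    r <- 1000 + 40 * sin(2 * pi * 0.25 * t)
    rr <- c(rr, r); t <- t + r / 1000
  }
  ser <- make_series(rr)
  seg <- segment_series(ser)
  first <- seg[seg$segment_start == seg$segment_start[1], ]
  sp <- segment_spectral(as.numeric(first$time), first$rr_ms)
  # total power ~ A^2/2 = 800 ms^2; HF band must hold >= 90% of LF+HF
  expect_gt(sp[["hf_ms2"]] / (sp[["hf_ms2"]] + sp[["lf_ms2"]]), 0.9)
  expect_equal(sp[["hf_ms2"]], 40^2 / 2, tolerance = 0.15)
})

test_that("hourly slots require the 3-segment quorum", {
  # k identical segments in hour 3, k = 2 then 3
  mk_segments <- function(k) {
    data.frame(patient_id = "Q",
               segment_start = as.POSIXct("2021-01-01 03:00:00", tz = "UTC") +
                 300 * (seq_len(k) - 1),
               n_beats = 60, hr_bpm = 72, sdnn_ms = 10, rmssd_ms = 12,
               lf_ms2 = 1, hf_ms2 = 1, lf_hf_ratio = 1,
               stringsAsFactors = FALSE)
  }
  p2 <- build_profile(mk_segments(2), "hr")
  expect_true(is.na(p2$value[p2$hour == 3]))
  expect_equal(p2$n_segments[p2$hour == 3], 2)
  p3 <- build_profile(mk_segments(3), "hr")
  expect_equal(p3$value[p3$hour == 3], 72)
  # segment-count conservation over hours
  expect_equal(sum(p3$n_segments), 3)
})

test_that("group summary reduces to hand arithmetic", {
  prof <- make_cohort_profiles(rbind(rep(70, 24), rep(74, 24)), c("A", "B"))
  groups <- data.frame(patient_id = c("A", "B"), group = "g1")
  s <- cohort_profile_summary(prof, groups)
  expect_equal(unique(s$mean), 72)
  expect_equal(unique(s$sd), sd(c(70, 74)))
  expect_equal(unique(s$n_patients), 2)
  # identical profiles give SD 0
  prof2 <- make_cohort_profiles(rbind(rep(70, 24), rep(70, 24)), c("A", "B"))
  s2 <- cohort_profile_summary(prof2, groups)
  expect_true(all(s2$sd == 0))
})

test_that("a synthetic dipper's night HR slots sit below its day slots", {
  s <- circadian_hr_spec(baseline_day_hr = 70, dip_fraction = 0.12,
                         noise_sd_ms = 5)
  ser <- generate_rr_series(s, "2021-01-01 00:00:00", 24, seed = 9)
  sm <- compute_segment_metrics(ser, metrics = "hr")
  p <- build_profile(sm, "hr")
  night <- p$value[p$hour %in% c(0:3)]
  day <- p$value[p$hour %in% 11:15]
  expect_true(max(night, na.rm = TRUE) < min(day, na.rm = TRUE))
})
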