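## synthetic clean ECG: Gaussian QRS train at given beat times
gaussianEcg <- function(beat_times, dur, fs = 200, sigma = 0.012, amp = 1) {
  n <- dur * fs
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (b in beat_times) {
    lo <- max(1, round((b - 5 * sigma) * fs))
    hi <- min(n, round((b + 5 * sigma) * fs))
    tt <- t[lo:hi]
    x[lo:hi] <- x[lo:hi] + amp * exp(-(tt - b)^2 / (2 * sigma^2))
  }
  x
}

test_that("R-peak detection recovers a clean regular rhythm", {
  truth <- seq(0.5, 59.5, by = 1.0)
  ecg <- filterECG(gaussianEcg(truth, 60))
  beats <- detectRPeaks(ecg)
  expect_gte(length(beats$r_peak_times), 59)
  expect_lte(length(beats$r_peak_times), 61)
  ## every detection within 10 ms of a true beat
  err <- vapply(beats$r_peak_times,
                function(d) min(abs(truth - d)), numeric(1))
  expect_lt(max(err), 0.010 + 1e-9)
  expect_error(detectRPeaks(rep(0, 200 * 30)), "no QRS detected")
})

test_that("R-peak detection stays accurate at 120 BPM under 20 dB noise", {
  set.seed(77)
  truth <- seq(0.5, 119.5, by = 0.5)
  clean <- gaussianEcg(truth, 120)
  snr_sd <- sqrt(mean(clean^2)) / 10^(20 / 20)
  noisy <- clean + rnorm(length(clean), 0, snr_sd)
  beats <- detectRPeaks(filterECG(noisy))
  expect_gte(detectionF1(beats$r_peak_times, truth, tol = 0.05), 0.99)
})

test_that("windowed HR matches the brute-force trailing-window mean", {
  b1 <- structure(list(r_peak_times = seq(0, 60, by = 1.0)),
                  class = "BeatSeries")
  expect_true(all(abs(heartRateSeries(b1, 60)$hr - 60) < 1e-9))
  b2 <- structure(list(r_peak_times = seq(0, 60, by = 0.5)),
                  class = "BeatSeries")
  expect_true(all(abs(heartRateSeries(b2, 60)$hr - 120) < 1e-9))
  ## alternating 0.5 / 1.0 s intervals vs an independent oracle
  times <- cumsum(c(0, rep(c(0.5, 1.0), 40)))
  b3 <- structure(list(r_peak_times = times), class = "BeatSeries")
  got <- heartRateSeries(b3, floor(max(times)))
  rr <- diff(times); term <- times[-1]
  oracle <- vapply(got$t, function(tk) {
    inw <- term > (tk + 1) - 4 & term <= tk + 1
    if (any(inw)) mean(60 / rr[inw]) else NA_real_
  }, numeric(1))
  for (k in seq_along(oracle))
    if (is.na(oracle[k]) && k > 1) oracle[k] <- oracle[k - 1]
  expect_equal(got$hr, oracle, tolerance = 1e-12)
  expect_error(heartRateSeries(structure(list(r_peak_times = numeric()),
                                         class = "BeatSeries"), 10),
               "no beats")
})

test_that("HR depends only on R-peak times, not on the waveform between", {
  truth <- seq(0.5, 59.5, by = 0.8)
  e1 <- filterECG(gaussianEcg(truth, 60))
  ## add small bumps mid-diastole; detections must not change
  spur <- truth + 0.4
  e2 <- filterECG(gaussianEcg(truth, 60) +
                  gaussianEcg(spur[spur < 60], 60, amp = 0.08))
  h1 <- heartRateSeries(detectRPeaks(e1), 60)
  h2 <- heartRateSeries(detectRPeaks(e2), 60)
  expect_equal(h1$hr, h2$hr, tolerance = 0.5)
})

test_that("age-predicted maximum HR and HR% follow the stated relations", {
  expect_equal(hrMax(40), 180)
  expect_equal(hrMax(24), 191.2)
  expect_error(hrMax(0), "positive")
  expect_equal(hrPercent(95.6, 24), 50)
  expect_equal(hrPercent(hrMax(33), 33), 100)
  expect_error(hrPercent(0, 30), "positive")
})

test_that("breath detection finds peaks, troughs and amplitudes", {
  t <- seq(0, 60 - 1 / 25, by = 1 / 25)
  y <- filterRespiration(sin(2 * pi * 0.25 * t))
  br <- detectBreaths(y)
  npk <- length(br$peak_times)
  expect_gte(npk, 14); expect_lte(npk, 16)
  ## unit sinusoid: peak - trough = 2 x the cascade's gain at 0.25 Hz
  gain <- measuredAmplitude(y, 25, discard_s = 10, f = 0.25)
  da <- daptSeries(br)$dapt
  mid <- da[3:(length(da) - 3)]
  expect_true(all(abs(mid - 2 * gain) < 0.1))
  expect_true(all(mid > 1.8 & mid <= 2.0))
  expect_error(detectBreaths(rep(1, 1000)), "too few breaths")
})

test_that("per-breath amplitude tracks an amplitude ramp monotonically", {
  t <- seq(0, 120 - 1 / 25, by = 1 / 25)
  ramp <- seq(1, 2, length.out = length(t))
  y <- filterRespiration(ramp * sin(2 * pi * 0.25 * t))
  da <- daptSeries(detectBreaths(y))
  mid <- da$dapt[3:(nrow(da) - 2)]
  expect_true(all(diff(mid) > -0.02))
  expect_gt(mid[length(mid)], mid[1] * 1.5)
})

test_that("per-breath RR is 60 over the peak-to-peak interval", {
  br <- structure(list(peak_times = seq(0, 40, by = 4)),
                  class = "BreathSeries")
  expect_true(all(respRateSeries(br)$rr == 15))
  br2 <- structure(list(peak_times = seq(0, 40, by = 2)),
                   class = "BreathSeries")
  expect_true(all(respRateSeries(br2)$rr == 30))
  br3 <- structure(list(peak_times = c(0, 3, 8)), class = "BreathSeries")
  expect_equal(respRateSeries(br3)$rr, c(20, 12))
})

test_that("DApt is the paired peak-minus-trough amplitude", {
  br <- structure(list(peak_times = c(1, 2, 3),
                       peak_amplitudes = c(2, 1, 1),
                       trough_amplitudes = c(-1, 1, 0.5)),
                  class = "BreathSeries")
  expect_equal(daptSeries(br)$dapt, c(3, 0, 0.5))
})

test_that("SVM is the Euclidean norm with its symmetries", {
  expect_equal(svmSeries(3, 4, 0), 5)
  expect_equal(svmSeries(1, 1, 1), sqrt(3))
  expect_equal(svmSeries(0, 0, 0), 0)
  set.seed(21)
  x <- rnorm(50); y <- rnorm(50); z <- rnorm(50)
  expect_equal(svmSeries(x, y, z), svmSeries(z, -x, y))
  expect_error(svmSeries(1:3, 1:3, 1:2), "channel mismatch")
})

test_that("MADs matches its blocked definition and shift invariance", {
  expect_true(all(madsSeries(rep(2.5, 100))$mads == 0))
  expect_equal(madsSeries(rep(c(0, 1), length.out = 25))$mads, 1.0)
  ## linear ramp with per-sample step d has MADs d
  d <- 0.037
  expect_equal(madsSeries(seq(0, by = d, length.out = 50))$mads,
               rep(d, 2), tolerance = 1e-12)
  set.seed(22)
  s <- abs(rnorm(250))
  expect_equal(madsSeries(s)$mads, madsSeries(s + 7.3)$mads,
               tolerance = 1e-12)
})

test_that("1 Hz resampling is shape preserving without overshoot", {
  expect_equal(resampleTo1Hz(c(0, 10), c(10, 10), 0:10), rep(10, 11))
  y <- resampleTo1Hz(c(0, 5, 10), c(0, 5, 10), c(2.5, 7.5))
  expect_equal(y, c(2.5, 7.5), tolerance = 1e-9)
  ## local max in the support: interpolant never exceeds the data max
  ts <- c(0, 2, 4, 6, 8); vs <- c(1, 3, 8, 2, 1)
  fine <- resampleTo1Hz(ts, vs, seq(0, 8, by = 0.01))
  expect_lte(max(fine), max(vs) + 1e-9)
  expect_gte(min(fine), min(vs) - 1e-9)
  ## outside the support: clamped to endpoint values
  out <- resampleTo1Hz(c(2, 4), c(5, 9), c(0, 6))
  expect_equal(out, c(5, 9))
  expect_error(resampleTo1Hz(1, 1), "at least 2")
})

test_that("centered moving average has the stated edge behaviour", {
  expect_equal(smoothMovingAverage(rep(3.3, 100)), rep(3.3, 100))
  imp <- rep(0, 101); imp[51] <- 1
  sm <- smoothMovingAverage(imp)
  expect_equal(sm[51], 1 / 31)
  ramp <- seq(0, 10, length.out = 101)
  sm2 <- smoothMovingAverage(ramp)
  expect_equal(sm2[16:86], ramp[16:86], tolerance = 1e-12)
})

test_that("feature frame tracks a steady rest recording within 5%", {
  p <- simParams(rest_normal = 120, rest_deep = 1e-9, rest_talk = 1e-9,
                 rest_fast = 1e-9, rest_gap = 1e-9,
                 include_treadmill = FALSE,
                 hr_ar_sd = 0, hrv_jitter_sd = 0, ecg_noise_sd = 0,
                 ecg_wander_amp = 0, resp_noise_sd = 0, resp_drift_amp = 0,
                 acc_noise_sd = 0, vo2_ref_noise_sd = 0,
                 hr_rest_sd = 0, hr_slope_cv = 0, vo2_rest_sd = 0,
                 rr_rest_sd = 0, amp_gain_cv = 0)
  sim <- simulateSubject(testSubject(), p, seed = 3)
  fr <- buildFeatureFrame(sim$recording)
  tr <- sim$truth
  mid <- 30:100    # clear of windowing start-up and edge smoothing
  expect_lt(max(abs(fr$hr[mid] - tr$hr[mid + 1]) / tr$hr[mid + 1]), 0.05)
  expect_lt(max(abs(fr$rr[mid] - tr$rr[mid + 1]) / tr$rr[mid + 1]), 0.05)
  expect_lt(max(abs(fr$vo2[mid] - tr$vo2[mid + 1]) / tr$vo2[mid + 1]),
            0.05)
  expect_equal(nrow(fr), 600)
  expect_true(all(fr$hr > 0 & fr$rr > 0 & fr$dapt >= 0 & fr$mads >= 0))
})

test_that("frames flag prediction-only input and unlabeled seconds", {
  sim <- simulateSubject(testSubject(), tinyParams(), seed = 5)
  rec <- sim$recording
  fr <- buildFeatureFrame(rec)
  expect_null(attr(fr, "prediction_only"))
  expect_true("unlabeled" %in% fr$activity)   # inter-posture gaps
  expect_equal(sum(fr$activity == "unlabeled"), 4 * 5)
  ## drop vo2_ref: prediction-only frame without a vo2 column
  rec2 <- Recording(rec@subject,
                    rec@channels[setdiff(channelNames(rec), "vo2_ref")],
                    activities(rec))
  fr2 <- buildFeatureFrame(rec2)
  expect_true(isTRUE(attr(fr2, "prediction_only")))
  expect_false("vo2" %in% names(fr2))
  ## SDI is broadcast to every row
  expect_true(all(fr$age == 25) && all(fr$sex == "male"))
})

test_that("feature frames round-trip through their delimited form", {
  sim <- simulateSubject(testSubject(), tinyParams(), seed = 6)
  fr <- buildFeatureFrame(sim$recording)
  f <- tempfile(fileext = ".csv")
  writeFeatureFrame(fr, f)
  back <- readFeatureFrame(f)
  expect_equal(names(back)[1:8],
               c("t", "hr", "hr_pct", "rr", "dapt", "mads", "vo2",
                 "activity"))
  expect_equal(back$hr, fr$hr, tolerance = 1e-9)
  unlink(f)
})
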