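test_that("the default schedule reproduces the protocol's structure", {
  sched <- makeSchedule(simParams(), testSubject())
  act <- sched$activities
  rest <- act[act$label %in% c("stand", "lie", "lie_left", "lie_right",
                               "sit"), ]
  expect_equal(nrow(rest), 5)
  expect_true(all(rest$t_end - rest$t_start == 180))
  ## rest battery including the four inter-posture gaps spans 17 min
  expect_equal(max(rest$t_end), 5 * 180 + 4 * 30)
  walk <- act[act$label == "walk", ]
  expect_equal(walk$t_end - walk$t_start, 180)
  levels <- act[grepl("bruce", act$label), ]
  expect_true(all(levels$t_end - levels$t_start == 180))
  rec <- act[act$label == "recovery", ]
  expect_lte(rec$t_end - rec$t_start, 1200)
})

test_that("the exhaustion rule truncates the Bruce sequence", {
  ## default coupling for a 25-year-old reaches 180 BPM at stage 5
  sched <- makeSchedule(simParams(), testSubject(age = 25))
  labs <- sched$activities$label
  expect_true("bruce_level_5" %in% labs)
  expect_false("bruce_level_6" %in% labs)
  expect_equal(labs[length(labs)], "recovery")
  ## a threshold above any reachable HR keeps all seven stages
  all7 <- makeSchedule(simParams(hr_exhaustion = 1000), testSubject())
  expect_true(all(paste0("bruce_level_", 1:7) %in%
                  all7$activities$label))
  expect_equal(bruceProtocol()$speed_kmh[c(1, 7)], c(2.74, 9.65))
  ## rest-only configuration: no treadmill blocks at all
  rest_only <- makeSchedule(simParams(include_treadmill = FALSE),
                            testSubject())
  expect_false(any(grepl("bruce|walk|recovery",
                         rest_only$activities$label)))
  expect_equal(max(rest_only$segments$t_end), 1020)
})

test_that("ground-truth kinetics follow the first-order step response", {
  p <- shortParams(hr_ar_sd = 0, hrv_jitter_sd = 0, ecg_noise_sd = 0,
                   resp_noise_sd = 0, acc_noise_sd = 0,
                   vo2_ref_noise_sd = 0, hr_rest_sd = 0, hr_slope_cv = 0,
                   vo2_rest_sd = 0, rr_rest_sd = 0, amp_gain_cv = 0,
                   tau = 35)
  sim <- simulateSubject(testSubject(), p, seed = 1)
  sched <- sim$truth$schedule
  segs <- sched$segments
  vo2 <- sim$truth$vo2
  for (lab in c("bruce_level_1", "bruce_level_3")) {
    t0 <- segs$t_start[segs$label == lab]
    tgt <- segs$vo2[segs$label == lab]
    v0 <- vo2[t0 + 1]                  # value at the step onset
    v_tau <- vo2[t0 + 35 + 1]
    expect_equal(v_tau, v0 + (1 - exp(-1)) * (tgt - v0),
                 tolerance = 1e-6)
  }
  ## noiseless references equal the truth exactly
  expect_equal(channelData(sim$recording, "vo2_ref"), sim$truth$vo2)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  s1 <- simulateSubject(testSubject(), tinyParams(), seed = 31)
  s2 <- simulateSubject(testSubject(), tinyParams(), seed = 31)
  for (nm in channelNames(s1$recording))
    expect_identical(channelData(s1$recording, nm),
                     channelData(s2$recording, nm))
  expect_identical(s1$truth$r_peak_times, s2$truth$r_peak_times)
  s3 <- simulateSubject(testSubject(), tinyParams(), seed = 32)
  expect_false(identical(channelData(s1$recording, "ecg"),
                         channelData(s3$recording, "ecg")))
})

test_that("rest-only simulation sits near the configured resting VO2", {
  p <- simParams(include_treadmill = FALSE, vo2_rest_sd = 0)
  sim <- simulateSubject(testSubject(), p, seed = 13)
  m <- mean(channelData(sim$recording, "vo2_ref"))
  expect_lt(abs(m - 3.5) / 3.5, 0.10)
})

test_that("cohorts honour sex quotas and demographic ranges", {
  co <- simulateCohort(29, tinyParams(), seed = 3, n_male = 17)
  sexes <- vapply(co, function(s) subjectInfo(s$recording)@sex,
                  character(1))
  expect_equal(sum(sexes == "male"), 17)
  expect_equal(sum(sexes == "female"), 12)
  ages <- vapply(co, function(s) subjectInfo(s$recording)@age, numeric(1))
  bmis <- vapply(co, function(s) subjectInfo(s$recording)@bmi, numeric(1))
  expect_true(all(ages >= 20 & ages <= 30))
  expect_true(all(bmis >= 17.9 & bmis <= 25.1))
  ## same seed reproduces demographics; different subjects differ in noise
  co2 <- simulateCohort(29, tinyParams(), seed = 3, n_male = 17)
  expect_identical(vapply(co2, function(s) subjectInfo(s$recording)@age,
                          numeric(1)), ages)
  ## point ranges: identical demographics, distinct noise realizations
  cop <- simulateCohort(3, tinyParams(), seed = 4,
                        age_range = c(25, 25), bmi_range = c(22, 22))
  a <- vapply(cop, function(s) subjectInfo(s$recording)@age, numeric(1))
  expect_true(all(a == 25))
  expect_false(identical(channelData(cop[[1]]$recording, "ecg"),
                         channelData(cop[[2]]$recording, "ecg")))
  expect_error(simulateCohort(0), ">= 1")
})

test_that("noiseless simulations let the features recover the truth", {
  p <- shortParams(hr_ar_sd = 0, hrv_jitter_sd = 0, ecg_noise_sd = 0,
                   ecg_wander_amp = 0, resp_noise_sd = 0,
                   resp_drift_amp = 0, acc_noise_sd = 0,
                   vo2_ref_noise_sd = 0, hr_rest_sd = 0, hr_slope_cv = 0,
                   vo2_rest_sd = 0, rr_rest_sd = 0, amp_gain_cv = 0,
                   deep_rr_mult = 1, deep_amp_mult = 1, talk_rr_mult = 1,
                   talk_amp_mult = 1, fast_rr_mult = 1, fast_amp_mult = 1)
  sim <- simulateSubject(testSubject(), p, seed = 2)
  fr <- buildFeatureFrame(sim$recording)
  tr <- sim$truth
  idx <- fr$t + 1
  ## exclude the top Bruce stages where breathing leaves the belt band
  keep <- tr$rr[idx] <= 21 & fr$t > 30
  expect_lt(mean(abs(fr$hr[keep] - tr$hr[idx][keep])), 2)
  expect_lt(mean(abs(fr$rr[keep] - tr$rr[idx][keep])), 1)
})
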