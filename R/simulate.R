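## Protocol-faithful synthetic cohorts: a rest battery in five postures
## (normal / deep / talking / fast breathing sub-blocks), a treadmill
## warm-up walk, Bruce incremental stages until an exhaustion rule fires,
## and recovery. Ground-truth VO2 follows first-order kinetics toward each
## activity's steady state; HR, respiration and acceleration are coupled to
## it, so every extracted feature carries recoverable signal.

#' The Bruce treadmill protocol stages
#'
#' Seven 3-minute stages of increasing speed and incline.
#'
#' @return data.frame with `level`, `speed_kmh`, `incline_pct`
#' @export
bruceProtocol <- function() {
  data.frame(level = 1:7,
             speed_kmh = c(2.74, 4.02, 5.47, 6.76, 8.05, 8.85, 9.65),
             incline_pct = c(10, 12, 14, 16, 18, 20, 22))
}

#' Simulation parameters
#'
#' Defaults encode the experimental protocol (17-min rest battery, 3-min
#' warm-up walk, 3-min Bruce stages, recovery) and physiologically
#' plausible coupling: a steady-state VO2 ladder rising from rest
#' (3.5 ml/kg/min, 1 MET) through walking to the Bruce stages; first-order
#' VO2 on-kinetics with time constant `tau`; an affine HR-VO2 relation
#' whose slope spans rest HR to near the age-predicted maximum; linear
#' RR and breath-amplitude coupling to VO2; posture-dependent gravity plus
#' gait harmonics and slow postural sway (growing with treadmill speed) on
#' the accelerometer. The exhaustion rule stops the Bruce sequence at the
#' first stage whose steady-state HR reaches `hr_exhaustion`.
#'
#' Durations may be shortened (same block structure) for fast experiments.
#'
#' @param ... overrides of any default listed below
#' @return named list of simulation parameters
#' @export
simParams <- function(...) {
  p <- list(
    ## steady-state VO2 ladder (ml/kg/min)
    vo2_rest = 3.5, vo2_walk = 12,
    vo2_levels = c(16, 21, 28, 35, 43, 50, 55),
    tau = 35,                      # VO2 kinetics time constant (s)
    ## durations (s): protocol values
    rest_normal = 60, rest_deep = 60, rest_talk = 30, rest_fast = 30,
    rest_gap = 30, walk_s = 180, level_s = 180, recovery_s = 300,
    include_treadmill = TRUE,
    walk_speed = 3.0, recovery_speed = 1.5,    # km/h
    ## cardiac coupling
    hr_rest = 70, hr_slope = NULL,  # NULL: (hrMax(age) - hr_rest) / 40
    hr_ar_sd = 1.0, hr_ar_phi = 0.9, hr_ref_noise_sd = 1.0,
    hr_exhaustion = 180,
    hrv_jitter_sd = 0.02,
    ## between-subject heterogeneity (drawn once per subject)
    hr_rest_sd = 4,        # resting-HR spread (BPM)
    hr_slope_cv = 0.06,    # HR-VO2 slope gain CV
    vo2_rest_sd = 0.3,     # resting-VO2 spread (ml/kg/min)
    rr_rest_sd = 1.5,      # resting-RR spread (breaths/min)
    amp_gain_cv = 0.15,    # belt coupling gain CV
    ## ECG waveform
    qrs_sigma = 0.012, qrs_amp = 1.0,
    ecg_wander_amp = 0.15, ecg_wander_hz = 0.25, ecg_noise_sd = 0.02,
    ## respiratory coupling
    rr_rest = 12, rr_slope = 0.5,          # breaths/min per ml/kg/min
    amp_rest = 1.0, amp_slope = 0.04,      # belt units per ml/kg/min
    resp_drift_amp = 2.0, resp_drift_hz = 0.008, resp_noise_sd = 0.02,
    ## rest-phase breathing tasks (multipliers on RR / amplitude)
    deep_rr_mult = 0.6, deep_amp_mult = 1.8,
    talk_rr_mult = 1.1, talk_amp_mult = 0.7,
    fast_rr_mult = 2.0, fast_amp_mult = 0.8,
    ## acceleration (g units)
    gait_base = 0.05, gait_per_speed = 0.025,
    sway_base = 0.004, sway_per_speed = 0.012, sway_hz = 0.15,
    acc_noise_sd = 0.01,
    ## reference and planted effects
    vo2_ref_noise_sd = 0.4,
    sex_vo2_offset = 0)            # added to female Bruce-stage targets
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown simulation parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (any(diff(p$vo2_levels) <= 0))
    stop("vo2_levels must be strictly increasing")
  if (p$recovery_s > 1200) stop("recovery must not exceed 1200 s")
  p
}

.hr_slope_of <- function(params, subject) {
  if (!is.null(params$hr_slope)) params$hr_slope
  else (hrMax(subject@age) - params$hr_rest) / 40
}

#' Build a subject's activity schedule
#'
#' Rest battery (five postures, each normal / deep / talking / fast
#' breathing, with rest gaps between postures), warm-up walk, Bruce stages
#' truncated at the first stage whose steady-state HR (affine in the
#' stage's VO2 target) reaches the exhaustion threshold, then recovery.
#' Inter-posture gaps are deliberately left unannotated.
#'
#' @param params from [simParams()]
#' @param subject a [SubjectInfo-class]
#' @return list with `activities` (annotation data.frame), `segments`
#'   (VO2 target per contiguous span) and `breathing` (RR/amplitude
#'   multipliers of the rest-phase tasks)
#' @export
makeSchedule <- function(params, subject) {
  slope <- .hr_slope_of(params, subject)
  postures <- c("stand", "lie", "lie_left", "lie_right", "sit")
  sub_d <- c(params$rest_normal, params$rest_deep, params$rest_talk,
             params$rest_fast)
  acts <- list(); segs <- list(); brth <- list()
  t <- 0
  for (i in seq_along(postures)) {
    plen <- sum(sub_d)
    acts[[length(acts) + 1L]] <- data.frame(label = postures[i],
                                            t_start = t, t_end = t + plen)
    segs[[length(segs) + 1L]] <- data.frame(label = postures[i],
                                            t_start = t, t_end = t + plen,
                                            vo2 = params$vo2_rest, speed = 0)
    mults <- rbind(c(1, 1),
                   c(params$deep_rr_mult, params$deep_amp_mult),
                   c(params$talk_rr_mult, params$talk_amp_mult),
                   c(params$fast_rr_mult, params$fast_amp_mult))
    tt <- t + c(0, cumsum(sub_d))
    brth[[length(brth) + 1L]] <- data.frame(
      t_start = tt[1:4], t_end = tt[2:5],
      rr_mult = mults[, 1], amp_mult = mults[, 2])
    t <- t + plen
    if (i < length(postures)) {
      ## unannotated rest gap between postures
      segs[[length(segs) + 1L]] <- data.frame(label = "unlabeled",
                                              t_start = t,
                                              t_end = t + params$rest_gap,
                                              vo2 = params$vo2_rest,
                                              speed = 0)
      t <- t + params$rest_gap
    }
  }
  if (isTRUE(params$include_treadmill)) {
    acts[[length(acts) + 1L]] <- data.frame(label = "walk", t_start = t,
                                            t_end = t + params$walk_s)
    segs[[length(segs) + 1L]] <- data.frame(label = "walk", t_start = t,
                                            t_end = t + params$walk_s,
                                            vo2 = params$vo2_walk,
                                            speed = params$walk_speed)
    t <- t + params$walk_s
    bp <- bruceProtocol()
    ## the sex offset raises the oxygen cost of treadmill stages without
    ## changing the effort signature the wearable channels see: measured
    ## VO2 targets are shifted, the drive targets (feeding HR/RR/motion
    ## coupling and the exhaustion rule) are not
    offs <- if (subject@sex == "female") params$sex_vo2_offset else 0
    drive <- params$vo2_levels
    hr_steady <- params$hr_rest + slope * (drive - params$vo2_rest)
    last <- which(hr_steady >= params$hr_exhaustion)[1]
    last <- if (is.na(last)) nrow(bp) else min(last, nrow(bp))
    for (k in seq_len(last)) {
      lab <- paste0("bruce_level_", k)
      acts[[length(acts) + 1L]] <- data.frame(label = lab, t_start = t,
                                              t_end = t + params$level_s)
      segs[[length(segs) + 1L]] <- data.frame(label = lab, t_start = t,
                                              t_end = t + params$level_s,
                                              vo2 = drive[k] + offs,
                                              speed = bp$speed_kmh[k])
      t <- t + params$level_s
    }
    acts[[length(acts) + 1L]] <- data.frame(label = "recovery",
                                            t_start = t,
                                            t_end = t + params$recovery_s)
    segs[[length(segs) + 1L]] <- data.frame(label = "recovery",
                                            t_start = t,
                                            t_end = t + params$recovery_s,
                                            vo2 = params$vo2_rest,
                                            speed = params$recovery_speed)
    t <- t + params$recovery_s
  }
  segments <- do.call(rbind, segs)
  segments$vo2_drive <- segments$vo2
  bruce <- grepl("^bruce", segments$label)
  if (any(bruce) && subject@sex == "female")
    segments$vo2_drive[bruce] <- segments$vo2[bruce] -
      params$sex_vo2_offset
  list(activities = do.call(rbind, acts),
       segments = segments,
       breathing = do.call(rbind, brth))
}

## ground-truth VO2 at arbitrary times: piecewise first-order relaxation
## toward each segment's steady state
.vo2_truth <- function(segments, tau, v0, col = "vo2") {
  nseg <- nrow(segments)
  target <- segments[[col]]
  v_start <- numeric(nseg)
  v_start[1] <- v0
  for (i in seq_len(nseg - 1L)) {
    len <- segments$t_end[i] - segments$t_start[i]
    v_start[i + 1L] <- target[i] +
      (v_start[i] - target[i]) * exp(-len / tau)
  }
  function(t) {
    idx <- findInterval(t, segments$t_start)
    idx[idx < 1L] <- 1L
    tgt <- target[idx]
    tgt + (v_start[idx] - tgt) * exp(-(t - segments$t_start[idx]) / tau)
  }
}

.lookup_mult <- function(tbl, t, col) {
  out <- rep(1, length(t))
  for (i in seq_len(nrow(tbl))) {
    hit <- t >= tbl$t_start[i] & t < tbl$t_end[i]
    out[hit] <- tbl[[col]][i]
  }
  out
}

.gravity_of <- function(labels) {
  g <- matrix(rep(c(0, 0, 1), each = length(labels)), ncol = 3)
  g[labels == "lie", ] <- rep(c(1, 0, 0), each = sum(labels == "lie"))
  g[labels == "lie_left", ] <- rep(c(0, 1, 0),
                                   each = sum(labels == "lie_left"))
  g[labels == "lie_right", ] <- rep(c(0, -1, 0),
                                    each = sum(labels == "lie_right"))
  g
}

#' Simulate one subject's recording
#'
#' Generates all wearable channels plus the 1 Hz references, coupled to a
#' common ground-truth VO2 trace (first-order kinetics over the subject's
#' schedule): HR is affine in VO2 with AR(1) noise (clipped below
#' `hrMax(age) + 5`); the ECG is a Gaussian-QRS pulse train at intervals
#' `60 / HR` with multiplicative HRV jitter, baseline wander and additive
#' noise; both respiration belts carry a sinusoid at the VO2-coupled
#' breathing rate and amplitude (abdominal scaled by 0.8) plus slow drift;
#' acceleration is posture gravity plus gait harmonics and slow sway.
#' Fully reproducible under `seed`.
#'
#' @param subject a [SubjectInfo-class]
#' @param params from [simParams()]
#' @param seed integer seed
#' @return list with `recording` (a [Recording-class]) and `truth`
#'   (instantaneous 1 Hz VO2/HR/RR/amplitude traces, true R-peak and
#'   breath-peak times, the schedule)
#' @export
simulateSubject <- function(subject, params = simParams(), seed = 1L) {
  set.seed(seed)
  ## subject-level physiological traits, not fully explained by SDI: drawn
  ## once, then treated as this subject's fixed parameters (the schedule's
  ## exhaustion rule sees the same resolved values)
  params$hr_rest <- params$hr_rest + stats::rnorm(1, 0, params$hr_rest_sd)
  params$hr_slope <- .hr_slope_of(params, subject) *
    exp(stats::rnorm(1, 0, params$hr_slope_cv))
  params$vo2_rest <- params$vo2_rest +
    stats::rnorm(1, 0, params$vo2_rest_sd)
  params$rr_rest <- params$rr_rest + stats::rnorm(1, 0, params$rr_rest_sd)
  params$amp_rest <- params$amp_rest * exp(stats::rnorm(1, 0,
                                                        params$amp_gain_cv))
  sched <- makeSchedule(params, subject)
  dur <- as.integer(round(max(sched$segments$t_end)))
  vo2_at <- .vo2_truth(sched$segments, params$tau, params$vo2_rest)
  drive_at <- .vo2_truth(sched$segments, params$tau, params$vo2_rest,
                         col = "vo2_drive")
  t1 <- seq(0, dur - 1)
  vo2_t <- vo2_at(t1)          # measured oxygen uptake (gas analyzer)
  drive_t <- drive_at(t1)      # effort trace driving the wearable channels
  slope <- .hr_slope_of(params, subject)

  ## cardiac truth: affine coupling + AR(1) noise, physiological clip
  ar <- as.numeric(stats::filter(stats::rnorm(dur, 0, params$hr_ar_sd),
                                 params$hr_ar_phi, method = "recursive"))
  hr_t <- params$hr_rest + slope * (drive_t - params$vo2_rest) + ar
  hr_t <- pmin(pmax(hr_t, 30), hrMax(subject@age) + 5)

  ## ECG: integrate-and-fire beat train with HRV jitter
  hr_inst <- stats::approxfun(t1, hr_t, rule = 2)
  beats <- numeric(0)
  tb <- stats::runif(1, 0, 0.5)
  while (tb < dur) {
    beats <- c(beats, tb)
    tb <- tb + 60 / hr_inst(tb) *
      exp(stats::rnorm(1, 0, params$hrv_jitter_sd))
  }
  fs_e <- 200
  n_e <- dur * fs_e
  ecg <- stats::rnorm(n_e, 0, params$ecg_noise_sd)
  te <- (seq_len(n_e) - 1) / fs_e
  ecg <- ecg + params$ecg_wander_amp *
    sin(2 * pi * params$ecg_wander_hz * te + stats::runif(1, 0, 2 * pi))
  halfw <- ceiling(5 * params$qrs_sigma * fs_e)
  for (b in beats) {
    c_idx <- round(b * fs_e) + 1
    lo <- max(1, c_idx - halfw); hi <- min(n_e, c_idx + halfw)
    tt <- (lo:hi - 1) / fs_e
    ecg[lo:hi] <- ecg[lo:hi] +
      params$qrs_amp * exp(-(tt - b)^2 / (2 * params$qrs_sigma^2))
  }

  ## respiration: phase-integrated sinusoid at the VO2-coupled rate
  fs_r <- 25
  n_r <- dur * fs_r
  tr <- (seq_len(n_r) - 1) / fs_r
  rr_t <- (params$rr_rest +
           params$rr_slope * (drive_t - params$vo2_rest)) *
    .lookup_mult(sched$breathing, t1, "rr_mult")
  amp_t <- (params$amp_rest +
            params$amp_slope * (drive_t - params$vo2_rest)) *
    .lookup_mult(sched$breathing, t1, "amp_mult")
  rr25 <- stats::approx(t1, rr_t, tr, rule = 2)$y
  amp25 <- stats::approx(t1, amp_t, tr, rule = 2)$y
  phase <- cumsum(rr25 / 60) / fs_r
  resp <- amp25 * sin(2 * pi * phase)
  ## true breath peaks: phase crossings of k + 1/4 (sine maxima)
  crossings <- which(diff(floor(phase - 0.25)) >= 1)
  breath_times <- tr[pmin(crossings + 1L, n_r)]
  drift_phi <- stats::runif(1, 0, 2 * pi)
  drift <- params$resp_drift_amp *
    sin(2 * pi * params$resp_drift_hz * tr + drift_phi)
  resp_th <- resp + drift + stats::rnorm(n_r, 0, params$resp_noise_sd)
  resp_ab <- 0.8 * resp + 0.9 * drift +
    stats::rnorm(n_r, 0, params$resp_noise_sd)

  ## acceleration: posture gravity + gait harmonics + slow sway + noise
  seg_idx <- findInterval(tr, sched$segments$t_start)
  seg_idx[seg_idx < 1L] <- 1L
  labels <- sched$segments$label[seg_idx]
  speed <- sched$segments$speed[seg_idx]
  grav <- .gravity_of(labels)
  f_step <- 1.0 + 0.3 * speed
  gait_phase <- cumsum(f_step) / fs_r
  a_gait <- ifelse(speed > 0, params$gait_base +
                   params$gait_per_speed * speed, 0)
  a_sway <- params$sway_base + params$sway_per_speed * speed
  sway_phi <- stats::runif(2, 0, 2 * pi)
  acc_z <- grav[, 3] + a_gait * sin(2 * pi * gait_phase) +
    0.4 * a_gait * sin(4 * pi * gait_phase) +
    a_sway * sin(2 * pi * params$sway_hz * tr + sway_phi[1]) +
    stats::rnorm(n_r, 0, params$acc_noise_sd)
  acc_x <- grav[, 1] + 0.5 * a_gait * cos(2 * pi * gait_phase) +
    0.6 * a_sway * sin(2 * pi * 0.11 * tr + sway_phi[2]) +
    stats::rnorm(n_r, 0, params$acc_noise_sd)
  acc_y <- grav[, 2] + stats::rnorm(n_r, 0, params$acc_noise_sd)

  ## 1 Hz references
  vo2_ref <- vo2_t + stats::rnorm(dur, 0, params$vo2_ref_noise_sd)
  hr_ref <- hr_t + stats::rnorm(dur, 0, params$hr_ref_noise_sd)

  rec <- Recording(subject, list(
    Channel("ecg", ecg),
    Channel("resp_thoracic", resp_th),
    Channel("resp_abdominal", resp_ab),
    Channel("acc_x", acc_x), Channel("acc_y", acc_y),
    Channel("acc_z", acc_z),
    Channel("vo2_ref", vo2_ref), Channel("hr_ref", hr_ref)),
    sched$activities)
  list(recording = rec,
       truth = list(t = t1, vo2 = vo2_t, hr = hr_t, rr = rr_t,
                    amplitude = amp_t, r_peak_times = beats,
                    breath_peak_times = breath_times,
                    schedule = sched))
}

#' Simulate a cohort
#'
#' Draws demographics uniformly within the given ranges (heights drawn per
#' sex; weight derived from BMI and height), assigns `n_male` male and
#' `n - n_male` female subjects, derives per-subject seeds
#' deterministically from the cohort seed, and simulates each subject.
#'
#' @param n number of subjects
#' @param params from [simParams()]
#' @param seed integer cohort seed
#' @param n_male number of male subjects (default `ceiling(n / 2)`)
#' @param age_range,bmi_range uniform demographic ranges
#' @return list of per-subject results as returned by [simulateSubject()]
#' @export
simulateCohort <- function(n, params = simParams(), seed = 1L,
                           n_male = ceiling(n / 2),
                           age_range = c(20, 30), bmi_range = c(18, 25)) {
  if (n < 1L) stop("n must be >= 1")
  if (n_male > n) stop("n_male exceeds n")
  set.seed(seed)
  sexes <- c(rep("male", n_male), rep("female", n - n_male))
  ages <- stats::runif(n, age_range[1], age_range[2])
  bmis <- stats::runif(n, bmi_range[1], bmi_range[2])
  heights <- ifelse(sexes == "male", stats::runif(n, 168, 186),
                    stats::runif(n, 155, 173))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    subj <- SubjectInfo(sprintf("S%02d", i), age = round(ages[i], 1),
                        sex = sexes[i], height = round(heights[i], 1),
                        weight = round(bmis[i] * (heights[i] / 100)^2, 1))
    simulateSubject(subj, params, seed = sub_seeds[i])
  })
}
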