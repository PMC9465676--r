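## Assembly of the synchronized 1 Hz feature frame: the contract between
## feature extraction and modeling. Column order is fixed:
## t, hr, hr_pct, rr, dapt, mads, vo2, activity, then the broadcast SDI
## block (subject_id, age, sex, bmi).

.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(stage, ": ", conditionMessage(e), call. = FALSE))
}

#' Build the 1 Hz feature frame of one recording
#'
#' Runs the full extraction chain: channel filtering, R-peak detection and
#' 4 s / 1 s HR windowing, breath detection with per-breath RR and DApt,
#' SVM and blocked MADs, monotone cubic resampling of the per-breath
#' features to 1 Hz, and a 31-point centered moving average over VO2, HR,
#' RR, DApt and MADs. HR% is computed from the smoothed HR with the
#' subject's age-predicted maximum. Each second receives the activity
#' label of the interval containing it (`"unlabeled"` when uncovered),
#' and the subject's SDI block (age, sex, BMI) is broadcast to every row.
#'
#' @param rec a [Recording-class]
#' @param resp_source which belt feeds RR/DApt: `"thoracic"` (default),
#'   `"abdominal"`, or `"sum"` of both
#' @param hr_source `"ecg"` (detect beats on the vest ECG, default) or
#'   `"hr_ref"` (use the chest-strap reference channel)
#' @param smooth_width moving-average window in samples (1 Hz rows)
#' @return data.frame with one row per second; when the recording has no
#'   `vo2_ref` channel the `vo2` column is absent and the frame carries
#'   `attr(, "prediction_only") = TRUE`
#' @export
buildFeatureFrame <- function(rec,
                              resp_source = c("thoracic", "abdominal", "sum"),
                              hr_source = c("ecg", "hr_ref"),
                              smooth_width = 31) {
  resp_source <- match.arg(resp_source)
  hr_source <- match.arg(hr_source)
  stopifnot(is(rec, "Recording"))
  dur <- floor(duration(rec))
  ticks <- seq(0, dur - 1)
  subject <- rec@subject

  ## --- cardiac chain -----------------------------------------------------
  hr <- .with_stage("hr", {
    if (hr_source == "hr_ref") {
      if (!"hr_ref" %in% channelNames(rec)) stop("no hr_ref channel")
      channelData(rec, "hr_ref")[seq_len(dur)]
    } else {
      ecg_f <- filterECG(channelData(rec, "ecg"), samplingRate(rec, "ecg"))
      beats <- detectRPeaks(ecg_f, samplingRate(rec, "ecg"))
      heartRateSeries(beats, duration = dur)$hr
    }
  })

  ## --- respiratory chain -------------------------------------------------
  resp_raw <- .with_stage("respiration", {
    have <- intersect(c("resp_thoracic", "resp_abdominal"), channelNames(rec))
    pick <- switch(resp_source,
      thoracic = "resp_thoracic", abdominal = "resp_abdominal", sum = "sum")
    if (pick == "sum") {
      if (length(have) == 2L)
        channelData(rec, "resp_thoracic") + channelData(rec, "resp_abdominal")
      else channelData(rec, have[1])
    } else {
      if (!pick %in% have) pick <- have[1]
      channelData(rec, pick)
    }
  })
  rrdapt <- .with_stage("respiration", {
    resp_f <- filterRespiration(resp_raw)
    breaths <- detectBreaths(resp_f)
    rr_b <- respRateSeries(breaths)
    da_b <- daptSeries(breaths)
    list(rr = resampleTo1Hz(rr_b$t, rr_b$rr, ticks),
         dapt = resampleTo1Hz(da_b$t, da_b$dapt, ticks))
  })

  ## --- motion chain ------------------------------------------------------
  mads <- .with_stage("acceleration", {
    fs_a <- samplingRate(rec, "acc_x")
    acc <- filterAcceleration(channelData(rec, "acc_x"),
                              channelData(rec, "acc_y"),
                              channelData(rec, "acc_z"), fs_a)
    svm <- svmSeries(acc$acc_x, acc$acc_y, acc$acc_z)
    mt <- madsSeries(svm, fs = fs_a, T = 1)
    v <- mt$mads[seq_len(min(dur, nrow(mt)))]
    if (length(v) < dur) v <- c(v, rep(v[length(v)], dur - length(v)))
    v
  })

  have_vo2 <- "vo2_ref" %in% channelNames(rec)
  vo2 <- if (have_vo2) channelData(rec, "vo2_ref")[seq_len(dur)] else NULL

  ## --- smoothing and assembly -------------------------------------------
  sm <- function(v) smoothMovingAverage(v, width = smooth_width)
  hr_s <- sm(hr)
  frame <- data.frame(t = ticks,
                      hr = hr_s,
                      hr_pct = hrPercent(hr_s, subject@age),
                      rr = sm(rrdapt$rr),
                      dapt = pmax(sm(rrdapt$dapt), 0),
                      mads = pmax(sm(mads), 0))
  if (have_vo2) frame$vo2 <- sm(vo2)
  frame$activity <- activityAt(rec@activities, ticks)
  frame$subject_id <- subject@subject_id
  frame$age <- subject@age
  frame$sex <- subject@sex
  frame$bmi <- subject@bmi
  if (!have_vo2) attr(frame, "prediction_only") <- TRUE
  frame
}

#' Activity label at given seconds
#'
#' @param act activity annotation data.frame (label, t_start, t_end)
#' @param t numeric times (s)
#' @return character labels; `"unlabeled"` where no interval covers `t`
#' @export
activityAt <- function(act, t) {
  lab <- rep("unlabeled", length(t))
  for (i in seq_len(nrow(act))) {
    hit <- t >= act$t_start[i] & t < act$t_end[i]
    lab[hit] <- act$label[i]
  }
  lab
}

#' Read / write feature frames as delimited text
#'
#' The on-disk frame is a CSV with the fixed column order
#' `t, hr, hr_pct, rr, dapt, mads, vo2, activity, subject_id, age, sex,
#' bmi` (the `vo2` column may be absent for prediction-only frames).
#'
#' @param frame a feature frame from [buildFeatureFrame()]
#' @param path file path
#' @return `readFeatureFrame`: the frame; `writeFeatureFrame`: `path`,
#'   invisibly
#' @export
writeFeatureFrame <- function(frame, path) {
  order <- c("t", "hr", "hr_pct", "rr", "dapt", "mads", "vo2", "activity",
             "subject_id", "age", "sex", "bmi")
  utils::write.csv(frame[, intersect(order, names(frame))], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureFrame
#' @export
readFeatureFrame <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
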