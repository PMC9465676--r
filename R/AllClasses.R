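## Central S4 containers: SubjectInfo, Channel, Recording.
## Derived tabular results (beat series, breath series, feature frames,
## evaluation reports) are plain data.frames / lightweight S3 lists.

#' Channel roles and their mandated sampling rates
#'
#' The wearable vest records single-lead ECG at 200 Hz, two respiration belts
#' and a tri-axial accelerometer at 25 Hz; the gas analyzer (reference VO2)
#' and the chest-strap reference HR are sampled at 1 Hz.
#'
#' @return named numeric vector mapping channel name to sampling rate (Hz)
#' @export
#' @examples
#' channelRates()
channelRates <- function() {
  c(ecg = 200,
    resp_thoracic = 25, resp_abdominal = 25,
    acc_x = 25, acc_y = 25, acc_z = 25,
    vo2_ref = 1, hr_ref = 1)
}

## activity vocabulary (rest postures, treadmill stages, recovery)
.activityLabels <- c("stand", "lie", "lie_left", "lie_right", "sit",
                     "walk", paste0("bruce_level_", 1:7), "recovery")

#' Valid activity labels
#'
#' Five rest postures, treadmill walk (warm-up), seven Bruce stages and
#' recovery. Seconds not covered by any annotated interval are reported as
#' `"unlabeled"` in feature frames.
#'
#' @return character vector of recognised activity labels
#' @export
activityLabels <- function() .activityLabels

#' Subject demographics
#'
#' Demographic information of one subject; `age`, `sex` and `bmi` form the
#' SDI (subject demographic information) feature block used by the VO2
#' models. BMI is validated against weight / (height/100)^2 when height and
#' weight are given.
#'
#' @slot subject_id character scalar identifier
#' @slot age years, > 0
#' @slot sex `"male"` or `"female"`
#' @slot height cm (may be `NA`)
#' @slot weight kg (may be `NA`)
#' @slot bmi kg/m^2
#' @export
setClass("SubjectInfo",
  representation(subject_id = "character", age = "numeric", sex = "character",
                 height = "numeric", weight = "numeric", bmi = "numeric"),
  prototype(height = NA_real_, weight = NA_real_))

setValidity("SubjectInfo", function(object) {
  msg <- character()
  if (length(object@subject_id) != 1L || !nzchar(object@subject_id))
    msg <- c(msg, "subject_id must be a non-empty string")
  if (length(object@age) != 1L || is.na(object@age) || object@age <= 0)
    msg <- c(msg, "age must be a positive scalar")
  if (!object@sex %in% c("male", "female"))
    msg <- c(msg, "sex must be 'male' or 'female'")
  for (f in c("height", "weight")) {
    v <- slot(object, f)
    if (!is.na(v) && v <= 0) msg <- c(msg, paste(f, "must be positive"))
  }
  if (length(object@bmi) != 1L || is.na(object@bmi) || object@bmi <= 0)
    msg <- c(msg, "bmi must be a positive scalar")
  if (!is.na(object@height) && !is.na(object@weight)) {
    bmi_chk <- object@weight / (object@height / 100)^2
    if (abs(bmi_chk - object@bmi) > 0.1)
      msg <- c(msg, sprintf("bmi %.2f inconsistent with weight/height^2 = %.2f",
                            object@bmi, bmi_chk))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SubjectInfo
#'
#' @param subject_id identifier string
#' @param age years (> 0)
#' @param sex `"male"` or `"female"`
#' @param height cm, optional when `bmi` is supplied
#' @param weight kg, optional when `bmi` is supplied
#' @param bmi kg/m^2; computed from height and weight when omitted
#' @return a [SubjectInfo-class]
#' @export
#' @examples
#' SubjectInfo("S01", age = 24, sex = "female", height = 165, weight = 55)
SubjectInfo <- function(subject_id, age, sex, height = NA_real_,
                        weight = NA_real_, bmi = NULL) {
  if (is.null(bmi)) {
    if (is.na(height) || is.na(weight))
      stop("either bmi or both height and weight must be given")
    bmi <- weight / (height / 100)^2
  }
  new("SubjectInfo", subject_id = as.character(subject_id),
      age = as.numeric(age), sex = as.character(sex),
      height = as.numeric(height), weight = as.numeric(weight),
      bmi = as.numeric(bmi))
}

setMethod("show", "SubjectInfo", function(object) {
  cat(sprintf("SubjectInfo '%s': %s, %g y, BMI %.1f kg/m2\n",
              object@subject_id, object@sex, object@age, object@bmi))
})

#' A single recorded channel
#'
#' One uniformly sampled signal; `name` fixes its physiological role and
#' thereby its mandated sampling rate (see [channelRates()]).
#'
#' @slot name channel role, one of `names(channelRates())`
#' @slot fs sampling rate in Hz
#' @slot samples numeric sample vector (sample 1 is the common time origin)
#' @export
setClass("Channel",
  representation(name = "character", fs = "numeric", samples = "numeric"))

setValidity("Channel", function(object) {
  msg <- character()
  rates <- channelRates()
  if (!object@name %in% names(rates))
    msg <- c(msg, paste0("unknown channel name '", object@name, "'"))
  else if (!isTRUE(all.equal(object@fs, rates[[object@name]])))
    msg <- c(msg, sprintf("sampling-rate violation: %s requires %g Hz, got %g",
                          object@name, rates[[object@name]], object@fs))
  if (anyNA(object@samples))
    msg <- c(msg, "samples must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct a Channel
#'
#' @param name channel role (see [channelRates()])
#' @param samples numeric sample vector
#' @param fs sampling rate; defaults to the rate mandated for `name`
#' @return a [Channel-class]
#' @export
Channel <- function(name, samples, fs = NULL) {
  if (is.null(fs)) {
    if (!name %in% names(channelRates()))
      stop("unknown channel name '", name, "'")
    fs <- channelRates()[[name]]
  }
  new("Channel", name = name, fs = as.numeric(fs),
      samples = as.numeric(samples))
}

setMethod("show", "Channel", function(object) {
  cat(sprintf("Channel %s: %d samples @ %g Hz (%.1f s)\n", object@name,
              length(object@samples), object@fs,
              length(object@samples) / object@fs))
})

#' @rdname recording-accessors
#' @export
setMethod("samplingRate", "Channel", function(x, ...) x@fs)

#' @rdname recording-accessors
#' @export
setMethod("channelData", "Channel", function(x, ...) x@samples)

#' Multichannel wearable recording
#'
#' Aligned channels of one experimental session, all sharing sample 1 as a
#' common time origin, plus the subject's demographics and the
#' activity-interval annotation (`data.frame` with columns `label`,
#' `t_start`, `t_end`; seconds from recording start, half-open
#' `[t_start, t_end)`).
#'
#' A valid recording carries ECG, at least one respiration belt and all
#' three acceleration axes; `vo2_ref` is additionally required for training
#' and evaluation (checked at feature-frame / model stage, not here, so that
#' prediction-only recordings remain representable).
#'
#' @slot subject a [SubjectInfo-class]
#' @slot channels named list of [Channel-class] objects
#' @slot activities data.frame(label, t_start, t_end)
#' @export
setClass("Recording",
  representation(subject = "SubjectInfo", channels = "list",
                 activities = "data.frame"))

setValidity("Recording", function(object) {
  msg <- character()
  nm <- vapply(object@channels, function(ch) ch@name, character(1))
  if (length(nm) && !identical(names(object@channels), unname(nm)))
    msg <- c(msg, "channel list names must match channel roles")
  if (anyDuplicated(nm)) msg <- c(msg, "duplicate channel")
  mandatory <- c("ecg", "acc_x", "acc_y", "acc_z")
  if (!all(mandatory %in% nm) || !any(c("resp_thoracic", "resp_abdominal") %in% nm))
    msg <- c(msg, "incomplete recording")
  act <- object@activities
  if (nrow(act)) {
    if (!all(c("label", "t_start", "t_end") %in% names(act)))
      msg <- c(msg, "activities must have columns label, t_start, t_end")
    else {
      if (any(act$t_end <= act$t_start))
        msg <- c(msg, "activity intervals must satisfy t_end > t_start")
      o <- order(act$t_start)
      if (nrow(act) > 1 && any(act$t_start[o][-1] < act$t_end[o][-nrow(act)] - 1e-9))
        msg <- c(msg, "activity intervals overlap")
      if (!all(act$label %in% .activityLabels))
        msg <- c(msg, "unknown activity label")
      dur <- min(vapply(object@channels,
                        function(ch) length(ch@samples) / ch@fs, numeric(1)))
      if (max(act$t_end) > dur + 1)
        msg <- c(msg, "channels do not cover the activity intervals")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param subject a [SubjectInfo-class]
#' @param channels list of [Channel-class] objects (names optional; they are
#'   set from the channel roles)
#' @param activities data.frame(label, t_start, t_end); may be empty
#' @return a [Recording-class]
#' @export
Recording <- function(subject, channels,
                      activities = data.frame(label = character(),
                                              t_start = numeric(),
                                              t_end = numeric())) {
  names(channels) <- vapply(channels, function(ch) ch@name, character(1))
  new("Recording", subject = subject, channels = channels,
      activities = as.data.frame(activities))
}

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording of subject '%s' (%.1f s)\n",
              object@subject@subject_id, duration(object)))
  for (ch in object@channels) show(ch)
  if (nrow(object@activities))
    cat(sprintf("  %d activity intervals (%s)\n", nrow(object@activities),
                paste(unique(object@activities$label), collapse = ", ")))
})

#' @rdname recording-accessors
#' @export
setMethod("subjectInfo", "Recording", function(x, ...) x@subject)

#' @rdname recording-accessors
#' @export
setMethod("channelNames", "Recording", function(x, ...) names(x@channels))

#' @rdname recording-accessors
#' @export
setMethod("activities", "Recording", function(x, ...) x@activities)

#' @rdname recording-accessors
#' @param which channel name
#' @export
setMethod("channelData", "Recording", function(x, which, ...) {
  if (!which %in% names(x@channels))
    stop("no such channel: ", which)
  x@channels[[which]]@samples
})

#' @rdname recording-accessors
#' @export
setMethod("samplingRate", "Recording", function(x, which, ...) {
  if (!which %in% names(x@channels))
    stop("no such channel: ", which)
  x@channels[[which]]@fs
})

#' @rdname recording-accessors
#' @export
setMethod("duration", "Recording", function(x, ...) {
  min(vapply(x@channels, function(ch) length(ch@samples) / ch@fs, numeric(1)))
})
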