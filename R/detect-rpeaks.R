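## QRS detection after the open-source Hamilton ("E. P. Limited") rules:
## band-limited differentiation, rectification, 80 ms moving-window
## integration, adaptive amplitude threshold with separate QRS/noise peak
## estimates, 200 ms refractory period and RR-based searchback.

#' Detect R peaks in a band-passed ECG
#'
#' Expects an ECG already band-pass filtered to 3-45 Hz (see
#' [filterECG()]). Returns a beat series: the detected R-peak times and the
#' successive R-R intervals, with a physiological gate retaining intervals
#' in \[0.24, 3\] s (20-250 BPM).
#'
#' @param x filtered ECG samples
#' @param fs sampling rate in Hz (200 for the wearable vest)
#' @return object of class `"BeatSeries"`: list with `r_peak_times` (s,
#'   strictly increasing), `rr_intervals` (s, gated), `fs`
#' @export
detectRPeaks <- function(x, fs = 200) {
  n <- length(x)
  if (n < fs) stop("signal too short")
  ## envelope: rectified derivative, integrated over 80 ms
  d <- c(0, diff(x))
  w <- max(3L, as.integer(round(0.08 * fs)))
  env <- stats::filter(abs(d), rep(1 / w, w), sides = 2)
  env <- as.numeric(env)
  env[is.na(env)] <- 0
  ## candidate peaks: strict local maxima of the envelope
  core <- env[2:(n - 1)]
  cand <- which(core > env[1:(n - 2)] & core >= env[3:n]) + 1L
  cand <- cand[env[cand] > 0]
  if (length(cand) == 0L) stop("no QRS detected")
  refractory <- 0.2 * fs
  ## adaptive thresholding over candidates in time order
  init <- cand[cand <= 2 * fs]
  spk <- if (length(init)) max(env[init]) else max(env[cand])
  npk <- stats::median(env[cand[seq_len(min(50L, length(cand)))]])
  if (npk >= spk) npk <- spk / 4
  thr_coef <- 0.3125
  peaks <- integer(0)
  rejected <- integer(0)
  mean_rr <- NA_real_
  for (i in cand) {
    thr <- npk + thr_coef * (spk - npk)
    since <- if (length(peaks)) i - peaks[length(peaks)] else Inf
    if (env[i] >= thr && since > refractory) {
      peaks <- c(peaks, i)
      spk <- 0.875 * spk + 0.125 * env[i]
    } else {
      ## searchback: long gap -> revisit the best rejected candidate
      if (length(peaks) && !is.na(mean_rr) && since > 1.5 * mean_rr) {
        gap <- rejected[rejected > peaks[length(peaks)] + refractory &
                        rejected < i - refractory]
        if (length(gap)) {
          best <- gap[which.max(env[gap])]
          if (env[best] >= 0.5 * thr) {
            peaks <- c(peaks, best)
            spk <- 0.875 * spk + 0.125 * env[best]
          }
        }
      }
      since <- if (length(peaks)) i - peaks[length(peaks)] else Inf
      if (env[i] >= thr && since > refractory) {
        peaks <- c(peaks, i)
        spk <- 0.875 * spk + 0.125 * env[i]
      } else if (since > refractory) {
        rejected <- c(rejected, i)
        npk <- 0.875 * npk + 0.125 * env[i]
      }
    }
    if (length(peaks) >= 2L) {
      rr_recent <- diff(utils::tail(peaks, 9L))
      mean_rr <- mean(rr_recent)
    }
  }
  if (length(peaks) == 0L) stop("no QRS detected")
  ## refine: R peak = maximum of the filtered ECG within +-60 ms
  half <- as.integer(round(0.06 * fs))
  ridx <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  ridx <- sort(unique(ridx))
  ## de-duplicate refinements that collapsed onto the same R wave
  if (length(ridx) > 1L)
    ridx <- ridx[c(TRUE, diff(ridx) > refractory)]
  times <- (ridx - 1) / fs
  rr <- diff(times)
  structure(list(r_peak_times = times,
                 rr_intervals = rr[rr >= 0.24 & rr <= 3.0],
                 fs = fs),
            class = "BeatSeries")
}

#' @export
print.BeatSeries <- function(x, ...) {
  cat(sprintf("BeatSeries: %d R peaks over %.1f s (median RR %.3f s)\n",
              length(x$r_peak_times),
              diff(range(x$r_peak_times)),
              stats::median(x$rr_intervals)))
  invisible(x)
}
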