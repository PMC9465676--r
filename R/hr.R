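#' Windowed 1 Hz heart-rate series
#'
#' At every 1 s tick, HR is the mean of `60 / rr` over the R-R intervals
#' whose terminating R peak lies in the trailing window (default 4 s).
#' Ticks whose window holds no interval carry the previous tick's value
#' forward; leading empty ticks take the first available value.
#'
#' @param beats a `"BeatSeries"` from [detectRPeaks()]
#' @param duration recording length in seconds (ticks run 0 .. duration-1);
#'   defaults to the last R-peak time
#' @param window trailing window length in s
#' @param step tick spacing in s
#' @return data.frame with columns `t` (s) and `hr` (BPM)
#' @export
heartRateSeries <- function(beats, duration = NULL, window = 4, step = 1) {
  times <- beats$r_peak_times
  if (length(times) == 0L) stop("no beats")
  if (is.null(duration)) duration <- max(times)
  rr <- diff(times)
  ok <- rr >= 0.24 & rr <= 3.0
  term <- times[-1][ok]          # terminating peak of each retained interval
  rate <- 60 / rr[ok]
  if (length(term) == 0L) stop("no beats")
  ticks <- seq(0, duration - step, by = step)
  hr <- rep(NA_real_, length(ticks))
  for (k in seq_along(ticks)) {
    t <- ticks[k] + step         # window ends at the tick's right edge
    inw <- term > t - window & term <= t
    if (any(inw)) hr[k] <- mean(rate[inw])
    else if (k > 1L) hr[k] <- hr[k - 1L]
  }
  if (anyNA(hr)) {
    first <- which(!is.na(hr))[1]
    if (is.na(first)) stop("no beats")
    hr[seq_len(first - 1L)] <- hr[first]
  }
  data.frame(t = ticks, hr = hr)
}

#' Age-predicted maximum heart rate
#'
#' `208 - 0.7 * age` (BPM).
#'
#' @param age years, > 0
#' @return maximum HR in BPM
#' @export
#' @examples
#' hrMax(40)   # 180
hrMax <- function(age) {
  if (any(is.na(age)) || any(age <= 0)) stop("age must be positive")
  208 - 0.7 * age
}

#' Heart rate as a percentage of the age-predicted maximum
#'
#' `100 * hr / hrMax(age)`.
#'
#' @param hr heart rate in BPM, > 0
#' @param age years, > 0
#' @return HR% (percent)
#' @export
hrPercent <- function(hr, age) {
  if (any(is.na(hr)) || any(hr <= 0)) stop("hr must be positive")
  100 * hr / hrMax(age)
}
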