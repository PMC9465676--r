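## Respiratory cycle detection on the cleaned belt signal: alternating
## peak/trough extrema with a minimum breath separation, each peak paired
## with the nearest preceding trough.

#' Detect breaths in a filtered respiration signal
#'
#' Finds local maxima (inspiratory peaks) and minima (expiratory troughs)
#' of the detrended, band-passed belt signal, enforcing a minimum
#' peak-to-peak separation of `1 / max_rate_hz` seconds (default 0.7 Hz,
#' i.e. at most 42 breaths/min). Each peak is paired with the nearest
#' preceding trough; unpaired extrema are dropped. The per-breath tidal
#' amplitude proxy DApt is the paired peak minus trough amplitude.
#'
#' @param x filtered respiration samples (near-zero mean)
#' @param fs sampling rate in Hz (25 for the belts)
#' @param max_rate_hz maximum plausible breathing frequency (Hz)
#' @return object of class `"BreathSeries"`: list with `peak_times`,
#'   `peak_amplitudes`, `trough_times`, `trough_amplitudes`,
#'   `breath_intervals` (s, between successive peaks)
#' @export
detectBreaths <- function(x, fs = 25, max_rate_hz = 0.7) {
  n <- length(x)
  if (n < 3L) stop("too few breaths")
  sep <- 1 / max_rate_hz
  min_gap <- as.integer(round(sep * fs))
  core <- x[2:(n - 1)]
  imax <- which(core > x[1:(n - 2)] & core >= x[3:n]) + 1L
  imin <- which(core < x[1:(n - 2)] & core <= x[3:n]) + 1L
  ## amplitude floor rejects micro-ripples around zero
  floor_amp <- 0.05 * stats::sd(x)
  if (!is.finite(floor_amp) || floor_amp == 0) stop("too few breaths")
  imax <- imax[x[imax] > floor_amp]
  imin <- imin[x[imin] < -floor_amp]
  .thin <- function(idx, keep_larger) {
    if (length(idx) < 2L) return(idx)
    out <- idx[1]
    for (i in idx[-1]) {
      last <- out[length(out)]
      if (i - last >= min_gap) out <- c(out, i)
      else {
        better <- if (keep_larger) x[i] > x[last] else x[i] < x[last]
        if (better) out[length(out)] <- i
      }
    }
    out
  }
  imax <- .thin(imax, TRUE)
  imin <- .thin(imin, FALSE)
  if (length(imax) < 2L) stop("too few breaths")
  ## pair each peak with the nearest preceding trough
  pk_keep <- integer(0); tr_keep <- integer(0)
  for (p in imax) {
    prev <- imin[imin < p]
    if (length(prev) == 0L) next
    tr <- prev[length(prev)]
    ## enforce alternation: trough must come after the previous kept peak
    if (length(pk_keep) && tr <= pk_keep[length(pk_keep)]) next
    pk_keep <- c(pk_keep, p)
    tr_keep <- c(tr_keep, tr)
  }
  if (length(pk_keep) < 2L) stop("too few breaths")
  structure(list(peak_times = (pk_keep - 1) / fs,
                 peak_amplitudes = x[pk_keep],
                 trough_times = (tr_keep - 1) / fs,
                 trough_amplitudes = x[tr_keep],
                 breath_intervals = diff((pk_keep - 1) / fs),
                 fs = fs),
            class = "BreathSeries")
}

#' @export
print.BreathSeries <- function(x, ...) {
  cat(sprintf("BreathSeries: %d breaths (median interval %.2f s)\n",
              length(x$peak_times), stats::median(x$breath_intervals)))
  invisible(x)
}

#' Per-breath respiration rate
#'
#' RR at each breath is 60 divided by the peak-to-peak interval in
#' seconds; the value is timestamped at the terminating peak.
#'
#' @param breaths a `"BreathSeries"` from [detectBreaths()]
#' @return data.frame with columns `t` (s) and `rr` (breaths/min)
#' @export
respRateSeries <- function(breaths) {
  if (length(breaths$peak_times) < 2L) stop("too few breaths")
  data.frame(t = breaths$peak_times[-1],
             rr = 60 / diff(breaths$peak_times))
}

#' Per-breath tidal amplitude difference (DApt)
#'
#' Elementwise inspiratory-peak amplitude minus the paired preceding
#' trough amplitude, timestamped at the peak.
#'
#' @param breaths a `"BreathSeries"` from [detectBreaths()]
#' @return data.frame with columns `t` (s) and `dapt` (signal units)
#' @export
daptSeries <- function(breaths) {
  data.frame(t = breaths$peak_times,
             dapt = breaths$peak_amplitudes - breaths$trough_amplitudes)
}
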