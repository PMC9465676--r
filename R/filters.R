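## Channel-specific cleaning chains applied before feature extraction:
##   ECG          : 201-tap linear-phase FIR band-pass 3-45 Hz (Hamming),
##                  group delay compensated
##   respiration  : db4 wavelet baseline removal, then zero-phase Butterworth
##                  band-pass 0.1-0.35 Hz (order 4, forward-backward)
##   acceleration : zero-phase Butterworth low-pass 0.32 Hz per axis (order 4)
## All filters reflect-pad the signal before filtering and strip the pad
## afterwards so edge transients never reach the features.

#' Filter design specifications used by the pipeline
#'
#' Returns the parameter set of one of the pipeline's filters as a plain
#' list so every cutoff and order is auditable and overridable through the
#' pipeline config.
#'
#' @param kind one of `"fir_bandpass"` (ECG), `"butter_bandpass"`
#'   (respiration), `"lowpass"` (acceleration), `"wavelet_detrend"`
#'   (respiration baseline)
#' @return list with elements `kind`, `band` (Hz), `order`/`taps`/`level`,
#'   `fs`, `zero_phase`
#' @export
filterSpec <- function(kind = c("fir_bandpass", "butter_bandpass",
                                "lowpass", "wavelet_detrend")) {
  kind <- match.arg(kind)
  switch(kind,
    fir_bandpass    = list(kind = kind, band = c(3, 45), taps = 201,
                           fs = 200, window = "hamming", zero_phase = FALSE),
    butter_bandpass = list(kind = kind, band = c(0.1, 0.35), order = 4,
                           fs = 25, zero_phase = TRUE),
    lowpass         = list(kind = kind, band = 0.32, order = 4,
                           fs = 25, zero_phase = TRUE),
    wavelet_detrend = list(kind = kind, wavelet = "db4", level = 9, fs = 25))
}

## reflect padding (odd extension about the end points keeps slopes smooth)
.reflect_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
}

.unpad <- function(x, p, n) x[(p + 1L):(p + n)]

## zero-phase IIR application with reflect padding
.filtfilt_padded <- function(filt, x, pad = 1000L) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  y <- signal::filtfilt(filt, .reflect_pad(x, pad))
  .unpad(y, pad, n)
}

#' ECG band-pass filter (3-45 Hz FIR)
#'
#' Linear-phase FIR band-pass (201 taps, Hamming window) at 200 Hz,
#' removing baseline wander and ST-band interference while amplifying the
#' R wave for peak detection. The constant group delay of (taps-1)/2
#' samples is compensated so R-wave timing is preserved; output length
#' equals input length.
#'
#' @param x ECG samples at 200 Hz
#' @param fs sampling rate, must be 200
#' @return filtered signal, same length as `x`
#' @export
filterECG <- function(x, fs = 200) {
  spec <- filterSpec("fir_bandpass")
  if (fs != spec$fs) stop("sampling-rate violation: ECG filter expects 200 Hz")
  if (length(x) <= spec$taps) stop("signal too short")
  b <- signal::fir1(spec$taps - 1L, spec$band / (fs / 2), type = "pass")
  b <- b - mean(b)      # exact DC null; negligible effect in the passband
  delay <- (spec$taps - 1L) %/% 2L
  n <- length(x)
  pad <- spec$taps
  xp <- c(.reflect_pad(x, pad), numeric(delay))
  y <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  y[is.na(y)] <- 0
  y[(pad + delay + 1L):(pad + delay + n)]
}

#' Respiration cleaning chain
#'
#' Removes the belt offset with a db4 wavelet baseline (approximation below
#' ~0.012 Hz subtracted) and then applies a zero-phase order-4 Butterworth
#' band-pass, 0.1-0.35 Hz, at 25 Hz. Output has near-zero mean.
#'
#' @param x respiration samples at 25 Hz
#' @param fs sampling rate, must be 25
#' @return filtered signal, same length as `x`
#' @export
filterRespiration <- function(x, fs = 25) {
  spec <- filterSpec("butter_bandpass")
  wspec <- filterSpec("wavelet_detrend")
  if (fs != spec$fs) stop("sampling-rate violation: respiration filter expects 25 Hz")
  if (length(x) < 2L^wspec$level) stop("signal too short")
  x <- waveletDetrend(x, level = wspec$level)
  bf <- signal::butter(spec$order, spec$band / (fs / 2), type = "pass")
  .filtfilt_padded(bf, x, pad = 2000L)
}

#' Acceleration low-pass chain
#'
#' Zero-phase order-4 Butterworth low-pass at 0.32 Hz applied to each axis
#' (25 Hz); the DC (gravity) component is preserved.
#'
#' @param acc_x,acc_y,acc_z axis samples at 25 Hz, equal lengths
#' @param fs sampling rate, must be 25
#' @return list with filtered `acc_x`, `acc_y`, `acc_z`
#' @export
filterAcceleration <- function(acc_x, acc_y, acc_z, fs = 25) {
  spec <- filterSpec("lowpass")
  if (fs != spec$fs) stop("sampling-rate violation: acceleration filter expects 25 Hz")
  if (length(acc_x) != length(acc_y) || length(acc_y) != length(acc_z))
    stop("channel mismatch: acceleration axes differ in length")
  bf <- signal::butter(spec$order, spec$band / (fs / 2), type = "low")
  list(acc_x = .filtfilt_padded(bf, acc_x),
       acc_y = .filtfilt_padded(bf, acc_y),
       acc_z = .filtfilt_padded(bf, acc_z))
}
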