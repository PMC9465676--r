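#' Resample irregular support points onto a 1 Hz grid
#'
#' Shape-preserving (monotone cubic, Fritsch-Carlson) interpolation of
#' values given at irregular times, evaluated on a regular grid. Inside
#' the support range the interpolant never overshoots the local data
#' envelope; grid points outside the support take the nearest endpoint
#' value.
#'
#' @param times strictly increasing support times (s), length >= 2
#' @param values values at `times`
#' @param t_out output grid (s); default `0, 1, 2, ...` covering the
#'   support range
#' @return numeric vector of interpolated values at `t_out`
#' @export
resampleTo1Hz <- function(times, values, t_out = NULL) {
  if (length(times) < 2L) stop("need at least 2 support points")
  if (any(diff(times) <= 0)) stop("support times must be strictly increasing")
  if (is.null(t_out)) t_out <- seq(0, floor(max(times)), by = 1)
  f <- stats::splinefun(times, values, method = "monoH.FC")
  tc <- pmin(pmax(t_out, times[1]), times[length(times)])
  y <- f(tc)
  ## Fritsch-Carlson can overshoot marginally at interior extrema; clamp
  ## each output to the envelope of its bracketing support values
  idx <- findInterval(tc, times, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(times) - 1L)
  lo <- pmin(values[idx], values[idx + 1L])
  hi <- pmax(values[idx], values[idx + 1L])
  pmin(pmax(y, lo), hi)
}

#' Centered moving average with edge renormalization
#'
#' 31-point (by default) centered moving average; at the edges the window
#' is truncated to the available samples and renormalized, so the output
#' has the same length as the input and a constant series is reproduced
#' exactly.
#'
#' @param x numeric series
#' @param width odd window width in samples
#' @return smoothed series, same length as `x`
#' @export
smoothMovingAverage <- function(x, width = 31) {
  n <- length(x)
  if (n == 0L) return(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
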