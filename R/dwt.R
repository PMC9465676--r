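## Periodized orthogonal discrete wavelet transform (Daubechies db4, 8 taps).
## Used to estimate and remove the slow baseline of the respiration belts:
## the approximation at a deep decomposition level is the baseline.

## db4 scaling (low-pass) filter, orthonormal: sum = sqrt(2), energy = 1
.db4_lo <- c(0.230377813308855230, 0.714846570552541530,
             0.630880767929590360, -0.027983769416983850,
             -0.187034811718881140, 0.030841381835986970,
             0.032883011666982950, -0.010597401784997280)

.qmf <- function(h) rev(h) * (-1)^(seq_along(h) - 1)

## one periodized analysis step: circular convolution + dyadic decimation
.dwt_step <- function(x, f) {
  n <- length(x)
  l <- length(f)
  half <- n %/% 2L
  idx <- outer(0:(l - 1L), 2L * (seq_len(half) - 1L), "+") %% n + 1L
  as.numeric(crossprod(matrix(x[idx], nrow = l), f))
}

## one periodized synthesis step (inverse of .dwt_step pair)
.idwt_step <- function(a, d, lo, hi) {
  half <- length(a)
  n <- 2L * half
  l <- length(lo)
  x <- numeric(n)
  for (j in seq_len(l)) {
    idx <- (2L * (seq_len(half) - 1L) + (j - 1L)) %% n + 1L
    contrib <- lo[j] * a + hi[j] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Wavelet baseline estimation and removal
#'
#' Decomposes a signal with a periodized db4 discrete wavelet transform,
#' zeroes all detail coefficients, and reconstructs the coarse approximation,
#' which serves as the slow baseline (offset / drift) of the signal.
#' `waveletDetrend()` subtracts that baseline.
#'
#' At 25 Hz and `level = 9` the retained approximation band lies below
#' `25 / 2^10` = 0.012 Hz, well under the respiratory band, so breathing
#' oscillations survive detrending intact. The input is reflect-padded to
#' the next multiple of `2^level` before the periodized transform to avoid
#' wrap-around artefacts.
#'
#' @param x numeric signal
#' @param level decomposition depth (default 9)
#' @return `waveletBaseline`: the baseline (same length as `x`);
#'   `waveletDetrend`: `x` minus its baseline
#' @export
#' @examples
#' t <- seq(0, 120, by = 1 / 25)
#' x <- sin(2 * pi * 0.25 * t) + t / 12          # breathing + drift
#' d <- waveletDetrend(x, level = 9)
#' max(abs(mean(d)))                             # near-zero mean
waveletBaseline <- function(x, level = 9) {
  n <- length(x)
  block <- 2L^level
  if (n < block)
    stop("signal too short: need at least ", block, " samples for level ",
         level, " decomposition")
  ## reflect-pad to a multiple of 2^level (periodized DWT needs even splits)
  ntot <- as.integer(ceiling(n / block) * block)
  pad <- ntot - n
  xp <- if (pad > 0) c(x, x[n - seq_len(pad) + 1L]) else x
  lo <- .db4_lo
  hi <- .qmf(lo)
  approx <- xp
  details <- vector("list", level)
  for (j in seq_len(level)) {
    details[[j]] <- .dwt_step(approx, hi)
    approx <- .dwt_step(approx, lo)
  }
  for (j in rev(seq_len(level)))
    approx <- .idwt_step(approx, numeric(length(details[[j]])), lo, hi)
  approx[seq_len(n)]
}

#' @rdname waveletBaseline
#' @export
waveletDetrend <- function(x, level = 9) {
  x - waveletBaseline(x, level = level)
}
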