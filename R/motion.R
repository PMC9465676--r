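#' Signal vector magnitude of tri-axial acceleration
#'
#' Elementwise Euclidean norm `sqrt(x^2 + y^2 + z^2)` of the three
#' (filtered) acceleration axes.
#'
#' @param acc_x,acc_y,acc_z axis samples, equal lengths
#' @return numeric SVM series, same length as the inputs
#' @export
#' @examples
#' svmSeries(3, 4, 0)   # 5
svmSeries <- function(acc_x, acc_y, acc_z) {
  if (length(acc_x) != length(acc_y) || length(acc_y) != length(acc_z))
    stop("channel mismatch: acceleration axes differ in length")
  sqrt(acc_x^2 + acc_y^2 + acc_z^2)
}

#' Mean absolute differential of SVM per time block (MADs)
#'
#' Motion-intensity feature: over non-overlapping blocks of `T` seconds
#' (default 1 s, i.e. `T * fs` samples), the mean absolute successive
#' difference of the SVM series,
#' `1 / (T*fs - 1) * sum(|SVM[i+1] - SVM[i]|)` within the block
#' (`T*fs - 1` differences per block).
#'
#' @param svm SVM series from [svmSeries()]
#' @param fs sampling rate in Hz
#' @param T block length in seconds
#' @return data.frame with columns `t` (block start, s) and `mads`
#' @export
madsSeries <- function(svm, fs = 25, T = 1) {
  blk <- as.integer(round(T * fs))
  if (blk < 2L) stop("block must span at least 2 samples")
  nblk <- length(svm) %/% blk
  if (nblk < 1L) stop("signal too short for one MADs block")
  m <- matrix(svm[seq_len(nblk * blk)], nrow = blk)
  mads <- colSums(abs(m[-1L, , drop = FALSE] - m[-blk, , drop = FALSE])) /
    (blk - 1L)
  data.frame(t = (seq_len(nblk) - 1L) * T, mads = mads)
}
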