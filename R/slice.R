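#' Restrict a recording to the intervals of one activity
#'
#' Extracts, for every channel, exactly the samples whose timestamps fall in
#' the half-open intervals `[t_start, t_end)` annotated with `label`, and
#' concatenates them (multiple intervals in time order). Sample `i` of a
#' channel at rate `fs` carries timestamp `(i - 1) / fs`.
#'
#' @param rec a [Recording-class]
#' @param label an activity label present in `activities(rec)`
#' @return a [Recording-class] whose channels hold only the matching
#'   samples; its annotation is the matching intervals re-based to the
#'   sliced timeline
#' @export
sliceByActivity <- function(rec, label) {
  act <- rec@activities
  hits <- act[act$label == label, , drop = FALSE]
  if (nrow(hits) == 0L) stop("no such activity: ", label)
  hits <- hits[order(hits$t_start), , drop = FALSE]
  channels <- lapply(rec@channels, function(ch) {
    t <- (seq_along(ch@samples) - 1) / ch@fs
    keep <- rep(FALSE, length(t))
    for (i in seq_len(nrow(hits)))
      keep <- keep | (t >= hits$t_start[i] & t < hits$t_end[i])
    Channel(ch@name, ch@samples[keep], fs = ch@fs)
  })
  off <- c(0, cumsum(hits$t_end - hits$t_start))
  new_act <- data.frame(label = hits$label,
                        t_start = off[-length(off)],
                        t_end = off[-1])
  Recording(rec@subject, channels, new_act)
}
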