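## Minimal European Data Format (EDF) writer/reader: ASCII header (256 bytes
## + 256 per signal), 1-second data records, 16-bit little-endian samples
## linearly scaled between the per-signal physical and digital ranges.
## Covers multirate physiological recordings; subject demographics and
## activity annotations travel in plain-text sidecar files next to the .edf.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

.edf_num <- function(x, width = 8) {
  s <- formatC(x, digits = 6, format = "g")
  if (nchar(s) > width) s <- formatC(x, digits = 4, format = "g")
  .edf_pad(s, width)
}

.sidecar <- function(path, what) sub("\\.edf$", paste0("_", what, ".csv"), path)

.write_recording_edf <- function(rec, path) {
  chans <- rec@channels
  ns <- length(chans)
  durs <- vapply(chans, function(ch) length(ch@samples) / ch@fs, numeric(1))
  nrec <- as.integer(round(durs[1]))
  if (any(abs(durs - nrec) > 1e-9))
    stop("EDF dialect requires equal whole-second channel durations")
  spr <- vapply(chans, function(ch) as.integer(round(ch@fs)), integer(1))
  dmin <- -32767L; dmax <- 32767L
  pmin <- numeric(ns); pmax <- numeric(ns)
  digital <- vector("list", ns)
  for (s in seq_len(ns)) {
    x <- chans[[s]]@samples
    lo <- min(x); hi <- max(x)
    if (hi <= lo) hi <- lo + 1
    ## store the rounded header values and quantize against those, so the
    ## scaling used on write matches the scaling recovered on read
    lo <- as.numeric(trimws(.edf_num(lo))); hi <- as.numeric(trimws(.edf_num(hi)))
    if (hi <= lo) hi <- lo + 1
    pmin[s] <- lo; pmax[s] <- hi
    d <- as.integer(round((x - lo) / (hi - lo) * (dmax - dmin))) + dmin
    digital[[s]] <- matrix(pmin(pmax(d, dmin), dmax), nrow = spr[s])
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(rec@subject@subject_id, 80),
    .edf_pad("vo2wear recording", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (ns + 1), 8),
    .edf_pad("", 44),
    .edf_pad(nrec, 8),
    .edf_pad("1", 8),
    .edf_pad(ns, 4),
    paste(vapply(names(chans), .edf_pad, character(1), width = 16), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad("", 8), ns), collapse = ""),
    paste(vapply(pmin, .edf_num, character(1)), collapse = ""),
    paste(vapply(pmax, .edf_num, character(1)), collapse = ""),
    paste(rep(.edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(.edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(vapply(spr, .edf_pad, character(1), width = 8), collapse = ""),
    paste(rep(.edf_pad("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  ## record-major interleave: record r = signal 1 block, signal 2 block, ...
  stacked <- do.call(rbind, digital)
  writeBin(as.integer(as.vector(stacked)), con, size = 2, endian = "little")
  .write_subject_csv(rec@subject, .sidecar(path, "subject"))
  if (nrow(rec@activities))
    .write_activities_csv(rec@activities, .sidecar(path, "activities"))
  invisible(path)
}

.read_recording_edf <- function(path, label_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  rd(8)
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  raw <- readBin(con, integer(), n = sum(spr) * nrec, size = 2,
                 signed = TRUE, endian = "little")
  stacked <- matrix(raw, nrow = sum(spr), ncol = nrec)
  offsets <- c(0L, cumsum(spr))
  if (!is.null(label_map)) {
    hit <- labels %in% names(label_map)
    labels[hit] <- label_map[labels[hit]]
  }
  rates <- channelRates()
  keep <- labels %in% names(rates)
  channels <- lapply(which(keep), function(s) {
    d <- as.vector(stacked[(offsets[s] + 1L):offsets[s + 1L], , drop = FALSE])
    x <- pmin[s] + (d - dmin[s]) / (dmax[s] - dmin[s]) * (pmax[s] - pmin[s])
    Channel(labels[s], x, fs = spr[s])
  })
  names(channels) <- labels[keep]
  mandatory <- c("ecg", "acc_x", "acc_y", "acc_z")
  if (!all(mandatory %in% labels[keep]) ||
      !any(c("resp_thoracic", "resp_abdominal") %in% labels[keep]))
    stop("incomplete recording: mandatory channel missing")
  subj_file <- .sidecar(path, "subject")
  if (!file.exists(subj_file))
    stop("incomplete recording: subject sidecar missing")
  subject <- .read_subject_csv(subj_file)
  act_file <- .sidecar(path, "activities")
  act <- if (file.exists(act_file)) .read_activities_csv(act_file)
         else .empty_activities()
  Recording(subject, channels, act)
}
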