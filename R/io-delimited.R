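## On-disk recording layout (delimited dialect): a directory with
##   manifest.txt          key = value lines mapping channel -> file
##   <channel>.csv         header "channel,fs", then one sample per line
##   subject.csv           demographics table (one row)
##   activities.csv        label,t_start,t_end
## Trivially diffable, lossless for doubles (17 significant digits).

.write_subject_csv <- function(subject, file) {
  df <- data.frame(subject_id = subject@subject_id, age = subject@age,
                   sex = subject@sex, height = subject@height,
                   weight = subject@weight, bmi = subject@bmi)
  utils::write.csv(df, file, row.names = FALSE)
}

.read_subject_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  SubjectInfo(df$subject_id[1], age = df$age[1], sex = df$sex[1],
              height = df$height[1], weight = df$weight[1], bmi = df$bmi[1])
}

.write_activities_csv <- function(act, file) {
  utils::write.csv(act[, c("label", "t_start", "t_end")], file,
                   row.names = FALSE)
}

.read_activities_csv <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

.empty_activities <- function() {
  data.frame(label = character(), t_start = numeric(), t_end = numeric())
}

#' Read a multichannel recording from disk
#'
#' The delimited dialect reads a directory written by [writeRecording()]
#' (one text file per channel plus `manifest.txt`, `subject.csv` and
#' `activities.csv`). The EDF dialect reads a single `.edf` file (with
#' optional `*_subject.csv` / `*_activities.csv` sidecars); `label_map`
#' translates EDF signal labels to channel roles, e.g.
#' `c("ECG I" = "ecg")`.
#'
#' @param path directory (delimited) or `.edf` file (edf)
#' @param dialect `"delimited"` or `"edf"`
#' @param label_map named character vector mapping EDF labels to channel
#'   names; unmapped labels must already be valid channel names
#' @return a [Recording-class]
#' @export
readRecording <- function(path, dialect = c("delimited", "edf"),
                          label_map = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "edf")
    return(.read_recording_edf(path, label_map = label_map))
  manifest_file <- file.path(path, "manifest.txt")
  if (!file.exists(manifest_file)) stop("no manifest.txt under ", path)
  kv <- .read_keyvalue(manifest_file)
  rates <- channelRates()
  chan_keys <- intersect(names(kv), names(rates))
  channels <- lapply(chan_keys, function(nm) {
    f <- file.path(path, kv[[nm]])
    if (!file.exists(f)) stop("incomplete recording: missing file for ", nm)
    hdr <- strsplit(readLines(f, n = 1L), ",")[[1]]
    fs <- as.numeric(hdr[2])
    if (!isTRUE(all.equal(fs, rates[[nm]])))
      stop("sampling-rate violation: ", nm, " declared at ", fs, " Hz")
    samples <- utils::read.csv(f, skip = 1L, header = FALSE)[[1]]
    Channel(nm, samples, fs = fs)
  })
  names(channels) <- chan_keys
  mandatory <- c("ecg", "acc_x", "acc_y", "acc_z")
  if (!all(mandatory %in% chan_keys) ||
      !any(c("resp_thoracic", "resp_abdominal") %in% chan_keys))
    stop("incomplete recording: mandatory channel missing")
  subject <- .read_subject_csv(file.path(path, kv[["subject"]]))
  act <- if ("activities" %in% names(kv))
    .read_activities_csv(file.path(path, kv[["activities"]]))
  else .empty_activities()
  Recording(subject, channels, act)
}

#' Write a multichannel recording to disk
#'
#' Inverse of [readRecording()]. The delimited dialect is lossless
#' (`read(write(rec))` reproduces every sample exactly); the EDF dialect
#' quantizes each signal to 16 bits over its physical range.
#'
#' @param rec a [Recording-class]
#' @param path target directory (delimited) or `.edf` file path (edf)
#' @param dialect `"delimited"` or `"edf"`
#' @return `path`, invisibly
#' @export
writeRecording <- function(rec, path, dialect = c("delimited", "edf")) {
  dialect <- match.arg(dialect)
  if (length(rec@channels) == 0L) stop("empty channel list")
  if (dialect == "edf")
    return(.write_recording_edf(rec, path))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  lines <- character()
  for (nm in names(rec@channels)) {
    ch <- rec@channels[[nm]]
    f <- paste0(nm, ".csv")
    con <- file(file.path(path, f), "w")
    writeLines(sprintf("%s,%g", nm, ch@fs), con)
    writeLines(formatC(ch@samples, digits = 17, format = "g"), con)
    close(con)
    lines <- c(lines, paste(nm, "=", f))
  }
  .write_subject_csv(rec@subject, file.path(path, "subject.csv"))
  lines <- c(lines, "subject = subject.csv")
  if (nrow(rec@activities)) {
    .write_activities_csv(rec@activities, file.path(path, "activities.csv"))
    lines <- c(lines, "activities = activities.csv")
  }
  writeLines(lines, file.path(path, "manifest.txt"))
  invisible(path)
}

## "key = value" reader shared by manifests and pipeline configs
.read_keyvalue <- function(file) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "[")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed key-value line: ", lines[bad][1])
  stats::setNames(vapply(kv, `[`, character(1), 2L),
                  vapply(kv, `[`, character(1), 1L))
}
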