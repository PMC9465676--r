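## Shared fixtures. Cohort simulations are memoized so several test files
## can reuse them without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

## protocol-faithful schedule with shortened blocks: same structure
## (5 postures x 4 breathing tasks + gaps, walk, Bruce stages, recovery),
## compressed durations to keep experiments fast
shortParams <- function(...) {
  simParams(rest_normal = 20, rest_deep = 20, rest_talk = 10,
            rest_fast = 10, rest_gap = 10, walk_s = 60, level_s = 60,
            recovery_s = 60, ...)
}

## even shorter, for wiring/smoke tests
tinyParams <- function(...) {
  simParams(rest_normal = 10, rest_deep = 10, rest_talk = 5, rest_fast = 5,
            rest_gap = 5, walk_s = 30, level_s = 30, recovery_s = 30, ...)
}

testSubject <- function(id = "S01", age = 25, sex = "male") {
  SubjectInfo(id, age = age, sex = sex, height = 178, weight = 72)
}

## memoized 12-subject cohort (6 male / 6 female) + stacked feature frames
cohortFrames <- function() {
  if (is.null(.fixture_env$frames12)) {
    co <- simulateCohort(12, shortParams(), seed = 7, n_male = 6)
    frames <- do.call(rbind, lapply(co, function(s)
      buildFeatureFrame(s$recording)))
    .fixture_env$cohort12 <- co
    .fixture_env$frames12 <- frames
  }
  .fixture_env$frames12
}

cohortTruths <- function() {
  cohortFrames()
  .fixture_env$cohort12
}

singleCell <- function() {
  data.frame(n_trees = 50L, max_depth = 5L, learning_rate = 0.1)
}

## small complete recording for I/O tests
tinyRecording <- function(dur = 10, seed = 99) {
  set.seed(seed)
  chans <- lapply(names(channelRates()), function(nm) {
    fs <- channelRates()[[nm]]
    Channel(nm, rnorm(dur * fs))
  })
  act <- data.frame(label = c("stand", "sit"),
                    t_start = c(0, dur / 2), t_end = c(dur / 2, dur))
  Recording(testSubject(), chans, act)
}

## frequency-response oracles, independent of the signal package's filters:
## direct evaluation of the transfer polynomial on the unit circle
firGainOracle <- function(b, f, fs) {
  w <- 2 * pi * f / fs
  abs(sum(b * exp(-1i * w * (seq_along(b) - 1))))
}

iirGainOracle <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(-1i * w * (seq_along(b) - 1))
  num <- sum(b * z)
  den <- sum(a * exp(-1i * w * (seq_along(a) - 1)))
  abs(num / den)
}

## steady-state amplitude of a (near-)sinusoidal response, middle section;
## when the probe frequency is known, project onto the complex exponential
## over an integer number of cycles (leakage-free estimate)
measuredAmplitude <- function(y, fs, discard_s = 20, f = NULL) {
  d <- round(discard_s * fs)
  mid <- y[(d + 1):(length(y) - d)]
  if (is.null(f)) return(sqrt(2 * mean(mid^2)))
  tt <- (seq_along(mid) - 1) / fs
  ncyc <- floor(length(mid) / fs * f)
  stopifnot(ncyc >= 1)
  keep <- tt < ncyc / f
  2 * Mod(mean(mid[keep] * exp(-2i * pi * f * tt[keep])))
}

## detection scoring against truth event times
detectionF1 <- function(detected, truth, tol = 0.05) {
  if (length(detected) == 0) return(0)
  used <- logical(length(truth))
  tp <- 0
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol)
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1 }
  }
  prec <- tp / length(detected)
  rec <- tp / length(truth)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
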