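## Flat key-value pipeline configuration. Every protocol constant the
## pipeline relies on (filter bands, window lengths, smoothing width, the
## hyperparameter grid, simulation parameters) is surfaced as a named key
## with its default, so a run is auditable and overridable from one file.

.config_defaults <- function() {
  sim <- simParams()
  names(sim) <- paste0("sim_", names(sim))
  sim$sim_hr_slope <- NULL          # computed per subject unless overridden
  c(list(
    resp_source = "thoracic",       # thoracic | abdominal | sum
    hr_source = "ecg",              # ecg | hr_ref
    feature_set = "HR%+RD+MADs+SDI",
    seed = 1L,
    n = 12L,
    n_male = NA,
    smooth_width = 31L,
    hr_window = 4, hr_step = 1,
    mads_block = 1,
    grid_full = TRUE), sim)
}

#' Read a pipeline configuration file
#'
#' Flat `key = value` lines (`#` comments and `[section]` headers are
#' ignored); unknown keys are rejected. Values override the package
#' defaults; the fully resolved configuration is returned (and logged via
#' `message()` when `verbose`).
#'
#' @param path config file path, or `NULL` for pure defaults
#' @param verbose log the resolved configuration
#' @return named list of configuration values
#' @export
readPipelineConfig <- function(path = NULL, verbose = FALSE) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    kv <- .read_keyvalue(path)
    unknown <- setdiff(names(kv), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    for (k in names(kv)) {
      v <- kv[[k]]
      old <- cfg[[k]]
      cfg[[k]] <- if (is.numeric(old) || is.null(old)) {
        num <- suppressWarnings(as.numeric(v))
        if (is.na(num) && !identical(v, "NA")) v else num
      } else if (is.logical(old)) as.logical(v) else v
    }
  }
  if (verbose)
    for (k in names(cfg))
      message("config: ", k, " = ",
              paste(format(cfg[[k]]), collapse = " "))
  cfg
}

.sim_params_from_config <- function(cfg) {
  keys <- names(cfg)[startsWith(names(cfg), "sim_")]
  p <- cfg[keys]
  names(p) <- sub("^sim_", "", names(p))
  p$vo2_levels <- if (is.character(p$vo2_levels))
    as.numeric(strsplit(p$vo2_levels, ",")[[1]])
  else as.numeric(p$vo2_levels)
  do.call(simParams, p)
}
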