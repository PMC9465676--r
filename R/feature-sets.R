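## The seven model input combinations. RD denotes the paired respiratory
## features {RR, DApt}; SDI the subject demographics {age, sex, BMI} and is
## always included.

.feature_sets <- list(
  "HR%+SDI"          = c("hr_pct"),
  "RD+SDI"           = c("rr", "dapt"),
  "MADs+SDI"         = c("mads"),
  "HR%+RD+SDI"       = c("hr_pct", "rr", "dapt"),
  "HR%+MADs+SDI"     = c("hr_pct", "mads"),
  "RD+MADs+SDI"      = c("rr", "dapt", "mads"),
  "HR%+RD+MADs+SDI"  = c("hr_pct", "rr", "dapt", "mads")
)

.sdi_cols <- c("age", "sex", "bmi")

#' Model input combinations
#'
#' `featureSetNames()` lists the seven recognised input combinations;
#' `featureSetColumns()` resolves one to the feature-frame columns it uses
#' (the SDI block is always appended).
#'
#' @param name a feature-set name, e.g. `"HR%+RD+MADs+SDI"`
#' @return `featureSetNames`: character vector of the seven names;
#'   `featureSetColumns`: character vector of resolved column names
#' @export
featureSetNames <- function() names(.feature_sets)

#' @rdname featureSetNames
#' @export
featureSetColumns <- function(name) {
  if (!name %in% names(.feature_sets))
    stop("unknown feature set '", name, "'; valid names: ",
         paste(names(.feature_sets), collapse = ", "))
  c(.feature_sets[[name]], .sdi_cols)
}

## numeric design matrix for the boosted-tree model (sex: male=1, female=0)
.design_matrix <- function(frames, feature_set) {
  cols <- featureSetColumns(feature_set)
  df <- frames[, cols, drop = FALSE]
  if ("sex" %in% cols) df$sex <- as.numeric(df$sex == "male")
  as.matrix(df)
}
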