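#' Error and agreement metrics
#'
#' `meanAbsError()` is the mean absolute error `1/N * sum(|true - pred|)`
#' (ml/kg/min for VO2). `rSquared()` is the coefficient of determination
#' `1 - SS_res / SS_tot`; it is undefined (error) for zero-variance truth.
#'
#' @param true,pred equal-length numeric vectors
#' @return a scalar
#' @export
#' @examples
#' meanAbsError(c(1, 2, 3), c(2, 3, 4))   # 1
meanAbsError <- function(true, pred) {
  if (length(true) != length(pred)) stop("length mismatch")
  mean(abs(true - pred))
}

#' @rdname meanAbsError
#' @export
rSquared <- function(true, pred) {
  if (length(true) != length(pred)) stop("length mismatch")
  if (length(true) < 2L) stop("need at least 2 observations")
  ss_tot <- sum((true - mean(true))^2)
  if (ss_tot == 0) stop("R^2 undefined for zero-variance truth")
  1 - sum((true - pred)^2) / ss_tot
}

#' Bland-Altman agreement statistics
#'
#' For differences `d = pred - true`: bias `mean(d)`, limits of agreement
#' `bias +- 1.96 * sd(d)` and the width between the limits.
#'
#' @param true,pred equal-length numeric vectors, length >= 3
#' @return list with `bias`, `loa_low`, `loa_high`, `ci95_width`, `sd_diff`
#' @export
blandAltman <- function(true, pred) {
  if (length(true) != length(pred)) stop("length mismatch")
  if (length(true) < 3L) stop("need at least 3 observations")
  d <- pred - true
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       ci95_width = 2 * 1.96 * s, sd_diff = s)
}

#' Group comparison tests
#'
#' Two groups: two-sided independent-sample t test. More than two groups:
#' one-way ANOVA followed by Tukey HSD pairwise comparisons. Significance
#' is reported against the 0.05 threshold.
#'
#' @param groups named list of numeric vectors (each n >= 2)
#' @return list with `method`, `p_value` (t test / ANOVA omnibus),
#'   `pairwise` (named vector of Tukey adjusted p values; `NULL` for two
#'   groups), `significant` (omnibus p < 0.05), `alpha`
#' @export
compareGroups <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 observations")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  if (length(groups) == 2L) {
    tt <- stats::t.test(groups[[1]], groups[[2]])
    return(list(method = "t-test", p_value = tt$p.value, pairwise = NULL,
                significant = tt$p.value < 0.05, alpha = 0.05))
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  fit <- stats::aov(value ~ group, data = df)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  list(method = "anova+tukey", p_value = p,
       pairwise = stats::setNames(tk[, "p adj"], rownames(tk)),
       significant = p < 0.05, alpha = 0.05)
}
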