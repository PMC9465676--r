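## Evaluation designs: leave-one-subject-out cross-validation and the
## gender-crossover experiment, with per-subject, pooled, per-activity and
## Bland-Altman summaries.

.stack_frames <- function(frames) {
  if (is.data.frame(frames)) return(frames)
  do.call(rbind, frames)
}

.report_from_predictions <- function(pred, feature_set) {
  per_subject <- do.call(rbind, lapply(split(pred, pred$subject_id),
    function(d) data.frame(subject_id = d$subject_id[1],
                           n = nrow(d),
                           mae = meanAbsError(d$true, d$pred),
                           r2 = rSquared(d$true, d$pred))))
  rownames(per_subject) <- NULL
  acts <- setdiff(unique(pred$activity), "unlabeled")
  per_activity <- do.call(rbind, lapply(acts, function(a) {
    d <- pred[pred$activity == a, , drop = FALSE]
    data.frame(activity = a, n = nrow(d),
               mae = meanAbsError(d$true, d$pred))
  }))
  structure(list(
    feature_set = feature_set,
    per_subject = per_subject,
    pooled = list(mae_mean = mean(per_subject$mae),
                  mae_sd = stats::sd(per_subject$mae),
                  r2_mean = mean(per_subject$r2),
                  r2_sd = stats::sd(per_subject$r2),
                  mae_pooled = meanAbsError(pred$true, pred$pred),
                  r2_pooled = rSquared(pred$true, pred$pred),
                  n = nrow(pred)),
    bland_altman = blandAltman(pred$true, pred$pred),
    per_activity = per_activity,
    predictions = pred), class = "Vo2EvalReport")
}

#' @export
print.Vo2EvalReport <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("VO2 evaluation [%s], %d subjects, n = %d\n", x$feature_set,
              nrow(x$per_subject), p$n))
  cat(sprintf("  MAE  %.2f +- %.2f ml/kg/min (pooled %.2f)\n",
              p$mae_mean, p$mae_sd, p$mae_pooled))
  cat(sprintf("  R^2  %.3f +- %.3f (pooled %.3f)\n",
              p$r2_mean, p$r2_sd, p$r2_pooled))
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman bias %.3f, LoA [%.2f, %.2f]\n",
              ba$bias, ba$loa_low, ba$loa_high))
  invisible(x)
}

#' Leave-one-subject-out evaluation
#'
#' For each subject, hyperparameters are grid-searched (subject-grouped
#' five-fold CV) on the remaining subjects, a model is fitted on them and
#' the held-out subject is predicted; the held-out subject's rows never
#' enter training (asserted). Subjects contributing fewer than `min_rows`
#' seconds are excluded with a warning. A single-cell `grid` skips the
#' search.
#'
#' @param frames list of per-subject feature frames or one stacked frame
#' @param feature_set feature-set name (see [featureSetNames()])
#' @param grid hyperparameter grid (see [defaultGrid()])
#' @param seed integer seed
#' @param k folds of the inner grid-search CV
#' @param min_rows minimum seconds per subject
#' @return a `"Vo2EvalReport"`: per-subject and pooled MAE/R^2,
#'   Bland-Altman statistics, per-activity MAE and the held-out
#'   predictions
#' @export
losoEvaluate <- function(frames, feature_set = "HR%+RD+MADs+SDI",
                         grid = defaultGrid(), seed = 1L, k = 5,
                         min_rows = 60L) {
  frames <- .stack_frames(frames)
  counts <- table(frames$subject_id)
  drop <- names(counts)[counts < min_rows]
  if (length(drop)) {
    warning("excluding subjects with < ", min_rows, " rows: ",
            paste(drop, collapse = ", "))
    frames <- frames[!frames$subject_id %in% drop, , drop = FALSE]
  }
  subjects <- unique(as.character(frames$subject_id))
  if (length(subjects) < 3L) stop("LOSO needs at least 3 subjects")
  preds <- vector("list", length(subjects))
  folds <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    tr <- frames[frames$subject_id != s, , drop = FALSE]
    te <- frames[frames$subject_id == s, , drop = FALSE]
    stopifnot(length(intersect(unique(tr$subject_id),
                               unique(te$subject_id))) == 0L)
    hp <- if (nrow(grid) > 1L)
      gridSearchCV(tr, feature_set, grid, k = k, seed = seed)$best
    else list(n_trees = grid$n_trees[1], max_depth = grid$max_depth[1],
              learning_rate = grid$learning_rate[1])
    m <- fitVo2Model(tr, feature_set, hp, seed = seed)
    stopifnot(!s %in% m@training_subjects)
    preds[[i]] <- data.frame(subject_id = s, t = te$t,
                             activity = te$activity, true = te$vo2,
                             pred = predictVo2(m, te))
    folds[[i]] <- list(test_subject = s,
                       training_subjects = m@training_subjects,
                       hyperparams = hp)
  }
  rep <- .report_from_predictions(do.call(rbind, preds), feature_set)
  rep$folds <- folds
  rep
}

#' Gender-crossover evaluation
#'
#' Four designs: LOSO within males (`male_male`), LOSO within females
#' (`female_female`), train on all males / test all females
#' (`male_female`) and the reverse (`female_male`). The cross-sex designs
#' grid-search hyperparameters within the training sex. A per-activity
#' MAE table across the four designs is attached.
#'
#' @inheritParams losoEvaluate
#' @return list with the four `"Vo2EvalReport"`s and `per_activity_table`
#'   (activity x design MAE data.frame)
#' @export
genderCrossover <- function(frames, feature_set = "HR%+RD+MADs+SDI",
                            grid = defaultGrid(), seed = 1L, k = 5) {
  frames <- .stack_frames(frames)
  sexes <- unique(frames$sex)
  if (!all(c("male", "female") %in% sexes))
    stop("both sexes must be present")
  male <- frames[frames$sex == "male", , drop = FALSE]
  female <- frames[frames$sex == "female", , drop = FALSE]
  cross <- function(tr, te, label) {
    hp <- if (nrow(grid) > 1L)
      gridSearchCV(tr, feature_set, grid, k = k, seed = seed)$best
    else list(n_trees = grid$n_trees[1], max_depth = grid$max_depth[1],
              learning_rate = grid$learning_rate[1])
    m <- fitVo2Model(tr, feature_set, hp, seed = seed)
    stopifnot(length(intersect(m@training_subjects,
                               unique(te$subject_id))) == 0L)
    pred <- data.frame(subject_id = te$subject_id, t = te$t,
                       activity = te$activity, true = te$vo2,
                       pred = predictVo2(m, te))
    .report_from_predictions(pred, feature_set)
  }
  reports <- list(
    male_male = losoEvaluate(male, feature_set, grid, seed = seed, k = k),
    female_female = losoEvaluate(female, feature_set, grid, seed = seed,
                                 k = k),
    male_female = cross(male, female, "male_female"),
    female_male = cross(female, male, "female_male"))
  acts <- Reduce(union, lapply(reports,
                               function(r) r$per_activity$activity))
  tab <- data.frame(activity = acts)
  for (nm in names(reports)) {
    pa <- reports[[nm]]$per_activity
    tab[[nm]] <- pa$mae[match(acts, pa$activity)]
  }
  c(reports, list(per_activity_table = tab))
}
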