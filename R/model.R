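## Gradient-boosted VO2 regression. The boosted-tree ensemble (sum of K
## regression-tree scores minimizing a regularized squared-error objective)
## is provided by xgboost; this package owns the feature contract,
## subject-grouped cross-validation and evaluation design around it.

#' Fitted VO2 estimator
#'
#' A trained boosted-tree regressor together with the feature-set choice,
#' hyperparameters and the training-subject ids. When the training target
#' is constant the model degenerates to a mean predictor (`constant`
#' slot).
#'
#' @slot feature_set feature-set name (see [featureSetNames()])
#' @slot hyperparams list with `n_trees`, `max_depth`, `learning_rate`
#' @slot booster the trained xgboost handle (or `NULL` for a mean
#'   predictor)
#' @slot constant mean-predictor value (`NA` when a booster is present)
#' @slot training_subjects character vector of subject ids seen in
#'   training
#' @export
setClass("Vo2Model",
  representation(feature_set = "character", hyperparams = "list",
                 booster = "ANY", constant = "numeric",
                 training_subjects = "character"))

setValidity("Vo2Model", function(object) {
  hp <- object@hyperparams
  msg <- character()
  if (!all(c("n_trees", "max_depth", "learning_rate") %in% names(hp)))
    msg <- c(msg, "hyperparams must name n_trees, max_depth, learning_rate")
  else if (hp$n_trees <= 0 || hp$max_depth <= 0 ||
           hp$learning_rate <= 0 || hp$learning_rate > 1)
    msg <- c(msg, "hyperparams out of range")
  if (!object@feature_set %in% featureSetNames())
    msg <- c(msg, "unknown feature set")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Vo2Model", function(object) {
  hp <- object@hyperparams
  cat(sprintf(
    "Vo2Model [%s] trees=%d depth=%d lr=%g, trained on %d subjects%s\n",
    object@feature_set, hp$n_trees, hp$max_depth, hp$learning_rate,
    length(object@training_subjects),
    if (is.null(object@booster)) " (mean predictor)" else ""))
})

#' Hyperparameter grid of the boosted-tree model
#'
#' The default 8-cell grid crosses number of trees {10, 50}, maximum tree
#' depth {1, 5} and learning rate {1, 0.1}.
#'
#' @return data.frame with columns `n_trees`, `max_depth`, `learning_rate`
#' @export
defaultGrid <- function() {
  expand.grid(n_trees = c(10L, 50L), max_depth = c(1L, 5L),
              learning_rate = c(1, 0.1), KEEP.OUT.ATTRS = FALSE)
}

#' Fit the boosted-tree VO2 model
#'
#' Trains a squared-error boosted-tree ensemble on the stacked feature
#' frames (rows with missing VO2 are rejected). Training is deterministic
#' given `seed` (single-threaded). A constant target degenerates to a mean
#' predictor with a warning.
#'
#' @param frames stacked feature frame(s): a data.frame with the resolved
#'   feature columns, `vo2` and `subject_id`
#' @param feature_set feature-set name (see [featureSetNames()])
#' @param hyperparams list with `n_trees`, `max_depth`, `learning_rate`
#' @param seed integer training seed
#' @return a [Vo2Model-class]
#' @export
fitVo2Model <- function(frames, feature_set = "HR%+RD+MADs+SDI",
                        hyperparams = list(n_trees = 50L, max_depth = 5L,
                                           learning_rate = 0.1),
                        seed = 1L) {
  if (is.null(frames$vo2) || anyNA(frames$vo2))
    stop("training frames must carry a complete vo2 target")
  if (nrow(frames) < 100L) stop("too few training rows (need >= 100)")
  subjects <- unique(as.character(frames$subject_id))
  y <- frames$vo2
  if (stats::var(y) == 0) {
    warning("constant training target; returning mean predictor")
    return(new("Vo2Model", feature_set = feature_set,
               hyperparams = hyperparams, booster = NULL,
               constant = y[1], training_subjects = subjects))
  }
  X <- .design_matrix(frames, feature_set)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  max_depth = as.integer(hyperparams$max_depth),
                  eta = hyperparams$learning_rate,
                  nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = as.integer(hyperparams$n_trees), verbose = 0)
  new("Vo2Model", feature_set = feature_set, hyperparams = hyperparams,
      booster = booster, constant = NA_real_, training_subjects = subjects)
}

#' Predict VO2 for new feature-frame rows
#'
#' @param model a [Vo2Model-class]
#' @param frames feature frame rows to predict
#' @return numeric vector of VO2 estimates (ml/kg/min)
#' @export
predictVo2 <- function(model, frames) {
  if (is.null(model@booster)) return(rep(model@constant, nrow(frames)))
  X <- .design_matrix(frames, model@feature_set)
  predict(model@booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' Subject-grouped grid search with k-fold cross-validation
#'
#' Evaluates every grid cell by k-fold cross-validation whose folds split
#' whole subjects (never rows), returning the cell with minimum mean CV
#' MAE. Ties break deterministically toward fewer trees, then shallower
#' trees, then larger learning rate. When fewer subjects than folds are
#' available, k is reduced to the subject count with a warning.
#'
#' @param frames stacked feature frames with `vo2` and `subject_id`
#' @param feature_set feature-set name
#' @param grid data.frame of candidate cells (see [defaultGrid()])
#' @param k number of folds
#' @param seed integer seed (fold assignment and training)
#' @return list with `best` (hyperparameter list), `cv_table` (grid with a
#'   `cv_mae` column)
#' @export
gridSearchCV <- function(frames, feature_set = "HR%+RD+MADs+SDI",
                         grid = defaultGrid(), k = 5, seed = 1L) {
  if (nrow(grid) == 0L) stop("empty grid")
  subjects <- unique(as.character(frames$subject_id))
  if (length(subjects) < k) {
    warning("fewer subjects than folds; reducing k to ", length(subjects))
    k <- length(subjects)
  }
  set.seed(seed)
  fold_of <- stats::setNames(rep_len(seq_len(k), length(subjects)),
                             sample(subjects))
  cv_mae <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- list(n_trees = grid$n_trees[g], max_depth = grid$max_depth[g],
               learning_rate = grid$learning_rate[g])
    fold_err <- numeric(k)
    for (f in seq_len(k)) {
      test_sub <- names(fold_of)[fold_of == f]
      tr <- frames[!frames$subject_id %in% test_sub, , drop = FALSE]
      te <- frames[frames$subject_id %in% test_sub, , drop = FALSE]
      m <- fitVo2Model(tr, feature_set, hp, seed = seed)
      fold_err[f] <- meanAbsError(te$vo2, predictVo2(m, te))
    }
    cv_mae[g] <- mean(fold_err)
  }
  ord <- order(cv_mae, grid$n_trees, grid$max_depth, -grid$learning_rate)
  best <- grid[ord[1], , drop = FALSE]
  list(best = list(n_trees = best$n_trees, max_depth = best$max_depth,
                   learning_rate = best$learning_rate),
       cv_table = cbind(grid, cv_mae = cv_mae))
}
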