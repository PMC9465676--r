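test_that("MAE and R^2 follow their definitions", {
  expect_equal(meanAbsError(c(1, 2, 3), c(2, 3, 4)), 1)
  expect_equal(meanAbsError(1:5, 1:5), 0)
  expect_equal(rSquared(1:5, 1:5), 1)
  expect_error(rSquared(rep(2, 5), 1:5), "zero-variance")
  expect_error(meanAbsError(1:3, 1:2), "length mismatch")
  ## brute-force agreement on random inputs
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(50); b <- rnorm(50)
    expect_equal(meanAbsError(a, b), sum(abs(a - b)) / 50,
                 tolerance = 1e-12)
    expect_equal(rSquared(a, b),
                 1 - sum((a - b)^2) / sum((a - mean(a))^2),
                 tolerance = 1e-12)
  }
})

test_that("Bland-Altman limits recover a known difference distribution", {
  expect_equal(blandAltman(1:10, 1:10)$bias, 0)
  expect_equal(blandAltman(1:10, 1:10 + 1),
               list(bias = 1, loa_low = 1, loa_high = 1, ci95_width = 0,
                    sd_diff = 0))
  set.seed(42)
  true <- rnorm(1e5, 10, 2)
  ba <- blandAltman(true, true + rnorm(1e5))
  expect_lt(abs(ba$loa_low - (-1.96)), 0.05)
  expect_lt(abs(ba$loa_high - 1.96), 0.05)
  expect_lt(abs(ba$bias), 0.05)
})

test_that("group comparisons detect planted shifts and not null data", {
  g <- rnorm(30)
  expect_gt(compareGroups(list(a = g, b = g))$p_value, 0.9)
  set.seed(43)
  res <- compareGroups(list(a = rnorm(30), b = rnorm(30, 5)))
  expect_lt(res$p_value, 0.001)
  expect_identical(res$method, "t-test")
  ## three groups, one shifted: omnibus + Tukey localization
  set.seed(44)
  res3 <- compareGroups(list(a = rnorm(20), b = rnorm(20),
                             c = rnorm(20, 3)))
  expect_lt(res3$p_value, 0.05)
  pw <- res3$pairwise
  expect_true(all(pw[grepl("c", names(pw))] < 0.05))
  expect_gt(pw[["b-a"]], 0.05)
  expect_error(compareGroups(list(rnorm(3))), "at least 2 groups")
})

test_that("the booster fits a deterministic monotone signal", {
  set.seed(45)
  n <- 600
  fr <- data.frame(hr_pct = runif(n, 40, 90), rr = runif(n, 10, 30),
                   dapt = runif(n, 1, 3), mads = runif(n, 0, 0.01),
                   age = 25, sex = "male", bmi = 22,
                   subject_id = rep(c("a", "b", "c"), each = n / 3))
  fr$vo2 <- 3 + 400 * fr$mads + fr$mads^2
  m <- fitVo2Model(fr, "MADs+SDI",
                   list(n_trees = 50, max_depth = 5, learning_rate = 0.1))
  expect_gte(rSquared(fr$vo2, predictVo2(m, fr)), 0.99)
  ## constant target degenerates to a warned mean predictor
  fr$vo2 <- 7
  expect_warning(m0 <- fitVo2Model(fr, "MADs+SDI"), "constant")
  expect_true(all(predictVo2(m0, fr) == 7))
  expect_error(fitVo2Model(fr[1:50, ], "MADs+SDI"), "too few")
})

test_that("a pure-noise target yields no held-out skill", {
  set.seed(46)
  n <- 1200
  fr <- data.frame(hr_pct = runif(n, 40, 90), rr = runif(n, 10, 30),
                   dapt = runif(n, 1, 3), mads = runif(n, 0, 0.01),
                   age = rep(21:26, each = n / 6), sex = "male", bmi = 22,
                   subject_id = rep(paste0("s", 1:6), each = n / 6),
                   t = 1, activity = "sit")
  fr$vo2 <- rnorm(n)
  rep <- losoEvaluate(fr, "HR%+RD+MADs+SDI", grid = singleCell(),
                      seed = 2)
  expect_lte(rep$pooled$r2_pooled, 0.1)
})

test_that("grid search equals exhaustive CV enumeration with stable ties", {
  frames <- cohortFrames()
  sub5 <- unique(frames$subject_id)[1:5]
  fr <- frames[frames$subject_id %in% sub5, ]
  grid <- expand.grid(n_trees = c(10L, 50L), max_depth = c(1L, 5L),
                      learning_rate = 0.1, KEEP.OUT.ATTRS = FALSE)
  gs <- gridSearchCV(fr, "HR%+RD+MADs+SDI", grid, k = 5, seed = 11)
  ## independent enumeration: same fold rule, own loops
  set.seed(11)
  subjects <- unique(as.character(fr$subject_id))
  fold_of <- stats::setNames(rep_len(1:5, length(subjects)),
                             sample(subjects))
  oracle <- apply(grid, 1, function(row) {
    errs <- vapply(1:5, function(f) {
      te_sub <- names(fold_of)[fold_of == f]
      tr <- fr[!fr$subject_id %in% te_sub, ]
      te <- fr[fr$subject_id %in% te_sub, ]
      m <- fitVo2Model(tr, "HR%+RD+MADs+SDI",
                       list(n_trees = row[["n_trees"]],
                            max_depth = row[["max_depth"]],
                            learning_rate = row[["learning_rate"]]),
                       seed = 11)
      meanAbsError(te$vo2, predictVo2(m, te))
    }, numeric(1))
    mean(errs)
  })
  expect_equal(gs$cv_table$cv_mae, unname(oracle), tolerance = 1e-9)
  best_idx <- which.min(oracle)
  expect_equal(gs$best$n_trees, grid$n_trees[best_idx])
  expect_equal(gs$best$max_depth, grid$max_depth[best_idx])
  ## all-tie grid (constant target -> every cell is the mean predictor):
  ## deterministic tie-break picks fewest/shallowest trees, largest rate
  fr0 <- fr; fr0$vo2 <- 5
  suppressWarnings(tie <- gridSearchCV(fr0, "HR%+RD+MADs+SDI",
                                       defaultGrid(), k = 5, seed = 11))
  expect_equal(tie$best, list(n_trees = 10L, max_depth = 1L,
                              learning_rate = 1))
  ## single-cell grid returns that cell
  one <- gridSearchCV(fr, "HR%+RD+MADs+SDI", singleCell(), k = 5,
                      seed = 11)
  expect_equal(one$best$n_trees, 50L)
})

test_that("LOSO keeps train and test subjects disjoint in every fold", {
  frames <- cohortFrames()
  rep <- losoEvaluate(frames, grid = singleCell(), seed = 1)
  expect_equal(length(rep$folds), 12)
  for (fd in rep$folds) {
    expect_false(fd$test_subject %in% fd$training_subjects)
    expect_equal(length(fd$training_subjects), 11)
  }
  expect_setequal(unique(rep$predictions$subject_id),
                  unique(frames$subject_id))
  ## pooled mean MAE equals the mean of per-subject MAEs
  expect_equal(rep$pooled$mae_mean, mean(rep$per_subject$mae))
})

test_that("LOSO excludes too-short subjects and needs three subjects", {
  frames <- cohortFrames()
  stub <- frames[frames$subject_id == "S01", ][1:10, ]
  stub$subject_id <- "SHORT"
  expect_warning(rep <- losoEvaluate(rbind(frames, stub),
                                     grid = singleCell(), seed = 1),
                 "excluding")
  expect_false("SHORT" %in% rep$per_subject$subject_id)
  two <- frames[frames$subject_id %in% c("S01", "S02"), ]
  expect_error(losoEvaluate(two, grid = singleCell()), "at least 3")
})

test_that("gender crossover rejects single-sex cohorts", {
  frames <- cohortFrames()
  male_only <- frames[frames$sex == "male", ]
  expect_error(genderCrossover(male_only, grid = singleCell()),
               "both sexes")
})

test_that("feature-set resolution covers the seven combinations", {
  expect_length(featureSetNames(), 7)
  expect_equal(featureSetColumns("HR%+SDI"),
               c("hr_pct", "age", "sex", "bmi"))
  expect_equal(featureSetColumns("RD+SDI"),
               c("rr", "dapt", "age", "sex", "bmi"))
  expect_true(all(vapply(featureSetNames(), function(nm)
    all(c("age", "sex", "bmi") %in% featureSetColumns(nm)), logical(1))))
  expect_error(featureSetColumns("HR"), "valid names")
})

test_that("model predictions are reproducible under a fixed seed", {
  frames <- cohortFrames()
  m1 <- fitVo2Model(frames, seed = 9)
  m2 <- fitVo2Model(frames, seed = 9)
  expect_identical(predictVo2(m1, frames), predictVo2(m2, frames))
})
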