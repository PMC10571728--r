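test_that("knn imputation restores structure and handles edge cases", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("S%02d", 1:40), sprintf("F%d", 1:6)))
  # no missing values: unchanged
  expect_identical(knn_impute(X, k = 2L), X)

  # two identical peptides, one value masked, k = 1: restored exactly
  X2 <- X
  X2[, 2] <- X2[, 1]
  X2[7, 2] <- NA
  out <- knn_impute(X2, k = 1L)
  expect_equal(out[7, 2], X2[7, 1])

  # k must be smaller than the peptide count; all-missing samples rejected
  expect_error(knn_impute(X, k = 6L), class = "config_error")
  X3 <- X
  X3[3, ] <- NA
  expect_error(knn_impute(X3, k = 2L), class = "validation_error")

  # heavily missing peptide falls back to its column mean
  X4 <- X
  X4[1:30, 4] <- NA
  out4 <- knn_impute(X4, k = 2L, max_missing = 0.5)
  expect_equal(unname(out4[1, 4]), mean(X4[, 4], na.rm = TRUE))
})

test_that("mask-and-recover imputation error stays within the noise scale", {
  set.seed(8)
  n <- 60L; p <- 30L
  base <- rnorm(p, sd = 2)
  X <- outer(rnorm(n, sd = 0.3), rep(1, p)) +
    matrix(base, n, p, byrow = TRUE) + matrix(rnorm(n * p, sd = 0.25), n, p)
  dimnames(X) <- list(sprintf("S%02d", 1:n), sprintf("F%02d", 1:p))
  mask <- matrix(runif(n * p) < 0.1, n, p)
  Xm <- X
  Xm[mask] <- NA
  out <- knn_impute(Xm, k = 10L)
  err <- abs(out[mask] - X[mask])
  # column sd is ~0.39; a sensible imputation beats it clearly
  expect_lt(median(err), 0.5)
})

test_that("stratified split preserves class proportions and is seeded", {
  labels <- stats::setNames(rep(c("MM", "rest"), c(55L, 1745L)),
                            sprintf("S%04d", 1:1800))
  sp <- split_cohort(labels, fraction = 0.7, seed = 1)
  n_mm_train <- sum(labels[sp$train] == "MM")
  expect_true(n_mm_train %in% c(38L, 39L))
  expect_identical(sort(c(sp$train, sp$test)), sort(names(labels)))
  expect_length(intersect(sp$train, sp$test), 0L)
  # stratification bound on the training class fraction
  expect_lte(abs(mean(labels[sp$train] == "MM") - 55 / 1800),
             1 / length(sp$train))
  expect_identical(split_cohort(labels, seed = 7), split_cohort(labels, seed = 7))
  expect_false(identical(split_cohort(labels, seed = 7)$train,
                         split_cohort(labels, seed = 8)$train))
  expect_error(split_cohort(labels, fraction = 1.0),
               class = "validation_error")
  expect_error(split_cohort(stats::setNames("MM", "S1")),
               class = "validation_error")
})

test_that("ROC curve is monotone and its AUC equals the Mann-Whitney oracle", {
  mw_auc <- function(scores, y) {
    r <- rank(scores)
    (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
  }
  set.seed(12)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y <- runif(n) < 0.3
    if (!any(y) || all(y)) next
    scores <- round(rnorm(n, mean = y), sample(c(1, 8), 1)) # force ties
    rc <- roc_curve(scores, y)
    expect_equal(rc$auc, mw_auc(scores, y), tolerance = 1e-12)
    expect_equal(rc$roc$fpr[1], 0)
    expect_equal(rc$roc$tpr[1], 0)
    expect_equal(rc$roc$fpr[nrow(rc$roc)], 1)
    expect_equal(rc$roc$tpr[nrow(rc$roc)], 1)
    expect_true(all(diff(rc$roc$tpr) >= 0) && all(diff(rc$roc$fpr) >= 0))
  }
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)),
               class = "validation_error")
})

test_that("random forest separates separable data and is reproducible", {
  set.seed(30)
  n <- 80L
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(sig = y + rnorm(n, sd = 0.05),
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("noise", 1:5))))
  rownames(X) <- sprintf("S%02d", 1:n)
  set.seed(1); fit1 <- rf_fit(X, y, num_trees = 100L)
  set.seed(1); fit2 <- rf_fit(X, y, num_trees = 100L)
  expect_identical(fit1$importance, fit2$importance)
  p <- rf_predict(fit1, X)
  expect_equal(roc_curve(p, y == 1L)$auc, 1)
  # the informative feature dominates and maxes the relevance scale
  rel <- relevance_scores(fit1)
  expect_identical(rel$feature[1L], "sig")
  expect_equal(rel$score[1L], 100)
  expect_error(rf_fit(X, rep(0L, n)), class = "validation_error")
})

test_that("train_and_evaluate gives perfect AUC on separable data without leakage", {
  set.seed(40)
  n <- 120L
  cls <- rep(c("MM", "rest"), c(30L, 90L))
  X <- cbind(sig = (cls == "MM") + rnorm(n, sd = 0.05),
             matrix(rnorm(n * 9), n, 9,
                    dimnames = list(NULL, paste0("noise", 1:9))))
  rownames(X) <- sprintf("S%03d", seq_len(n))
  labels <- stats::setNames(cls, rownames(X))
  rep <- train_and_evaluate(X, labels, num_trees = 100L,
                            mtry_grid = c(2L, 5L), cv_folds = 3L, seed = 2)
  expect_equal(rep$auc, 1)
  expect_identical(rep$relevance$feature[1L], "sig")
  # no-leakage contract: nothing from the holdout entered a fitting call
  expect_length(intersect(rep$fit_sample_ids, rep$split$test), 0L)
  expect_setequal(rep$fit_sample_ids, rep$split$train)
  expect_identical(nrow(rep$cv_results), 2L)
  # determinism under the same seed
  rep2 <- train_and_evaluate(X, labels, num_trees = 100L,
                             mtry_grid = c(2L, 5L), cv_folds = 3L, seed = 2)
  expect_identical(rep$auc, rep2$auc)
  expect_identical(rep$split, rep2$split)
})

test_that("within-split imputation uses training statistics only", {
  set.seed(50)
  n <- 60L
  cls <- rep(c("MM", "rest"), c(20L, 40L))
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(sprintf("S%02d", 1:n), paste0("F", 1:8)))
  X[cbind(sample(n, 10), sample(8, 10, replace = TRUE))] <- NA
  labels <- stats::setNames(cls, rownames(X))
  rep_ws <- train_and_evaluate(X, labels, num_trees = 50L,
                               mtry_grid = 2L, impute_k = 3L, seed = 3)
  # corrupting the holdout rows must not change the imputation statistics
  st1 <- knn_impute_stats(X[rep_ws$split$train, ], k = 3L)
  Xc <- X
  Xc[rep_ws$split$test, ] <- Xc[rep_ws$split$test, ] + 100
  st2 <- knn_impute_stats(Xc[rep_ws$split$train, ], k = 3L)
  expect_identical(st1, st2)
})
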