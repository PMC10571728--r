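#' k-nearest-neighbour imputation of a peptide matrix
#'
#' Each missing (sample, peptide) value is filled with the mean of that
#' sample's values over the `k` peptides nearest to the target peptide,
#' where distance is the root-mean-square difference over the samples both
#' peptides share (computed on the values as given, conventionally log2).
#' Peptides missing in more than `max_missing` of samples fall back to
#' their column mean, as do cells with no observed neighbour value.
#'
#' @param X Numeric samples x peptides matrix (log2 scale recommended).
#' @param k Number of neighbour peptides (default 10); must be smaller
#'   than the number of peptides.
#' @param max_missing Missingness fraction above which a peptide is
#'   mean-imputed wholesale (default 0.5).
#' @param stats Optional imputation statistics from a previous
#'   [knn_impute_stats()] call (e.g. computed on a training split) to apply
#'   to new samples.
#' @return Complete numeric matrix of the same shape.
#' @export
knn_impute <- function(X, k = 10L, max_missing = 0.5, stats = NULL) {
  if (k >= ncol(X))
    sq_stop("config_error", "k (%d) must be < number of peptides (%d)",
            k, ncol(X))
  if (any(rowSums(!is.na(X)) == 0L))
    sq_stop("validation_error", "matrix contains an all-missing sample")
  if (is.null(stats)) stats <- knn_impute_stats(X, k, max_missing)
  out <- X
  col_mean <- stats$col_mean[colnames(X)]
  nb <- stats$neighbours
  for (j in seq_len(ncol(X))) {
    miss <- which(is.na(X[, j]))
    if (!length(miss)) next
    cn <- colnames(X)[j]
    if (isTRUE(stats$wholesale[cn]) || is.null(nb[[cn]])) {
      out[miss, j] <- col_mean[cn]
      next
    }
    nb_cols <- match(nb[[cn]], colnames(X))
    for (s in miss) {
      v <- X[s, nb_cols]
      v <- v[!is.na(v)]
      out[s, j] <- if (length(v)) mean(v) else col_mean[cn]
    }
  }
  out
}

#' Imputation statistics (neighbour sets and column means)
#'
#' Separated from [knn_impute()] so leakage-safe workflows can derive the
#' statistics on a training split and apply them to held-out samples.
#'
#' @inheritParams knn_impute
#' @return List: `neighbours` (per peptide, its k nearest peptide names),
#'   `col_mean`, `wholesale` (logical per peptide), `k`.
#' @export
knn_impute_stats <- function(X, k = 10L, max_missing = 0.5) {
  W <- !is.na(X)
  Y <- X
  Y[!W] <- 0
  Wn <- W * 1
  overlap <- crossprod(Wn)
  ss <- crossprod(Y * Y, Wn) # [j, l] = sum_s y_sj^2 * w_sl
  cross <- crossprod(Y)
  msd <- (ss + t(ss) - 2 * cross) / overlap
  msd[overlap < 2L] <- Inf
  diag(msd) <- Inf
  col_mean <- colMeans(X, na.rm = TRUE)
  frac_missing <- colMeans(!W)
  wholesale <- frac_missing > max_missing
  neighbours <- lapply(seq_len(ncol(X)), function(j) {
    d <- msd[, j]
    ord <- order(d)[seq_len(k)]
    ord <- ord[is.finite(d[ord])]
    colnames(X)[ord]
  })
  names(neighbours) <- colnames(X)
  list(neighbours = neighbours, col_mean = col_mean,
       wholesale = wholesale, k = k)
}

#' Stratified train/test split
#'
#' Splits samples into a training and a held-out set, stratified by class
#' so the class proportions are preserved within rounding.
#'
#' @param labels Named vector (names are sample ids) of class labels.
#' @param fraction Training fraction (default 0.7).
#' @param seed Seed for the split.
#' @return List with `train` and `test` character vectors of sample ids.
#' @export
split_cohort <- function(labels, fraction = 0.7, seed = 1L) {
  if (is.null(names(labels)))
    sq_stop("validation_error", "labels must be named by sample id")
  tab <- table(labels)
  if (length(tab) < 2L)
    sq_stop("validation_error", "need at least two classes to split")
  if (any(tab < 2L))
    sq_stop("validation_error", "every class needs at least 2 members")
  set.seed(seed)
  train <- character()
  for (cls in names(tab)) {
    ids <- names(labels)[labels == cls]
    n_tr <- round(length(ids) * fraction)
    train <- c(train, sample(ids, n_tr))
  }
  test <- setdiff(names(labels), train)
  if (!length(test) || !length(train))
    sq_stop("validation_error", "degenerate split: empty train or test set")
  list(train = sort(train), test = sort(test))
}

#' Fit / predict a random forest classifier
#'
#' Binary-classification random forest (bootstrap + mtry-subsampled CART
#' on the Gini criterion, compiled) returning class-1 probabilities as the
#' fraction-of-votes average of per-tree leaf frequencies, and mean
#' impurity-decrease importances. Reproducible under `set.seed()`.
#'
#' @param X Complete numeric samples x features matrix.
#' @param y Logical or 0/1 vector (positive class = 1/TRUE).
#' @param num_trees Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param min_node Minimum node size (default 5).
#' @return List of class `rf_fit` with `importance` named by feature.
#' @export
rf_fit <- function(X, y, num_trees = 500L, mtry = NULL, min_node = 5L) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    sq_stop("validation_error", "y must be binary (0/1 or logical)")
  if (length(unique(y)) < 2L)
    sq_stop("validation_error", "training data contains a single class")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  fit <- .rf_train_cpp(X, y, as.integer(num_trees), as.integer(mtry),
                       as.integer(min_node))
  names(fit$importance) <- colnames(X)
  class(fit) <- "rf_fit"
  fit
}

#' @rdname rf_fit
#' @param fit An `rf_fit`.
#' @param newdata Matrix with the same feature columns.
#' @return `rf_predict`: numeric vector of class-1 probabilities.
#' @export
rf_predict <- function(fit, newdata) {
  stopifnot(inherits(fit, "rf_fit"))
  p <- .rf_predict_cpp(unclass(fit), newdata)
  names(p) <- rownames(newdata)
  p
}

#' ROC curve and area under it
#'
#' Standard threshold sweep over the scores: points start at (0, 0), end at
#' (1, 1) and are monotone non-decreasing; tied scores form diagonal
#' segments, so the trapezoid area equals the Mann-Whitney U statistic
#' normalized by `n_pos * n_neg` (ties counted 1/2).
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Logical or 0/1 truth.
#' @return List: `roc` (data.table `threshold`, `fpr`, `tpr`), `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.logical(labels)
  if (!any(y) || all(y))
    sq_stop("validation_error", "ROC needs both classes in the truth")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  tp <- cumsum(yy)
  fp <- cumsum(!yy)
  last <- c(s[-1] != s[-length(s)], TRUE) # keep last row of each tie group
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(!y))
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.table(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Stratified cross-validation fold assignment
#' @noRd
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ids <- which(y == cls)
    fold[ids] <- sample(rep(seq_len(k), length.out = length(ids)))
  }
  fold
}

#' Train and evaluate the disease classifier
#'
#' Stratified 70/30 split, kNN imputation, random forest tuned over a small
#' mtry grid by stratified 5-fold cross-validation on the training split
#' (selection metric: cross-validated AUC), refit on the full training
#' split, and evaluated on the untouched holdout: ROC/AUC from class
#' probabilities, sensitivity and specificity at the probability
#' threshold, and impurity importances rescaled to a 0-100 relevance
#' score.
#'
#' @param X Samples x peptides matrix of log2 concentrations (may contain
#'   NA; imputed internally).
#' @param labels Named vector of class labels per sample (names must cover
#'   `rownames(X)`).
#' @param positive Label of the positive class (default "MM").
#' @param split_fraction Training fraction (default 0.7).
#' @param cv_folds Cross-validation folds (default 5).
#' @param mtry_grid Integer vector of mtry values to tune over; default
#'   `floor(sqrt(p))` and `floor(p/3)` (deduplicated). A length-1 grid
#'   skips cross-validation.
#' @param num_trees Trees per forest (default 500).
#' @param min_node Minimum node size (default 5).
#' @param threshold Probability cut for sensitivity/specificity
#'   (default 0.5).
#' @param impute_k Neighbours for kNN imputation (default 10).
#' @param impute_mode "within_split" (default: imputation statistics from
#'   the training split only) or "paper_faithful" (impute the full matrix
#'   before splitting).
#' @param seed Master seed: governs split, folds and forests.
#' @return List of class `classifier_report`: `auc`, `roc`, `sensitivity`,
#'   `specificity`, `relevance` (data.table feature, score 0-100),
#'   `cv_results`, `chosen_mtry`, `split` (train/test ids),
#'   `fit_sample_ids` (every id that entered any fitting call), `config`.
#' @export
train_and_evaluate <- function(X, labels, positive = "MM",
                               split_fraction = 0.7, cv_folds = 5L,
                               mtry_grid = NULL, num_trees = 500L,
                               min_node = 5L, threshold = 0.5,
                               impute_k = 10L,
                               impute_mode = c("within_split",
                                               "paper_faithful"),
                               seed = 1L) {
  impute_mode <- match.arg(impute_mode)
  labels <- labels[rownames(X)]
  if (anyNA(labels))
    sq_stop("validation_error", "every sample needs a class label")
  y_all <- labels == positive
  if (is.null(mtry_grid))
    mtry_grid <- unique(pmax(1L, c(floor(sqrt(ncol(X))),
                                   floor(ncol(X) / 3))))

  split <- split_cohort(stats::setNames(ifelse(y_all, positive, "rest"),
                                        names(labels)),
                        fraction = split_fraction, seed = seed)
  set.seed(seed + 1L)

  if (!anyNA(X)) {
    Xtr <- X[split$train, , drop = FALSE]
    Xte <- X[split$test, , drop = FALSE]
  } else if (impute_mode == "paper_faithful") {
    Xc <- knn_impute(X, k = impute_k)
    Xtr <- Xc[split$train, , drop = FALSE]
    Xte <- Xc[split$test, , drop = FALSE]
  } else {
    st <- knn_impute_stats(X[split$train, , drop = FALSE], k = impute_k)
    Xtr <- knn_impute(X[split$train, , drop = FALSE], k = impute_k,
                      stats = st)
    Xte <- knn_impute(X[split$test, , drop = FALSE], k = impute_k,
                      stats = st)
  }
  ytr <- y_all[split$train]
  yte <- y_all[split$test]

  cv_results <- data.table(mtry = integer(), cv_auc = numeric())
  chosen <- mtry_grid[1L]
  if (length(mtry_grid) > 1L) {
    fold <- make_folds(ytr, cv_folds)
    for (mt in mtry_grid) {
      aucs <- numeric(cv_folds)
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        if (length(unique(ytr[tr])) < 2L || length(unique(ytr[!tr])) < 2L)
          sq_stop("validation_error",
                  "single-class cross-validation fold; reduce cv_folds")
        fit <- rf_fit(Xtr[tr, , drop = FALSE], ytr[tr],
                      num_trees = num_trees, mtry = mt,
                      min_node = min_node)
        aucs[f] <- roc_curve(rf_predict(fit, Xtr[!tr, , drop = FALSE]),
                             ytr[!tr])$auc
      }
      cv_results <- rbind(cv_results,
                          data.table(mtry = mt, cv_auc = mean(aucs)))
    }
    chosen <- cv_results$mtry[which.max(cv_results$cv_auc)]
  }

  final <- rf_fit(Xtr, ytr, num_trees = num_trees, mtry = chosen,
                  min_node = min_node)
  prob <- rf_predict(final, Xte)
  rc <- roc_curve(prob, yte)
  pred_pos <- prob >= threshold
  sens <- if (any(yte)) mean(pred_pos[yte]) else NA_real_
  spec <- if (any(!yte)) mean(!pred_pos[!yte]) else NA_real_

  structure(list(
    auc = rc$auc, roc = rc$roc, sensitivity = sens, specificity = spec,
    holdout_scores = prob, holdout_truth = unname(yte),
    relevance = relevance_scores(final),
    cv_results = cv_results, chosen_mtry = chosen,
    split = split, fit_sample_ids = split$train,
    config = list(positive = positive, split_fraction = split_fraction,
                  cv_folds = cv_folds, mtry_grid = mtry_grid,
                  num_trees = num_trees, min_node = min_node,
                  threshold = threshold, impute_k = impute_k,
                  impute_mode = impute_mode, seed = seed)
  ), class = "classifier_report")
}

#' Feature relevance scores on a 0-100 scale
#'
#' Mean impurity-decrease importances linearly rescaled so the most
#' important feature scores 100 (all-zero importances stay 0).
#'
#' @param fit An `rf_fit`.
#' @return data.table: `feature`, `score`, sorted by decreasing score.
#' @export
relevance_scores <- function(fit) {
  imp <- fit$importance
  mx <- max(imp)
  score <- if (mx > 0) 100 * imp / mx else imp * 0
  out <- data.table(feature = names(imp), score = unname(score))
  setorder(out, -score)
  out[]
}
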