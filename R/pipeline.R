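# Evaluation protocol: stratified 80:20 split, grid tuning by inner 3-fold
# CV on ROC-AUC with first-encountered tie-breaking, 3x3 nested CV, and
# holdout confusion-matrix metrics.

#' Stratified train/test split
#'
#' Shuffles each class separately and assigns `round(train_frac * n_class)`
#' rows per class to the training side, so both sides keep the 80:20 class
#' balance to within one row.
#'
#' @param data A data frame with a binary label column.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed.
#' @param label Label column name.
#' @return An `ecd_split` list with `train`, `test`, `train_idx`, `test_idx`.
#' @export
stratified_split <- function(data, train_frac = 0.8, seed = 1L, label = "lesion") {
  y <- as.character(data[[label]])
  if (any(table(y) < 2L)) abort("Every class needs at least 2 rows to split.")
  withr::with_seed(seed, {
    train_idx <- integer(0)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      train_idx <- c(train_idx, idx[seq_len(round(train_frac * length(idx)))])
    }
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_len(nrow(data)), train_idx)
    structure(list(train = data[train_idx, ], test = data[test_idx, ],
                   train_idx = train_idx, test_idx = test_idx, seed = seed),
              class = "ecd_split")
  })
}

#' The hyperparameter tuning grid
#'
#' All 250 combinations of K in 2-6, the ten kernels, and Minkowski distance
#' powers 1-5, enumerated K-major, then kernel in the canonical order, then
#' distance. This enumeration order defines the "first encountered"
#' combination used to break AUC ties during tuning.
#'
#' @return A 250-row tibble with `k`, `kernel`, `distance_power`.
#' @export
tuning_grid <- function() {
  tidyr::expand_grid(k = 2:6, kernel = ECD_KERNELS, distance_power = 1:5)
}

# stratified v-fold assignment; returns a fold id per row
stratified_folds <- function(y, v, seed) {
  y <- as.character(y)
  if (min(table(y)) < v) {
    abort(sprintf("Stratified %d-fold CV impossible: a class has fewer than %d rows.", v, v))
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(v), length(idx))
    }
  })
  folds
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC over the empirical ROC of scores against binary labels,
#' computed as the Mann-Whitney statistic with tied scores contributing 1/2
#' (equivalent to linear interpolation across score ties). A perfect scorer
#' gives 1; a constant scorer 0.5.
#'
#' @param scores Numeric scores (higher = more lesion-like).
#' @param labels Labels coercible to no/yes.
#' @return The AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  y <- as.character(labels) == "yes"
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) abort("AUC needs both classes.")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname auc_score
#' @return For `roc_points()`: a tibble of `(threshold, fpr, tpr)` tracing
#'   the empirical ROC from (0, 0) to (1, 1).
#' @export
roc_points <- function(scores, labels) {
  y <- as.character(labels) == "yes"
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # one point per distinct score
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    tpr = c(0, cumsum(y)[keep] / sum(y)),
    fpr = c(0, cumsum(!y)[keep] / sum(!y))
  )
}

# inner-CV mean AUC for every grid row; returns the grid with mean_auc
grid_cv_auc <- function(train, grid, inner_folds, seed, label) {
  y <- train[[label]]
  folds <- stratified_folds(y, inner_folds, seed)
  features <- grep("^rp_\\d+$", names(train), value = TRUE)
  X <- as.matrix(train[, features, drop = FALSE])
  yf <- factor(as.character(y), levels = c("no", "yes"))

  fold_aucs <- matrix(NA_real_, nrow(grid), inner_folds)
  for (f in seq_len(inner_folds)) {
    tr <- folds != f
    # one distance matrix per Minkowski power, shared across k and kernel
    for (p in unique(grid$distance_power)) {
      D <- minkowski_matrix(X[!tr, , drop = FALSE], X[tr, , drop = FALSE], p)
      rows <- which(grid$distance_power == p)
      for (gi in rows) {
        if (sum(tr) < grid$k[gi] + 1L) next
        prob <- wknn_prob_from_dist(D, yf[tr], grid$k[gi], grid$kernel[gi],
                                    dim = length(features))
        fold_aucs[gi, f] <- auc_score(prob, yf[!tr])
      }
    }
  }
  grid$mean_auc <- rowMeans(fold_aucs)
  grid
}

#' Tune hyperparameters by inner cross-validated AUC
#'
#' Scores every grid combination by its mean stratified `inner_folds`-fold
#' cross-validated ROC-AUC on the training data and returns the best; when
#' several combinations tie on AUC, the first encountered in the enumeration
#' order of [tuning_grid()] wins.
#'
#' @param train Training data (feature columns plus label).
#' @param grid A hyperparameter tibble (default [tuning_grid()]).
#' @param inner_folds Number of inner CV folds (default 3).
#' @param seed Integer seed for the fold assignment.
#' @param label Label column name.
#' @return A list with `best` (one-row tibble) and `results` (the grid with
#'   `mean_auc`).
#' @export
tune_wknn <- function(train, grid = tuning_grid(), inner_folds = 3L, seed = 1L,
                      label = "lesion") {
  results <- grid_cv_auc(train, grid, inner_folds, seed, label)
  best <- results[which.max(results$mean_auc), ]  # which.max: first maximum
  list(best = best, results = results)
}

confusion_metrics <- function(truth, pred) {
  truth <- as.character(truth) == "yes"
  pred <- as.character(pred) == "yes"
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  n <- tp + tn + fp + fn
  list(
    accuracy = 100 * (tp + tn) / n,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    classification_error = (fp + fn) / n,
    tp = tp, tn = tn, fp = fp, fn = fn
  )
}

new_eval_result <- function(predictions, best_params = NULL) {
  cm <- confusion_metrics(predictions$truth, predictions$.class)
  structure(
    list(
      auc = auc_score(predictions$.prob_yes, predictions$truth),
      classification_error = cm$classification_error,
      accuracy = cm$accuracy, sensitivity = cm$sensitivity,
      specificity = cm$specificity,
      roc = roc_points(predictions$.prob_yes, predictions$truth),
      predictions = predictions, best_params = best_params,
      confusion = cm[c("tp", "tn", "fp", "fn")]
    ),
    class = "ecd_eval"
  )
}

#' @export
print.ecd_eval <- function(x, ...) {
  cat(sprintf(
    "<ecd_eval> AUC = %.3f | accuracy %.1f%% | sensitivity %s | specificity %s | n = %d\n",
    x$auc, x$accuracy,
    ifelse(is.na(x$sensitivity), "NA", sprintf("%.1f%%", x$sensitivity)),
    ifelse(is.na(x$specificity), "NA", sprintf("%.1f%%", x$specificity)),
    nrow(x$predictions)
  ))
  invisible(x)
}

#' Nested cross-validation of the weighted-KNN pipeline
#'
#' Stratified 3 x 3 nested cross-validation: within each outer fold the full
#' tuning grid is re-tuned by inner CV on the outer-training rows only, the
#' winning model is fit and scored on the outer-test rows, and the pooled
#' out-of-fold predictions give the ROC/AUC and classification error. No row
#' is ever seen by the tuner that evaluates it (asserted structurally).
#'
#' @param data Feature data with label column.
#' @param outer_folds,inner_folds Fold counts (default 3 and 3).
#' @param seed Integer seed governing both fold layers.
#' @param grid Hyperparameter grid.
#' @param label Label column name.
#' @return An `ecd_eval`; `best_params` holds the per-outer-fold winners.
#' @export
nested_cv <- function(data, outer_folds = 3L, inner_folds = 3L, seed = 1L,
                      grid = tuning_grid(), label = "lesion") {
  folds <- stratified_folds(data[[label]], outer_folds, seed)
  preds <- purrr::map_dfr(seq_len(outer_folds), function(f) {
    tr_idx <- which(folds != f)
    te_idx <- which(folds == f)
    stopifnot(length(intersect(tr_idx, te_idx)) == 0L)  # leakage guard
    tuned <- tune_wknn(data[tr_idx, ], grid, inner_folds, seed = seed + f, label = label)
    fit <- fit_wknn(data[tr_idx, ], k = tuned$best$k, kernel = tuned$best$kernel,
                    distance_power = tuned$best$distance_power, label = label)
    p <- predict(fit, data[te_idx, ])
    p$truth <- factor(as.character(data[[label]][te_idx]), levels = c("no", "yes"))
    p$outer_fold <- f
    p$row <- te_idx
    p$k <- tuned$best$k; p$kernel <- tuned$best$kernel
    p$distance_power <- tuned$best$distance_power
    p
  })
  best <- dplyr::distinct(preds[, c("outer_fold", "k", "kernel", "distance_power")])
  new_eval_result(preds, best_params = best)
}

#' Evaluate a fitted model on a holdout test set
#'
#' Confusion-matrix metrics (accuracy, sensitivity, specificity in percent,
#' with "lesion = yes" as the positive class) plus ROC/AUC on a test set
#' disjoint from the training data.
#'
#' @param model A fitted `ecd_wknn`.
#' @param test Test data with label column.
#' @param label Label column name.
#' @return An `ecd_eval`.
#' @export
holdout_eval <- function(model, test, label = "lesion") {
  if (nrow(test) == 0L) abort("Empty test set.")
  p <- predict(model, test)
  p$truth <- factor(as.character(test[[label]]), levels = c("no", "yes"))
  new_eval_result(p, best_params = glance(model))
}

#' Split, tune and evaluate in one call
#'
#' The full holdout protocol: stratified 80:20 split, grid tuning by inner
#' 3-fold CV on the training side, final fit with the winning
#' hyperparameters, and holdout evaluation on the untouched test side.
#'
#' @inheritParams nested_cv
#' @param train_frac Training fraction for the initial split.
#' @return An `ecd_eval` for the holdout set; the selected hyperparameters
#'   are in `$best_params`.
#' @export
run_holdout_pipeline <- function(data, train_frac = 0.8, inner_folds = 3L,
                                 seed = 1L, grid = tuning_grid(), label = "lesion") {
  sp <- stratified_split(data, train_frac, seed, label)
  tuned <- tune_wknn(sp$train, grid, inner_folds, seed = seed, label = label)
  fit <- fit_wknn(sp$train, k = tuned$best$k, kernel = tuned$best$kernel,
                  distance_power = tuned$best$distance_power, label = label)
  holdout_eval(fit, sp$test, label = label)
}

#' @exportS3Method generics::glance
glance.ecd_eval <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, classification_error = x$classification_error,
    accuracy = x$accuracy, sensitivity = x$sensitivity,
    specificity = x$specificity, n = nrow(x$predictions)
  )
}

#' @exportS3Method generics::tidy
tidy.ecd_eval <- function(x, ...) x$roc
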