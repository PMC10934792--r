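#' @name classify
#' @title RBF-SVM classification with grid-searched hyperparameters
#'
#' @description
#' Feature vectors are classified with a radial-basis-function support
#' vector machine. The penalty `C` and kernel width `g` strongly affect
#' accuracy, so both are grid-searched (default grids
#' \{0.001, 0.01, 0.1, 1, 10, 100, 1000\}) by stratified k-fold
#' cross-validation (default five folds); features are standardized inside
#' each fit using the training data only (RBF kernels are scale-sensitive
#' and log-variance features are unbounded).
NULL

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds, balanced within each
#' class, using the current RNG stream (seed outside for reproducibility).
#'
#' @param labels class labels.
#' @param k number of folds.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("stratified_folds: class ", cl, " has ", length(idx),
           " members, fewer than k = ", k, "; use a smaller k", call. = FALSE)
    folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
  }
  folds
}

svm_fit_one <- function(features, labels, c_val, g_val, standardize = TRUE) {
  e1071::svm(x = features, y = factor(labels), kernel = "radial",
             cost = c_val, gamma = g_val, scale = standardize)
}

#' Grid-search an RBF SVM with stratified k-fold cross-validation
#'
#' For every `(C, g)` pair the mean k-fold accuracy is computed using a
#' fixed fold assignment (drawn here from the current RNG stream unless
#' `fold_ids` is supplied); the best pair - ties broken by smaller `C`,
#' then smaller `g` - is refit on all the data.
#'
#' @param features numeric matrix, trials x features.
#' @param labels two-class labels, at least `k` trials per class.
#' @param c_grid,g_grid candidate values for the penalty and kernel width.
#' @param k number of folds (default 5).
#' @param fold_ids optional precomputed fold assignment (overrides `k`'s
#'   random draw; length must match `labels`).
#' @param standardize standardize features inside each fit, using the
#'   training portion only (default `TRUE`).
#' @return a `trained_classifier`: list with the fitted `model`, chosen `C`
#'   and `g`, `cv_accuracy`, the full `cv_table` (one row per grid pair),
#'   `folds`, and `n_fits` (number of fold fits performed).
#' @export
grid_search_cv <- function(features, labels,
                           c_grid = c(0.001, 0.01, 0.1, 1, 10, 100, 1000),
                           g_grid = c(0.001, 0.01, 0.1, 1, 10, 100, 1000),
                           k = 5L, fold_ids = NULL, standardize = TRUE) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2L)
    stop("grid_search_cv: exactly two classes required", call. = FALSE)
  if (is.null(fold_ids)) fold_ids <- stratified_folds(labels, k)
  k <- max(fold_ids)
  c_grid <- sort(c_grid)
  g_grid <- sort(g_grid)
  grid <- expand.grid(g = g_grid, C = c_grid)   # C varies slowest
  acc <- numeric(nrow(grid))
  n_fits <- 0L
  fold_sets <- lapply(seq_len(k), function(f) which(fold_ids == f))
  for (gi in seq_len(nrow(grid))) {
    fold_acc <- numeric(k)
    for (f in seq_len(k)) {
      te <- fold_sets[[f]]
      fit <- svm_fit_one(features[-te, , drop = FALSE], labels[-te],
                         grid$C[gi], grid$g[gi], standardize)
      pred <- predict(fit, features[te, , drop = FALSE])
      fold_acc[f] <- mean(as.integer(as.character(pred)) == labels[te])
      n_fits <- n_fits + 1L
    }
    acc[gi] <- mean(fold_acc)
  }
  # first index of the max, scanning smaller C first, then smaller g
  ord <- order(grid$C, grid$g)
  best <- ord[which.max(acc[ord])]
  final <- svm_fit_one(features, labels, grid$C[best], grid$g[best],
                       standardize)
  structure(list(model = final, C = grid$C[best], g = grid$g[best],
                 cv_accuracy = acc[best],
                 cv_table = cbind(grid[, c("C", "g")], accuracy = acc),
                 folds = k, n_fits = n_fits, standardize = standardize),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier> RBF SVM, C = %g, g = %g; CV accuracy %.3f (%d folds)\n",
              x$C, x$g, x$cv_accuracy, x$folds))
  invisible(x)
}

#' Accuracy of a trained classifier on labelled features
#'
#' @param clf a `trained_classifier`.
#' @param features numeric matrix with the training feature dimension.
#' @param labels true labels.
#' @return fraction of correct predictions in `[0, 1]`.
#' @export
evaluate_classifier <- function(clf, features, labels) {
  features <- as.matrix(features)
  if (nrow(features) == 0L)
    stop("evaluate_classifier: empty feature set", call. = FALSE)
  if (ncol(features) != ncol(clf$model$SV))
    stop("evaluate_classifier: feature dimension mismatch", call. = FALSE)
  pred <- predict(clf$model, features)
  mean(as.integer(as.character(pred)) == as.integer(labels))
}
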