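# Multi-source feature selection: adaptive boosting of depth-limited
# decision trees; features are scored by the estimator-weight-weighted mean
# of per-tree Gini impurity decrease and kept when the score is strictly
# positive.

#' Fit the boosted-tree feature selector
#'
#' Fits a discrete AdaBoost (SAMME) ensemble of depth-limited CART-style
#' trees (stumps by default) on the labelled feature matrix.  Each tree is
#' grown on the current instance-weight distribution; every split records
#' the weighted Gini impurity decrease it achieves, attributed to the split
#' feature.  A feature's score is the estimator-weight-weighted mean of its
#' per-tree impurity decrease, and features with score strictly greater
#' than zero form the selected subset (so constant columns can never
#' enter).
#'
#' The boosting loop is deterministic: splits are searched exhaustively and
#' ties are broken by the first (lowest-index) feature and threshold, so
#' repeated fits on identical input give identical scores.  Boosting stops
#' early if a round produces a perfect weak learner (kept with unit weight)
#' or one no better than chance (discarded).
#'
#' @param X Numeric feature matrix (samples x features) with column names.
#' @param y Binary 0/1 label vector, one per row of `X`.
#' @param n_estimators Number of boosting rounds (default 100).
#' @param max_depth Tree depth limit (default 1 = decision stumps).
#' @param seed Integer recorded as fitting metadata (the fit itself is
#'   deterministic).
#' @return An object of class `enfusion_selector` with elements
#'   `feature_scores`, `selected_indices`, `feature_names`,
#'   `n_estimators`, `max_depth`, `seed`, `n_trees`.
#' @export
fit_selector <- function(X, y, n_estimators = 100L, max_depth = 1L,
                         seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop_enfusion("X rows must match y length")
  if (anyNA(X)) stop_enfusion("X contains missing values")
  if (!all(y %in% c(0L, 1L))) stop_enfusion("labels must be binary 0/1")
  if (length(unique(y)) < 2L) {
    stop_enfusion("both classes must be present to fit the selector")
  }
  n_estimators <- as.integer(n_estimators)
  stopifnot(n_estimators >= 1L)
  fit <- .adaboost_fit_cpp(X, y, n_estimators, as.integer(max_depth))
  scores <- as.numeric(fit$scores)
  structure(list(
    feature_scores = stats::setNames(scores, colnames(X)),
    selected_indices = which(scores > 0),
    feature_names = colnames(X),
    n_estimators = n_estimators,
    max_depth = as.integer(max_depth),
    seed = as.integer(seed),
    n_trees = fit$n_trees,
    estimator_weights = as.numeric(fit$alphas),
    train_errors = as.numeric(fit$errors)
  ), class = "enfusion_selector")
}

#' @export
print.enfusion_selector <- function(x, ...) {
  cat("<enfusion_selector> ", length(x$selected_indices), " of ",
      length(x$feature_scores), " features selected (",
      x$n_trees, " boosted trees, depth ", x$max_depth, ")\n", sep = "")
  invisible(x)
}

#' Project a feature matrix onto the selected features
#'
#' @param model An `enfusion_selector` from [fit_selector()].
#' @param X Feature matrix whose column names match those seen at fit time
#'   (same names, same order).
#' @return `X` restricted to the selected columns, original order.
#' @export
apply_selector <- function(model, X) {
  stopifnot(inherits(model, "enfusion_selector"))
  X <- as.matrix(X)
  if (!is.null(model$feature_names)) {
    if (is.null(colnames(X))) {
      stop_enfusion("feature names do not match those seen at fit time; ",
                    "input has no column names")
    }
    if (!identical(colnames(X), model$feature_names)) {
      k <- min(ncol(X), length(model$feature_names))
      i <- which(colnames(X)[seq_len(k)] != model$feature_names[seq_len(k)])
      i <- if (length(i)) i[1L] else k + 1L
      stop_enfusion("feature names do not match those seen at fit time; ",
                    "first divergent column ", i, ": '",
                    if (i <= ncol(X)) colnames(X)[i] else "<missing>",
                    "' vs '",
                    if (i <= length(model$feature_names)) model$feature_names[i] else "<missing>",
                    "'")
    }
  } else if (ncol(X) != length(model$feature_scores)) {
    stop_enfusion("feature count mismatch: ", ncol(X), " vs ",
                  length(model$feature_scores))
  }
  X[, model$selected_indices, drop = FALSE]
}
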