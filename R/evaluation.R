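# Evaluation: confusion counts, ACC / MCC / SN / SP / AUC, stratified
# k-fold cross-validation of the full pipeline, and a small grid-search
# utility driven by mean MCC.

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Binary 0/1 vectors of equal length (1 = enhancer).
#' @return List of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop_enfusion("y_true and y_pred must have equal length")
  }
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop_enfusion("labels must be binary 0/1")
  }
  structure(list(
    TP = sum(y_true == 1L & y_pred == 1L),
    FP = sum(y_true == 0L & y_pred == 1L),
    TN = sum(y_true == 0L & y_pred == 0L),
    FN = sum(y_true == 1L & y_pred == 0L)
  ), class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' convention that a zero factor in the denominator gives 0 (the formula is
#' undefined there).  1 is perfect classification, -1 total inversion.
#'
#' @param c A [confusion()] result (or a list with TP/FP/TN/FN).
#' @return Numeric value in `[-1, 1]`.
#' @export
mcc <- function(c) {
  tp <- c$TP; fp <- c$FP; tn <- c$TN; fn <- c$FN
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
}

#' Accuracy, sensitivity and specificity
#'
#' `ACC = (TP+TN)/(TP+FP+TN+FN)`, `SN = TP/(TP+FN)`, `SP = TN/(TN+FP)`.
#' A ratio with zero denominator is reported as `NA` (missing), not 0.
#'
#' @param c A [confusion()] result.
#' @return Named numeric vector `c(acc, sn, sp)`.
#' @export
acc_sn_sp <- function(c) {
  tp <- c$TP; fp <- c$FP; tn <- c$TN; fn <- c$FN
  total <- tp + fp + tn + fn
  c(acc = if (total == 0) NA_real_ else (tp + tn) / total,
    sn = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    sp = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}

# AUC of a score vector against binary truth; NA when one class is absent
score_auc <- function(y_true, score) {
  if (length(unique(y_true)) < 2L) return(NA_real_)
  r <- pROC::roc(response = y_true, predictor = score, quiet = TRUE,
                 levels = c(0L, 1L), direction = "<")
  as.numeric(pROC::auc(r))
}

metric_row <- function(y_true, y_pred, score = NULL) {
  cc <- confusion(y_true, y_pred)
  m <- acc_sn_sp(cc)
  data.frame(acc = m[["acc"]], sn = m[["sn"]], sp = m[["sp"]],
             mcc = mcc(cc),
             auc = if (is.null(score)) NA_real_ else score_auc(y_true, score))
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits the dataset into `k` stratified folds; for each fold the entire
#' pipeline — multi-source encoding + selector, embedder, sequence
#' network, voting ensemble — is fitted on the remaining folds only and
#' evaluated on the held-out fold.  AUC is computed from the ensemble's
#' vote fraction (the only graded score a hard-voting model emits).
#'
#' @param dataset A labelled [seq_dataset()]; each class must have at least
#'   `k` members.
#' @param config A [pipeline_config()].
#' @param k Number of folds (default 10).
#' @param seed Seed controlling fold assignment and all per-fold fits.
#' @return A `metric_report`: list with `folds` (per-fold data frame),
#'   `mean`, `sd` and the fold assignment.
#' @export
cross_validate <- function(dataset, config = pipeline_config(), k = 10L,
                           seed = 1L) {
  stopifnot(inherits(dataset, "seq_dataset"))
  if (is.null(dataset$label)) stop_enfusion("dataset must be labelled")
  k <- as.integer(k)
  counts <- table(factor(dataset$label, levels = c(0L, 1L)))
  if (any(counts < k)) {
    stop_enfusion("each class must have at least k = ", k,
                  " members (found ", paste(counts, collapse = "/"), ")")
  }
  folds <- with_seed(derive_seed(seed, "cv-folds"), {
    make_stratified_folds(dataset$label, k)
  })
  per_fold <- vector("list", k)
  for (fi in seq_len(k)) {
    train <- dataset[folds != fi]
    test <- dataset[folds == fi]
    model <- train_pipeline(train, config, seed = derive_seed(seed, paste0("fold", fi)))
    pred <- predict(model, test)
    per_fold[[fi]] <- cbind(fold = fi,
                            metric_row(test$label, pred$class, pred$vote))
  }
  fold_df <- do.call(rbind, per_fold)
  structure(list(
    folds = fold_df,
    mean = colMeans(fold_df[, -1L], na.rm = TRUE),
    sd = apply(fold_df[, -1L], 2L, stats::sd, na.rm = TRUE),
    k = k, fold_assignment = folds, seed = as.integer(seed)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> ", x$k, "-fold cross-validation\n", sep = "")
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 4))
  invisible(x)
}

#' Grid search over pipeline parameters by mean cross-validated MCC
#'
#' Evaluates every combination of the supplied parameter value lists with
#' [cross_validate()] and returns the combination with the highest mean
#' MCC; ties are broken in favour of the first-listed combination.
#'
#' Parameter names are dotted paths into the pipeline configuration, e.g.
#' `"seqnet.lstm_units"` or `"selector.n_estimators"`.
#'
#' @param dataset A labelled [seq_dataset()].
#' @param space Named list; each element is a vector/list of candidate
#'   values for one configuration path.
#' @param config Base [pipeline_config()] the combinations are applied to.
#' @param k Folds per evaluation.
#' @param seed Seed shared across evaluations.
#' @return List with `best` (combination + mean MCC), `results` (one row
#'   per combination) and the winning `config`.
#' @export
grid_search <- function(dataset, space, config = pipeline_config(),
                        k = 10L, seed = 1L) {
  if (length(space) == 0L) stop_enfusion("empty search space")
  if (is.null(names(space)) || any(names(space) == "")) {
    stop_enfusion("all search-space entries must be named")
  }
  grid <- expand.grid(lapply(space, seq_along), KEEP.OUT.ATTRS = FALSE)
  results <- data.frame()
  best <- list(mcc = -Inf, index = NA_integer_, config = NULL)
  for (ci in seq_len(nrow(grid))) {
    cfg <- config
    row <- list()
    for (pn in names(space)) {
      val <- space[[pn]][[grid[ci, pn]]]
      cfg <- set_config_path(cfg, strsplit(pn, ".", fixed = TRUE)[[1L]], val)
      row[[pn]] <- val
    }
    rep_i <- cross_validate(dataset, cfg, k = k, seed = seed)
    results <- rbind(results,
                     cbind(as.data.frame(row), mean_mcc = rep_i$mean[["mcc"]]))
    if (rep_i$mean[["mcc"]] > best$mcc) {
      best <- list(mcc = rep_i$mean[["mcc"]], index = ci, config = cfg,
                   combination = row)
    }
  }
  list(best = best, results = results, config = best$config)
}

set_config_path <- function(cfg, path, value) {
  if (length(path) == 1L) {
    cfg[[path]] <- value
    return(cfg)
  }
  cfg[[path[1L]]] <- set_config_path(cfg[[path[1L]]], path[-1L], value)
  cfg
}
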