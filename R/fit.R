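# Encoder plumbing shared by pathometa_fit() and grid_search(): fit an
# encoder state on the training table, and re-apply it to any table.

.fit_encoder <- function(table, encoding, ae_config = NULL) {
  onehot_needed <- encoding %in% c("onehot", "mca", "autoencoder")
  state <- list(encoding = encoding)
  if (encoding == "label") {
    state$X <- encode_label(table)
  } else {
    oh <- encode_onehot(table)
    if (encoding == "onehot") {
      state$X <- oh
    } else if (encoding == "mca") {
      state$mca <- fit_mca(oh)
      state$X <- transform_mca(state$mca, oh)
    } else if (encoding == "autoencoder") {
      if (is.null(ae_config)) ae_config <- autoencoder_config()
      state$ae <- fit_autoencoder(oh, ae_config)
      state$X <- transform_autoencoder(state$ae, oh)
    } else stop("unknown encoding: ", encoding, call. = FALSE)
  }
  state
}

.apply_encoder <- function(state, table) {
  switch(state$encoding,
    label = encode_label(table),
    onehot = encode_onehot(table),
    mca = transform_mca(state$mca, encode_onehot(table)),
    autoencoder = transform_autoencoder(state$ae, encode_onehot(table)),
    stop("unknown encoding: ", state$encoding, call. = FALSE))
}

.rf_fit_fun <- function(ntree, mtry, seed) {
  force(ntree); force(mtry); force(seed)
  function(X, y) {
    old <- .Random.seed_save()
    set.seed(seed)
    rf <- randomForest::randomForest(
      x = as.matrix(X), y = factor(y, levels = c(0L, 1L)),
      ntree = ntree, mtry = min(mtry, ncol(X)))
    .Random.seed_restore(old)
    function(Xnew) unname(stats::predict(rf, as.matrix(Xnew), type = "prob")[, "1"])
  }
}

#' Fit a random-forest pathogenicity metapredictor
#'
#' Trains a random forest on the encoded calls of the eight functional-impact
#' predictors: each tree is grown on a bootstrap sample of the training
#' variants with `mtry` candidate features per split, and the pathogenic
#' probability of a variant (RFprob) is the fraction of trees voting
#' pathogenic, with a majority vote for the label. The out-of-bag (OOB)
#' error — the misclassification rate on samples excluded from each tree's
#' bootstrap — is recorded as a built-in cross-validation surrogate.
#'
#' @param table a training `"feature_table"` (labels `benign`/`pathogenic`;
#'   typically `split_by_role(...)$train`), with at least 2 rows per class.
#' @param encoding feature representation: `"label"`, `"onehot"`, `"mca"`
#'   or `"autoencoder"`.
#' @param ntree number of trees (the tuning range of interest is 50-1000).
#' @param mtry candidate features per split.
#' @param seed integer seed; fixed seed gives an identical forest.
#' @param ae_config [autoencoder_config()] when `encoding = "autoencoder"`.
#' @return An object of class `"pathometa_model"`: the fitted forest, the
#'   fitted encoder state, `oob_error`, and the training call.
#' @examples
#' spec <- synthetic_spec(n_benign = 60, n_pathogenic = 60, concordance = 0.95,
#'                        seed = 3)
#' tab <- split_by_role(filter_complete_cases(simulate_variants(spec)))$train
#' fit <- pathometa_fit(tab, encoding = "onehot", ntree = 100, mtry = 4, seed = 1)
#' fit$oob_error
#' @export
pathometa_fit <- function(table, encoding = c("onehot", "label", "mca", "autoencoder"),
                          ntree = 500L, mtry = 2L, seed = 1L, ae_config = NULL) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(table, "feature_table"))
  y <- if ("y" %in% names(table)) table$y else as.integer(table$label == "pathogenic")
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("need at least 2 training rows per class", call. = FALSE)
  }
  state <- .fit_encoder(table, encoding, ae_config)
  X <- state$X

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = as.matrix(X), y = factor(y, levels = c(0L, 1L)),
    ntree = as.integer(ntree), mtry = min(as.integer(mtry), ncol(X)),
    importance = FALSE)
  oob <- unname(rf$err.rate[nrow(rf$err.rate), "OOB"])

  structure(list(
    forest = rf, encoder = state[setdiff(names(state), "X")],
    encoding = encoding, ntree = as.integer(ntree),
    mtry = min(as.integer(mtry), ncol(X)), seed = as.integer(seed),
    oob_error = oob, n_train = nrow(X), d = ncol(X),
    class_counts = table(factor(y, levels = c(0L, 1L)))
  ), class = "pathometa_model")
}

#' @export
print.pathometa_model <- function(x, ...) {
  cat("Pathogenicity metapredictor (random forest)\n")
  cat("  encoding:", x$encoding, " features:", x$d,
      " trees:", x$ntree, " mtry:", x$mtry, "\n")
  cat(sprintf("  trained on %d variants (%d benign / %d pathogenic), OOB error %.4f\n",
              x$n_train, x$class_counts[1], x$class_counts[2], x$oob_error))
  invisible(x)
}

#' @export
summary.pathometa_model <- function(object, ...) {
  print(object)
  imp <- gini_importance(object)
  cat("Gini importance (normalized):\n")
  print(round(sort(imp$importance, decreasing = TRUE), 4))
  invisible(object)
}

#' @export
plot.pathometa_model <- function(x, ...) {
  imp <- sort(gini_importance(x)$importance, decreasing = FALSE)
  graphics::barplot(imp, horiz = TRUE, las = 1,
                    xlab = "normalized Gini importance",
                    main = "Feature importance", ...)
  invisible(x)
}

#' Stratified k-fold cross-validated AUC of a random-forest configuration
#'
#' Splits the rows into k stratified folds, trains a forest on each
#' complement, scores the held-out fold by vote fraction, and computes the
#' per-fold ROC AUC by trapezoid ([roc_auc()]). Folds degenerate to a single
#' class are skipped with a warning.
#'
#' @param X encoded feature matrix.
#' @param y binary labels (0 = benign, 1 = pathogenic).
#' @param ntree,mtry forest configuration.
#' @param k number of folds.
#' @param seed seed for fold assignment and tree growing.
#' @return An `"evaluation_result"`: `auc` (mean over folds), `sd`,
#'   `fold_aucs`, plus the folds' misclassification rate at the 0.5 vote
#'   threshold (`cv_error`, `fold_errors`) for comparison with the OOB error.
#' @export
kfold_auc <- function(X, y, ntree = 500L, mtry = 2L, k = 10L, seed = 1L) {
  .cv_auc(as.matrix(X), y, .rf_fit_fun(ntree, mtry, seed), k = k, seed = seed)
}

#' Gini-impurity feature importance of a fitted metapredictor
#'
#' Mean decrease in node (Gini) impurity per feature, summed over all trees
#' and normalized to sum 1. For the one-hot encoding the per-category columns
#' are additionally aggregated to their source predictor, so importance is
#' comparable across encodings.
#'
#' @param model a `"pathometa_model"`.
#' @return A list of class `"importance_report"`: `importance` (named,
#'   nonnegative, sums to 1) and, for one-hot models, `by_column` (the
#'   unaggregated per-category values).
#' @export
gini_importance <- function(model) {
  stopifnot(inherits(model, "pathometa_model"))
  raw <- randomForest::importance(model$forest, type = 2)[, "MeanDecreaseGini"]
  total <- sum(raw)
  if (total <= 0) raw[] <- 1 / length(raw) else raw <- raw / total
  out <- list(importance = raw)
  if (model$encoding == "onehot") {
    pred <- sub("_[^_]$", "", names(raw))
    agg <- tapply(raw, pred, sum)
    out <- list(importance = agg[order(match(names(agg), predictor_names()))],
                by_column = raw)
  }
  class(out) <- "importance_report"
  out
}

#' @export
print.importance_report <- function(x, ...) {
  print(round(sort(x$importance, decreasing = TRUE), 4))
  invisible(x)
}
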