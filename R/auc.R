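#' Area under the ROC curve by threshold sweep
#'
#' Sweeps every distinct score as a decision threshold, computes the true- and
#' false-positive rates, and integrates by the trapezoid rule. Tied scores are
#' collapsed into a single ROC step, so the result equals the Mann-Whitney
#' concordance probability with ties counted 1/2.
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param labels binary labels (0/1, logical, or a factor whose second level
#'   is the positive class).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- .as_binary(labels)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("AUC requires both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  # cumulative TP/FP at the end of each tie group
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1L)[last_of_group] / npos
  fp <- cumsum(y == 0L)[last_of_group] / nneg
  tp <- c(0, tp); fp <- c(0, fp)
  sum(diff(fp) * (tp[-1] + tp[-length(tp)]) / 2)
}

.as_binary <- function(labels) {
  if (is.factor(labels)) as.integer(labels) - 1L
  else if (is.logical(labels)) as.integer(labels)
  else as.integer(labels)
}

# Stratified fold assignment: within each class, shuffled rows are dealt
# round-robin into k folds.
.stratified_folds <- function(y, k, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Generic stratified k-fold CV AUC: fit_fun(X, y) must return a scoring
# closure function(Xnew) -> numeric pathogenic-like score.
.cv_auc <- function(X, y, fit_fun, k = 10L, seed = 1L) {
  y <- .as_binary(y)
  n <- length(y)
  if (n < k) stop("need at least k rows for k-fold CV", call. = FALSE)
  fold <- .stratified_folds(y, k, seed)
  fold_aucs <- fold_errors <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    te <- fold == f
    if (length(unique(y[te])) < 2L) {
      warning("fold ", f, " has a single class; skipped", call. = FALSE)
      next
    }
    scores <- fit_fun(X[!te, , drop = FALSE], y[!te])(X[te, , drop = FALSE])
    fold_aucs[f] <- roc_auc(scores, y[te])
    fold_errors[f] <- mean((scores >= 0.5) != (y[te] == 1L))
  }
  keep <- !is.na(fold_aucs)
  fold_aucs <- fold_aucs[keep]
  structure(list(auc = mean(fold_aucs), sd = stats::sd(fold_aucs),
                 fold_aucs = fold_aucs, cv_error = mean(fold_errors[keep]),
                 fold_errors = fold_errors[keep], k = k),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("%d-fold CV AUC: %.4f (sd %.4f", x$k, x$auc,
              if (is.na(x$sd)) 0 else x$sd), ")\n", sep = "")
  if (!is.null(x$oob_error)) cat(sprintf("OOB error: %.4f\n", x$oob_error))
  invisible(x)
}
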