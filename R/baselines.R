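#' Naive Bayes and SVM baselines for the metapredictor comparison
#'
#' Trains a baseline classifier on an encoded matrix and reports stratified
#' 10-fold cross-validated AUC, comparable with the random-forest results.
#' Naive Bayes treats 0/1 indicator (and small-integer label-encoded)
#' columns as categorical; SVM scores are mapped to probabilities by Platt's
#' monotone sigmoid calibration, which leaves the AUC unchanged.
#'
#' @param X encoded feature matrix.
#' @param y binary labels (0 = benign, 1 = pathogenic).
#' @param kind `"naive_bayes"`, `"svm_linear"` or `"svm_rbf"`.
#' @param k CV folds.
#' @param seed seed for fold assignment (and the SVM's internal calibration).
#' @return A list with `model` (fitted on all rows) and `evaluation`
#'   (an `"evaluation_result"`).
#' @export
train_baseline <- function(X, y, kind = c("naive_bayes", "svm_linear", "svm_rbf"),
                           k = 10L, seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- .as_binary(y)
  categorical <- all(X == floor(X)) && length(unique(as.vector(X))) <= 8L

  fit_fun <- switch(kind,
    naive_bayes = function(Xtr, ytr) {
      df <- as.data.frame(Xtr)
      if (categorical) df[] <- lapply(df, factor)
      nb <- e1071::naiveBayes(df, factor(ytr, levels = c(0L, 1L)))
      function(Xnew) {
        dfn <- as.data.frame(Xnew)
        if (categorical) {
          dfn[] <- Map(function(col, tr) factor(col, levels = levels(tr)),
                       dfn, df)
        }
        unname(stats::predict(nb, dfn, type = "raw")[, "1"])
      }
    },
    svm_linear = .svm_fit_fun("linear", seed),
    svm_rbf = .svm_fit_fun("radial", seed)
  )

  model <- fit_fun(X, y)
  evaluation <- .cv_auc(X, y, fit_fun, k = k, seed = seed)
  list(kind = kind, model = model, evaluation = evaluation)
}

.svm_fit_fun <- function(kernel, seed) {
  force(kernel); force(seed)
  function(Xtr, ytr) {
    old <- .Random.seed_save()
    set.seed(seed)
    sv <- e1071::svm(x = Xtr, y = factor(ytr, levels = c(0L, 1L)),
                     kernel = kernel, probability = TRUE, scale = FALSE)
    .Random.seed_restore(old)
    function(Xnew) {
      p <- stats::predict(sv, Xnew, probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    }
  }
}
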