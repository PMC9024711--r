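#' Label-encode a feature table
#'
#' Each predictor's categories are mapped to integer codes `0..k-1` in
#' lexicographic category order (e.g. PolyPhen-2 `B=0, D=1, P=2`).
#'
#' @param table a complete-case `"feature_table"`.
#' @return An n x 8 integer matrix with predictor column names; attribute
#'   `encoding_kind = "label"`.
#' @export
encode_label <- function(table) {
  vocab <- predictor_vocabularies()
  preds <- predictor_names()
  n <- nrow(table)
  out <- matrix(0L, n, length(preds), dimnames = list(NULL, preds))
  for (p in preds) {
    code <- match(table[[p]], vocab[[p]]$categories) - 1L
    if (n > 0L && anyNA(code)) {
      stop("missing or unknown call for ", p, "; encode complete cases only",
           call. = FALSE)
    }
    out[, p] <- code
  }
  structure(out, encoding_kind = "label")
}

#' One-hot encode a feature table
#'
#' The indicator matrix of the eight categorical predictors: one binary
#' column per category (23 in total), exactly one 1 per predictor block per
#' row, so every row sums to 8. Column order is predictor order x
#' lexicographic category order, named `<predictor>_<category>`.
#'
#' @param table a complete-case `"feature_table"`.
#' @return An n x 23 binary matrix; attributes `encoding_kind = "onehot"` and
#'   `block` (predictor of each column).
#' @export
encode_onehot <- function(table) {
  vocab <- predictor_vocabularies()
  preds <- predictor_names()
  n <- nrow(table)
  cols <- unlist(lapply(preds, function(p)
    paste(p, vocab[[p]]$categories, sep = "_")))
  block <- unlist(lapply(preds, function(p)
    rep(p, length(vocab[[p]]$categories))))
  out <- matrix(0L, n, length(cols), dimnames = list(NULL, cols))
  if (n > 0L) {
    offset <- 0L
    for (p in preds) {
      k <- length(vocab[[p]]$categories)
      j <- match(table[[p]], vocab[[p]]$categories)
      if (anyNA(j)) {
        stop("missing or unknown call for ", p, "; encode complete cases only",
             call. = FALSE)
      }
      out[cbind(seq_len(n), offset + j)] <- 1L
      offset <- offset + k
    }
  }
  structure(out, encoding_kind = "onehot", block = block)
}
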