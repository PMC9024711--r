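#' Predict pathogenicity for new variants
#'
#' Applies the fitted encoder and forest to a complete-case feature table.
#' RFprob is the fraction of trees voting pathogenic; the predicted label is
#' pathogenic when RFprob >= 0.5 (ties go to pathogenic), and a prediction is
#' high-confidence when RFprob >= `threshold` or RFprob <= 1 - `threshold`.
#'
#' @param object a `"pathometa_model"`.
#' @param newdata a complete-case `"feature_table"` (e.g. the VUS/CI side of
#'   [split_by_role()]).
#' @param threshold high-confidence probability threshold in (0.5, 1\].
#' @param ... unused.
#' @return A `"prediction_result"` data frame: the variant key columns,
#'   `source_label`, `prob_pathogenic`, `predicted_label`,
#'   `high_confidence`.
#' @export
predict.pathometa_model <- function(object, newdata, threshold = 0.9, ...) {
  .check_threshold(threshold)
  stopifnot(inherits(newdata, "feature_table"))
  X <- .apply_encoder(object$encoder, newdata)
  if (ncol(X) != object$d) {
    stop("encoded dimension ", ncol(X), " does not match the fitted model (",
         object$d, "); vocabulary/encoder mismatch", call. = FALSE)
  }
  prob <- if (nrow(newdata) == 0L) numeric(0) else
    unname(stats::predict(object$forest, as.matrix(X), type = "prob")[, "1"])
  out <- data.frame(
    chrom = newdata$chrom, pos = newdata$pos, ref = newdata$ref,
    alt = newdata$alt, rsid = newdata$rsid,
    source_label = if ("label" %in% names(newdata)) newdata$label else NA_character_,
    prob_pathogenic = prob,
    predicted_label = ifelse(prob >= 0.5, "pathogenic", "benign"),
    high_confidence = prob >= threshold | prob <= 1 - threshold,
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("prediction_result", "data.frame")
  out
}

.check_threshold <- function(threshold) {
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0.5 || threshold > 1) {
    stop("threshold must lie in (0.5, 1]", call. = FALSE)
  }
  invisible(threshold)
}

#' High-confidence pathogenic predictions
#'
#' Filters a prediction set to the variants with RFprob at or above the
#' threshold (the boundary value is retained). Counts by source label and
#' predicted label are attached as attribute `"summary"`.
#'
#' @param results a `"prediction_result"` data frame.
#' @param threshold probability threshold in (0.5, 1\].
#' @return The retained rows, with a `"summary"` attribute (data frame of
#'   counts by `source_label`).
#' @examples
#' # probs 0.95, 0.50, 0.91 at threshold 0.9 -> 2 retained
#' @export
high_confidence_set <- function(results, threshold = 0.9) {
  .check_threshold(threshold)
  keep <- results$prob_pathogenic >= threshold
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  counts <- as.data.frame(table(
    source_label = factor(results$source_label[keep]),
    predicted_label = factor(results$predicted_label[keep])),
    stringsAsFactors = FALSE)
  attr(out, "summary") <- counts
  attr(out, "threshold") <- threshold
  out
}

#' Summarize a reclassification run
#'
#' Counts and percentages of pathogenic and benign predictions per source
#' label (VUS / conflicting). Percentages are reported against both the
#' source-label stratum total (`pct_*`) and the overall total
#' (`pct_*_overall`), since published summaries differ in which denominator
#' they use. Strata with zero variants report counts of 0 and `NA`
#' percentages.
#'
#' @param results a `"prediction_result"` data frame.
#' @return A data frame with one row per source label plus a `total` row.
#' @export
summarize_reclassification <- function(results) {
  strata <- c("vus", "conflicting")
  n_total <- nrow(results)
  rows <- lapply(strata, function(s) {
    sub <- results[!is.na(results$source_label) & results$source_label == s, ,
                   drop = FALSE]
    n <- nrow(sub)
    n_path <- sum(sub$predicted_label == "pathogenic")
    n_ben <- n - n_path
    data.frame(
      source_label = s, n = n,
      n_pathogenic = n_path, n_benign = n_ben,
      pct_pathogenic = if (n > 0) 100 * n_path / n else NA_real_,
      pct_benign = if (n > 0) 100 * n_ben / n else NA_real_,
      pct_pathogenic_overall = if (n_total > 0) 100 * n_path / n_total else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(
    source_label = "total", n = n_total,
    n_pathogenic = sum(out$n_pathogenic), n_benign = sum(out$n_benign),
    pct_pathogenic = if (n_total > 0) 100 * sum(out$n_pathogenic) / n_total else NA_real_,
    pct_benign = if (n_total > 0) 100 * sum(out$n_benign) / n_total else NA_real_,
    pct_pathogenic_overall = if (n_total > 0) 100 * sum(out$n_pathogenic) / n_total else NA_real_,
    stringsAsFactors = FALSE)
  rbind(out, total)
}
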