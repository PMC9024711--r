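#' Group raw ClinVar significance strings into four analysis labels
#'
#' ACMG-AMP assertion strings are grouped as: benign / likely benign (and the
#' combined `Benign/Likely_benign`) into `benign`; pathogenic / likely
#' pathogenic into `pathogenic`; `Uncertain_significance` stays `vus`;
#' `Conflicting_interpretations_of_pathogenicity` stays `conflicting`.
#' ClinVar compound strings with comma-joined qualifiers (e.g.
#' `"Pathogenic,_risk_factor"`) map by their leading term. Anything else
#' (e.g. `drug_response`) is unmapped and returned as `NA`.
#'
#' @param clnsig_raw character vector of verbatim `CLNSIG` strings.
#' @return Character vector with values in
#'   `c("benign", "pathogenic", "vus", "conflicting")` or `NA` for unmapped.
#' @examples
#' group_labels(c("Likely_pathogenic", "Benign/Likely_benign", "drug_response"))
#' @export
group_labels <- function(clnsig_raw) {
  lead <- vapply(strsplit(as.character(clnsig_raw), ",", fixed = TRUE),
                 function(x) if (length(x) == 0L) "" else x[[1L]], character(1))
  map <- c(
    Benign = "benign", Likely_benign = "benign", `Benign/Likely_benign` = "benign",
    Pathogenic = "pathogenic", Likely_pathogenic = "pathogenic",
    `Pathogenic/Likely_pathogenic` = "pathogenic",
    Uncertain_significance = "vus",
    Conflicting_interpretations_of_pathogenicity = "conflicting"
  )
  unname(map[lead])
}

#' Filter annotated variants to complete cases
#'
#' Retains variants with a grouped clinical label and all eight predictor
#' calls present — the metapredictor's training and reclassification universe.
#' Duplicate genomic keys keep their first occurrence (avoids train/test
#' leakage). An exclusion report (counts per missing-call pattern, unmapped
#' labels, duplicates) is attached as attribute `"exclusions"`.
#'
#' @param variants annotated-variant data frame.
#' @return A `"feature_table"` data frame: key columns, the eight predictor
#'   call columns, `label`, and (when present in the input) `truth`.
#' @export
filter_complete_cases <- function(variants) {
  preds <- predictor_names()
  df <- as.data.frame(variants, stringsAsFactors = FALSE)
  n_in <- nrow(df)
  label <- if (!is.null(df$clnsig)) group_labels(df$clnsig) else df$label
  if (is.null(label)) stop("variants carry neither clnsig nor label", call. = FALSE)

  key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  dup <- duplicated(key)
  unmapped <- is.na(label)
  calls <- df[, preds, drop = FALSE]
  miss_pattern <- apply(is.na(calls), 1L, function(m)
    if (!any(m)) "complete" else paste(preds[m], collapse = "+"))
  incomplete <- miss_pattern != "complete"

  keep <- !dup & !unmapped & !incomplete
  excl <- table(ifelse(dup, "duplicate_key",
                ifelse(unmapped, "unmapped_label", miss_pattern)))
  excl <- excl[names(excl) != "complete"]
  report <- data.frame(reason = names(excl), n = as.integer(excl),
                       stringsAsFactors = FALSE)

  if (!any(keep)) warning("no complete-case variants retained", call. = FALSE)

  out <- df[keep, c("chrom", "pos", "ref", "alt", "rsid",
                    intersect("clnsig", names(df)), preds,
                    intersect("truth", names(df))), drop = FALSE]
  out$label <- label[keep]
  rownames(out) <- NULL
  attr(out, "exclusions") <- report
  attr(out, "n_input") <- n_in
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x), "complete-case variant(s)\n")
  if (nrow(x)) print(table(label = x$label))
  excl <- attr(x, "exclusions")
  if (!is.null(excl) && nrow(excl)) {
    cat("excluded:", sum(excl$n), "record(s) (see attr(x, \"exclusions\"))\n")
  }
  invisible(x)
}

#' Split a feature table into training and reclassification sets
#'
#' Benign and pathogenic variants form the training set (with `y` binarized,
#' benign = 0, pathogenic = 1); VUS and conflicting-interpretation variants
#' form the reclassification set.
#'
#' @param table a `"feature_table"` from [filter_complete_cases()].
#' @return A list with `train` (feature table restricted to
#'   benign/pathogenic, plus integer column `y`) and `reclass` (vus /
#'   conflicting rows, possibly empty).
#' @export
split_by_role <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  is_train <- table$label %in% c("benign", "pathogenic")
  train <- table[is_train, , drop = FALSE]
  reclass <- table[!is_train, , drop = FALSE]
  if (nrow(train) == 0L || length(unique(train$label)) < 2L) {
    stop("training side is empty or single-class; cannot fit a classifier",
         call. = FALSE)
  }
  train$y <- as.integer(train$label == "pathogenic")
  rownames(train) <- rownames(reclass) <- NULL
  class(train) <- class(reclass) <- c("feature_table", "data.frame")
  list(train = train, reclass = reclass)
}
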