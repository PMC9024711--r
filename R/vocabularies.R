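# Category vocabularies for the eight functional-impact predictors, as emitted
# by SnpSift from dbNSFP `_pred` columns. Codes are case-sensitive single letters.
# LRT includes "D" (deleterious) as defined by dbNSFP even though some summaries
# list only N/U; set `lrt_d = FALSE` in predictor_vocabularies() to exclude it.

.predictor_defs <- list(
  FATHMM           = list(categories = c("D", "T"),           severity = c("D", "T")),
  SIFT             = list(categories = c("D", "T"),           severity = c("D", "T")),
  Polyphen2_HDIV   = list(categories = c("B", "D", "P"),      severity = c("D", "P", "B")),
  Polyphen2_HVAR   = list(categories = c("B", "D", "P"),      severity = c("D", "P", "B")),
  PROVEAN          = list(categories = c("D", "N"),           severity = c("D", "N")),
  MutationAssessor = list(categories = c("H", "L", "M", "N"), severity = c("H", "M", "L", "N")),
  MutationTaster   = list(categories = c("A", "D", "N", "P"), severity = c("A", "D", "N", "P")),
  LRT              = list(categories = c("D", "N", "U"),      severity = c("D", "N", "U"))
)

#' Predictor vocabularies
#'
#' The eight functional-impact predictors used as metapredictor features, each
#' with its closed set of category codes (lexicographic order, used for
#' encoding) and its severity order (most to least severe, used to collapse
#' multi-transcript calls).
#'
#' @param lrt_d logical; keep the "D" (deleterious) category for LRT. dbNSFP
#'   defines it, so it defaults to `TRUE`.
#' @return A named list with one element per predictor, each a list with
#'   `categories` (lexicographic) and `severity` (most severe first).
#' @examples
#' v <- predictor_vocabularies()
#' sum(lengths(lapply(v, `[[`, "categories")))  # 23 categories in total
#' @export
predictor_vocabularies <- function(lrt_d = TRUE) {
  defs <- .predictor_defs
  if (!lrt_d) {
    defs$LRT$categories <- setdiff(defs$LRT$categories, "D")
    defs$LRT$severity <- setdiff(defs$LRT$severity, "D")
  }
  defs
}

#' Names of the eight predictors, in the fixed feature order
#'
#' @return Character vector of length 8 (dbNSFP key spellings).
#' @export
predictor_names <- function() names(.predictor_defs)

# Total category count J across all predictors (23 with the full vocabularies).
vocabulary_size <- function(vocab = predictor_vocabularies()) {
  sum(vapply(vocab, function(v) length(v$categories), integer(1)))
}

#' Collapse multiple transcript-level calls to a single category
#'
#' dbNSFP reports one call per transcript; a variant can therefore carry
#' several categories for one predictor (e.g. `"T,D"` for SIFT). Calls are
#' collapsed to the most severe category under the predictor's severity order,
#' the conservative choice for pathogenicity screening.
#'
#' @param predictor predictor name, one of [predictor_names()].
#' @param values character vector of category codes, all in the predictor's
#'   vocabulary; must be nonempty.
#' @return A single category code.
#' @examples
#' aggregate_multivalue_call("Polyphen2_HVAR", c("B", "P", "D"))  # "D"
#' aggregate_multivalue_call("MutationAssessor", c("L", "M"))     # "M"
#' @export
aggregate_multivalue_call <- function(predictor, values) {
  vocab <- predictor_vocabularies()
  if (!predictor %in% names(vocab)) {
    stop("unknown predictor: ", predictor, call. = FALSE)
  }
  if (length(values) == 0L) {
    stop("aggregate_multivalue_call() requires at least one value", call. = FALSE)
  }
  sev <- vocab[[predictor]]$severity
  bad <- setdiff(values, sev)
  if (length(bad) > 0L) {
    stop("unknown category code(s) for ", predictor, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sev[min(match(values, sev))]
}
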