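#' Read a ClinVar-style VCF with dbNSFP predictor annotations
#'
#' Parses a VCF (plain or bgzipped) whose INFO field carries ClinVar `CLNSIG`
#' and SnpSift/dbNSFP `dbNSFP_<tool>_pred` keys for the eight predictors.
#' Multi-allelic rows are split into one record per ALT allele, each carrying
#' the row's annotations. Multi-transcript values (separated by `,` or `&`)
#' are collapsed to the most severe category via
#' [aggregate_multivalue_call()]; an absent key yields a missing call.
#'
#' @param path VCF file path.
#' @param lrt_d keep LRT's "D" category in the vocabulary (see
#'   [predictor_vocabularies()]).
#' @return An annotated-variant data frame (columns `chrom`, `pos`, `ref`,
#'   `alt`, `rsid`, `clnsig`, and one column per predictor), in input order.
#' @export
read_annotated_vcf <- function(path, lrt_d = TRUE) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    stop("VCF has no data lines: ", path, call. = FALSE)
  }
  vocab <- predictor_vocabularies(lrt_d = lrt_d)
  preds <- predictor_names()

  parse_info <- function(info, key) {
    # value of `key` in each raw INFO string, NA when absent
    m <- regexpr(paste0("(?:^|;)", key, "=([^;]*)"), info)
    out <- rep(NA_character_, length(info))
    hit <- m != -1L
    out[hit] <- sub(paste0("^;?", key, "="), "", regmatches(info, m))
    out
  }

  info <- fix$INFO
  clnsig <- parse_info(info, "CLNSIG")
  clnsig[is.na(clnsig)] <- ""

  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  row_idx <- rep(seq_len(nrow(fix)), n_alt)

  out <- data.frame(
    chrom = fix$CHROM[row_idx],
    pos = as.integer(fix$POS[row_idx]),
    ref = fix$REF[row_idx],
    alt = unlist(alt_list),
    rsid = ifelse(fix$ID[row_idx] %in% c(".", ""), NA_character_, fix$ID[row_idx]),
    clnsig = clnsig[row_idx],
    stringsAsFactors = FALSE
  )

  for (p in preds) {
    raw <- parse_info(info, paste0("dbNSFP_", p, "_pred"))
    call <- rep(NA_character_, length(raw))
    has <- !is.na(raw) & raw != "" & raw != "."
    if (any(has)) {
      call[has] <- vapply(strsplit(raw[has], "[,&]"), function(v) {
        v <- v[v != "" & v != "."]
        if (length(v) == 0L) return(NA_character_)
        bad <- setdiff(v, vocab[[p]]$categories)
        if (length(bad) > 0L) {
          stop("unknown category code(s) for ", p, ": ",
               paste(bad, collapse = ", "), call. = FALSE)
        }
        aggregate_multivalue_call(p, v)
      }, character(1))
    }
    out[[p]] <- call[row_idx]
  }
  class(out) <- c("annotated_variants", "data.frame")
  out
}

#' @export
print.annotated_variants <- function(x, ...) {
  cat("Annotated variants:", nrow(x), "record(s)\n")
  complete <- rowSums(is.na(as.data.frame(x)[, predictor_names(), drop = FALSE])) == 0
  cat("  complete predictor calls:", sum(complete), "\n")
  cat("  CLNSIG values:", paste(utils::head(sort(unique(x$clnsig)), 6), collapse = ", "),
      if (length(unique(x$clnsig)) > 6) "..." else "", "\n")
  invisible(x)
}

#' Write a prediction table to TSV
#'
#' One row per prediction with the variant key, the pathogenic probability
#' (`RFprob`, 4+ decimals), the predicted label and the high-confidence flag.
#' Absent rsids are written as `.`.
#'
#' @param results a prediction-result data frame (see
#'   [predict.pathometa_model()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(results, path) {
  df <- data.frame(
    chrom = results$chrom, pos = results$pos,
    rsid = ifelse(is.na(results$rsid), ".", results$rsid),
    ref = results$ref, alt = results$alt,
    source_label = results$source_label,
    prob_pathogenic = sprintf("%.6f", results$prob_pathogenic),
    predicted_label = results$predicted_label,
    high_confidence = results$high_confidence,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a prediction table written by [write_prediction_table()]
#'
#' @param path TSV path.
#' @return A data frame with `rsid` `"."` restored to `NA` and numeric
#'   probabilities.
#' @export
read_prediction_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(chrom = "character", rsid = "character"),
                          stringsAsFactors = FALSE)
  df$rsid[df$rsid == "."] <- NA_character_
  df$prob_pathogenic <- as.numeric(df$prob_pathogenic)
  df
}
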