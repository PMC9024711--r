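#' Specification for a synthetic annotated-variant set
#'
#' Defines a seeded simulation of ClinVar-style variants with dbNSFP-style
#' categorical predictor calls. Benign and pathogenic strata carry their true
#' label in `CLNSIG`; VUS and conflicting-interpretation (CI) strata get the
#' ClinVar strings `Uncertain_significance` /
#' `Conflicting_interpretations_of_pathogenicity` but keep a hidden
#' ground-truth class so that reclassification can be scored.
#'
#' For a variant whose ground truth is pathogenic, each predictor emits its
#' most severe category with probability `concordance` and otherwise a
#' category drawn uniformly from the remaining ones; for benign ground truth
#' the least severe category plays that role. Each call is then independently
#' replaced by missing with probability `missing_rate`.
#'
#' @param n_benign,n_pathogenic,n_vus,n_ci nonnegative stratum sizes.
#' @param concordance probability in \[0,1\] that a predictor emits its
#'   class-consistent call; either a scalar or a length-8 vector giving one
#'   value per predictor (order of [predictor_names()]), which allows planting
#'   informative predictors among uninformative ones.
#' @param missing_rate probability in \[0,1\] that any single call is missing.
#' @param seed integer seed; the same spec always simulates the same variants.
#' @param chrom_pool contigs to draw positions from.
#' @return An object of class `"synthetic_spec"`.
#' @seealso [simulate_variants()], [write_synthetic_vcf()]
#' @export
synthetic_spec <- function(n_benign = 0L, n_pathogenic = 0L, n_vus = 0L,
                           n_ci = 0L, concordance = 0.9, missing_rate = 0,
                           seed = 1L,
                           chrom_pool = c(as.character(1:22), "X")) {
  counts <- c(n_benign = n_benign, n_pathogenic = n_pathogenic,
              n_vus = n_vus, n_ci = n_ci)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("stratum counts must be nonnegative integers", call. = FALSE)
  }
  q <- length(predictor_names())
  if (!length(concordance) %in% c(1L, q)) {
    stop("concordance must be a scalar or length-", q, " vector", call. = FALSE)
  }
  if (any(!is.finite(concordance)) || any(concordance < 0) || any(concordance > 1)) {
    stop("concordance must lie in [0, 1]", call. = FALSE)
  }
  if (length(missing_rate) != 1L || !is.finite(missing_rate) ||
      missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must be a single probability in [0, 1]", call. = FALSE)
  }
  if (length(chrom_pool) == 0L) stop("chrom_pool must be nonempty", call. = FALSE)
  structure(list(
    n_benign = as.integer(n_benign), n_pathogenic = as.integer(n_pathogenic),
    n_vus = as.integer(n_vus), n_ci = as.integer(n_ci),
    concordance = rep_len(as.numeric(concordance), q),
    missing_rate = as.numeric(missing_rate),
    seed = as.integer(seed), chrom_pool = as.character(chrom_pool)
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic variant spec:",
      x$n_benign, "benign,", x$n_pathogenic, "pathogenic,",
      x$n_vus, "VUS,", x$n_ci, "CI\n")
  cat("  concordance:", paste(format(x$concordance), collapse = " "), "\n")
  cat("  missing rate:", x$missing_rate, " seed:", x$seed, "\n")
  invisible(x)
}

# draw one call for a predictor given the ground-truth class
.draw_calls <- function(vocab_entry, truth_is_path, concordance, n) {
  sev <- vocab_entry$severity
  consistent <- if (truth_is_path) sev[1L] else sev[length(sev)]
  others <- setdiff(sev, consistent)
  hit <- stats::runif(n) < concordance
  out <- character(n)
  out[hit] <- consistent
  if (any(!hit)) out[!hit] <- sample(others, sum(!hit), replace = TRUE)
  out
}

#' Simulate annotated variants from a spec
#'
#' @param spec a [synthetic_spec()].
#' @return A data frame of annotated variants: columns `chrom`, `pos`, `ref`,
#'   `alt`, `rsid`, `clnsig`, one column per predictor (category code or `NA`
#'   for missing), and `truth` — the hidden ground-truth class
#'   (`"benign"`/`"pathogenic"`), used only for simulation scoring and never
#'   written to VCF.
#' @examples
#' v <- simulate_variants(synthetic_spec(n_benign = 3, n_pathogenic = 2,
#'                                       concordance = 1, seed = 1))
#' nrow(v)  # 5
#' @export
simulate_variants <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_benign + spec$n_pathogenic + spec$n_vus + spec$n_ci
  if (n == 0L) stop("spec describes zero variants", call. = FALSE)
  vocab <- predictor_vocabularies()
  preds <- predictor_names()

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  clnsig <- rep(c("Benign", "Pathogenic", "Uncertain_significance",
                  "Conflicting_interpretations_of_pathogenicity"),
                times = c(spec$n_benign, spec$n_pathogenic, spec$n_vus, spec$n_ci))
  # hidden ground truth: benign/pathogenic strata keep their own; VUS/CI are
  # split 50:50 at random so recovery can be scored on both classes
  truth <- rep(c("benign", "pathogenic"),
               times = c(spec$n_benign, spec$n_pathogenic))
  truth <- c(truth, sample(c("benign", "pathogenic"),
                           spec$n_vus + spec$n_ci, replace = TRUE))

  # genomic keys: per-contig collision-free positions, ref != alt
  chrom <- sample(spec$chrom_pool, n, replace = TRUE)
  pos <- integer(n)
  for (ctg in unique(chrom)) {
    idx <- which(chrom == ctg)
    pos[idx] <- sort(sample.int(10000000L, length(idx)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
                    rsid = NA_character_, clnsig = clnsig,
                    stringsAsFactors = FALSE)
  is_path <- truth == "pathogenic"
  for (i in seq_along(preds)) {
    calls <- character(n)
    if (any(is_path)) {
      calls[is_path] <- .draw_calls(vocab[[preds[i]]], TRUE,
                                    spec$concordance[i], sum(is_path))
    }
    if (any(!is_path)) {
      calls[!is_path] <- .draw_calls(vocab[[preds[i]]], FALSE,
                                     spec$concordance[i], sum(!is_path))
    }
    if (spec$missing_rate > 0) {
      calls[stats::runif(n) < spec$missing_rate] <- NA_character_
    }
    out[[preds[i]]] <- calls
  }
  out$truth <- truth
  class(out) <- c("annotated_variants", "data.frame")
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write annotated variants to a VCF 4.2 file
#'
#' Emits a minimal VCF with `CLNSIG` and the eight `dbNSFP_<tool>_pred` INFO
#' keys; missing calls simply omit the key. Output is byte-deterministic, and
#' [read_annotated_vcf()] recovers the call map and `CLNSIG` losslessly. The
#' hidden `truth` column of synthetic sets is intentionally not written.
#'
#' @param variants an annotated-variant data frame ([simulate_variants()] or
#'   [read_annotated_vcf()] output); must be nonempty.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_synthetic_vcf <- function(variants, path) {
  if (nrow(variants) == 0L) stop("no variants to write", call. = FALSE)
  preds <- predictor_names()
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pathometa-synthetic",
    "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
    sprintf("##INFO=<ID=dbNSFP_%s_pred,Number=.,Type=Character,Description=\"%s prediction\">",
            preds, preds),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- paste0("CLNSIG=", variants$clnsig)
  for (p in preds) {
    calls <- variants[[p]]
    has <- !is.na(calls)
    info[has] <- paste0(info[has], ";dbNSFP_", p, "_pred=", calls[has])
  }
  id <- ifelse(is.na(variants$rsid), ".", variants$rsid)
  lines <- paste(variants$chrom, variants$pos, id, variants$ref, variants$alt,
                 ".", ".", info, sep = "\t")
  con <- file(path, open = "wb")  # binary mode: fixed \n line endings
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}
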