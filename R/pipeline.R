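#' Run the full metaprediction pipeline from one configuration
#'
#' Orchestrates simulate (or ingest) -> preprocess -> grid-search training ->
#' reclassification, writing stage outputs and a run manifest under
#' `out_dir`. Rerunning the same configuration reproduces the manifest's
#' counts and selected model exactly.
#'
#' @param config a named list, or the path of a YAML file holding one, with
#'   elements:
#'   \describe{
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{vcf}{path of an annotated VCF to ingest, \emph{or}}
#'     \item{synthetic}{list of [synthetic_spec()] arguments to simulate.}
#'     \item{seed}{global seed, propagated to every stochastic stage.}
#'     \item{encodings}{encodings searched (default `"onehot"` and `"label"`).}
#'     \item{tree_grid, mtry_grid}{forest grids (see [grid_search()]).}
#'     \item{cv_folds}{CV folds (default 10).}
#'     \item{threshold}{high-confidence RFprob threshold (default 0.9).}
#'   }
#' @return The manifest, invisibly: a list of per-stage counts, the selected
#'   model configuration, seeds and output paths (also written as
#'   `manifest.yaml`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  threshold <- if (is.null(config$threshold)) 0.9 else config$threshold
  encodings <- if (is.null(config$encodings)) c("onehot", "label") else config$encodings
  tree_grid <- if (is.null(config$tree_grid)) c(100L, 300L) else as.integer(config$tree_grid)
  cv_folds <- if (is.null(config$cv_folds)) 10L else as.integer(config$cv_folds)

  # stage 1: obtain annotated variants
  if (!is.null(config$vcf)) {
    if (!file.exists(config$vcf)) {
      stop("stage ingest: VCF not found: ", config$vcf, call. = FALSE)
    }
    vcf_path <- config$vcf
  } else if (!is.null(config$synthetic)) {
    spec <- do.call(synthetic_spec, c(config$synthetic, list(seed = seed)))
    variants <- simulate_variants(spec)
    vcf_path <- file.path(out_dir, "synthetic.vcf")
    write_synthetic_vcf(variants, vcf_path)
  } else {
    stop("config needs either $vcf or $synthetic", call. = FALSE)
  }
  variants <- read_annotated_vcf(vcf_path)
  n_ingested <- nrow(variants)

  # stage 2: preprocess
  tab <- filter_complete_cases(variants)
  excl <- attr(tab, "exclusions")
  utils::write.table(excl, file.path(out_dir, "exclusions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  roles <- split_by_role(tab)

  # stage 3: grid-search training
  gs <- grid_search(roles$train, encodings = encodings, tree_grid = tree_grid,
                    mtry_grid = config$mtry_grid, k = cv_folds, seed = seed)
  utils::write.table(gs$entries, file.path(out_dir, "grid_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 4: reclassification
  n_reclass <- nrow(roles$reclass)
  if (n_reclass > 0L) {
    preds <- predict(gs$best_model, roles$reclass, threshold = threshold)
    write_prediction_table(preds, file.path(out_dir, "predictions.tsv"))
    summ <- summarize_reclassification(preds)
    utils::write.table(summ, file.path(out_dir, "reclass_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n_high_conf <- nrow(high_confidence_set(preds, threshold))
  } else {
    n_high_conf <- 0L
  }

  b <- gs$entries[gs$best, ]
  manifest <- list(
    pathometa_version = as.character(utils::packageVersion("pathometa")),
    seed = seed,
    input_vcf = vcf_path,
    counts = list(
      ingested = n_ingested,
      complete_case = nrow(tab),
      excluded = n_ingested - nrow(tab),
      train = nrow(roles$train),
      reclassified = n_reclass,
      high_confidence_pathogenic = n_high_conf
    ),
    selected_model = list(
      encoding = b$encoding, ntree = b$ntree, mtry = b$mtry,
      cv_auc = b$cv_auc, oob_error = b$oob_error
    ),
    grids = list(encodings = encodings, tree_grid = tree_grid,
                 cv_folds = cv_folds, threshold = threshold)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
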