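#' Default mtry grid for a feature dimension
#'
#' `{2, floor(sqrt(d)), floor(d/2), d}`, clipped to `[1, d]`, deduplicated
#' and sorted. For the 23-column one-hot matrix this is `{2, 4, 11, 23}`.
#'
#' @param d number of encoded features.
#' @return Integer vector of candidate `mtry` values.
#' @export
default_mtry_grid <- function(d) {
  sort(unique(pmax(1L, pmin(as.integer(d),
    c(2L, floor(sqrt(d)), floor(d / 2), as.integer(d))))))
}

#' Grid-search tuning of the random-forest metapredictor
#'
#' Evaluates every combination of feature representation, autoencoder
#' hyperparameters (for the autoencoder representation), number of trees and
#' `mtry`. Each cell is scored by stratified k-fold cross-validated AUC
#' ([kfold_auc()]) and by the OOB error of a forest grown on all training
#' rows. The best cell maximizes AUC; ties are broken by lower OOB error,
#' then fewer trees, then smaller `mtry`. The winning configuration is
#' refitted on the full training table and returned as `best_model`.
#'
#' Unsupervised encoders (MCA, autoencoder) are fitted once on the full
#' training table before cross-validating the forest; labels play no part in
#' the encoders, so no label information leaks across folds.
#'
#' @param table training `"feature_table"`.
#' @param encodings subset of `c("label", "onehot", "mca", "autoencoder")`.
#' @param tree_grid numbers of trees (default `seq(50, 1000, by = 50)`).
#' @param mtry_grid candidate `mtry` values, or `NULL` for
#'   [default_mtry_grid()] per encoding dimension.
#' @param ae_configs list of [autoencoder_config()]s tried for the
#'   autoencoder representation.
#' @param k CV folds.
#' @param seed master seed; every cell derives its own fixed sub-seed, so the
#'   whole search is reproducible.
#' @return An object of class `"pathometa_grid"`: `entries` (one row per
#'   cell: encoding, hidden units/activation/epochs where relevant, ntree,
#'   mtry, cv_auc, cv_sd, oob_error), `best` (row index), `best_model`
#'   (a `"pathometa_model"`).
#' @export
grid_search <- function(table,
                        encodings = c("onehot", "label", "mca", "autoencoder"),
                        tree_grid = seq(50L, 1000L, by = 50L),
                        mtry_grid = NULL,
                        ae_configs = list(autoencoder_config()),
                        k = 10L, seed = 1L) {
  encodings <- match.arg(encodings, several.ok = TRUE)
  if (length(tree_grid) == 0L) stop("empty tree grid", call. = FALSE)
  y <- if ("y" %in% names(table)) table$y else as.integer(table$label == "pathogenic")

  entries <- list()
  states <- list()
  cell <- 0L
  for (enc in encodings) {
    configs <- if (enc == "autoencoder") ae_configs else list(NULL)
    for (ci in seq_along(configs)) {
      cfg <- configs[[ci]]
      state_id <- paste0(enc, ci)
      states[[state_id]] <- .fit_encoder(table, enc, cfg)
      X <- states[[state_id]]$X
      mg <- if (is.null(mtry_grid)) default_mtry_grid(ncol(X)) else
        sort(unique(pmax(1L, pmin(ncol(X), as.integer(mtry_grid)))))
      for (ntree in tree_grid) for (mtry in mg) {
        cell <- cell + 1L
        cell_seed <- (seed * 1000L + cell) %% .Machine$integer.max
        ev <- kfold_auc(X, y, ntree = ntree, mtry = mtry, k = k, seed = cell_seed)
        oob <- .rf_oob(X, y, ntree, mtry, cell_seed)
        entries[[cell]] <- data.frame(
          encoding = enc,
          hidden_units = if (is.null(cfg)) NA_integer_ else cfg$hidden_units,
          activation = if (is.null(cfg)) NA_character_ else cfg$activation,
          epochs = if (is.null(cfg)) NA_integer_ else cfg$epochs,
          ntree = as.integer(ntree), mtry = as.integer(mtry),
          cv_auc = ev$auc, cv_sd = ev$sd, oob_error = oob,
          state_id = state_id, cell_seed = cell_seed,
          stringsAsFactors = FALSE)
      }
    }
  }
  entries <- do.call(rbind, entries)
  ord <- order(-entries$cv_auc, entries$oob_error, entries$ntree, entries$mtry)
  best <- ord[1L]

  b <- entries[best, ]
  best_cfg <- if (b$encoding == "autoencoder") {
    ae_configs[[as.integer(sub("^autoencoder", "", b$state_id))]]
  } else NULL
  best_model <- pathometa_fit(table, encoding = b$encoding, ntree = b$ntree,
                              mtry = b$mtry, seed = b$cell_seed,
                              ae_config = best_cfg)

  structure(list(entries = entries[, setdiff(names(entries), "state_id")],
                 best = best, best_model = best_model, k = k, seed = seed),
            class = "pathometa_grid")
}

.rf_oob <- function(X, y, ntree, mtry, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = as.matrix(X), y = factor(y, levels = c(0L, 1L)),
    ntree = as.integer(ntree), mtry = min(as.integer(mtry), ncol(X)))
  unname(rf$err.rate[nrow(rf$err.rate), "OOB"])
}

#' @export
print.pathometa_grid <- function(x, ...) {
  cat("Grid search:", nrow(x$entries), "configurations,",
      x$k, "-fold CV\n", sep = " ")
  b <- x$entries[x$best, ]
  cat(sprintf("Best: %s encoding, %d trees, mtry %d -> CV AUC %.4f, OOB error %.4f\n",
              b$encoding, b$ntree, b$mtry, b$cv_auc, b$oob_error))
  invisible(x)
}

#' @export
summary.pathometa_grid <- function(object, ...) {
  print(object)
  e <- object$entries
  agg <- aggregate(cv_auc ~ encoding, data = e,
                   FUN = function(v) c(min = min(v), max = max(v)))
  cat("\nCV AUC range per encoding:\n")
  print(cbind(encoding = agg$encoding, round(agg$cv_auc, 4)))
  invisible(object)
}

#' @export
plot.pathometa_grid <- function(x, ...) {
  e <- x$entries
  encs <- unique(e$encoding)
  cols <- seq_along(encs)
  agg <- aggregate(cv_auc ~ encoding + ntree, data = e, FUN = max)
  graphics::plot(range(agg$ntree), range(agg$cv_auc), type = "n",
                 xlab = "number of trees", ylab = "best CV AUC",
                 main = "Grid search: AUC vs forest size", ...)
  for (i in seq_along(encs)) {
    sub <- agg[agg$encoding == encs[i], ]
    sub <- sub[order(sub$ntree), ]
    graphics::lines(sub$ntree, sub$cv_auc, col = cols[i], type = "b", pch = 19)
  }
  graphics::legend("bottomright", legend = encs, col = cols, lty = 1, pch = 19)
  invisible(x)
}
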