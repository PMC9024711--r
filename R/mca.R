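#' Multiple correspondence analysis of an indicator matrix
#'
#' Correspondence analysis of the one-hot (indicator) matrix Z of the eight
#' categorical predictors, retaining the first two dimensions as a
#' low-dimensional numeric representation. With n rows, Q variables and J
#' categories, the correspondence matrix is `P = Z/(nQ)`, row masses are
#' `r = 1/n`, column masses `c = colSums(P)`, and the matrix of standardized
#' residuals `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` carries total inertia
#' `(J - Q)/Q` (1.875 for the full 23-category, 8-predictor vocabularies).
#' No Benzecri/Greenacre eigenvalue correction is applied.
#'
#' Internally the category axes are obtained from the eigendecomposition of
#' the J x J cross-product `S'S`; row principal coordinates then follow from
#' the transition formula `f_i = (z_i/Q - c)' D_c^{-1/2} V`, which also maps
#' new (out-of-sample) rows. The per-axis sign is fixed by forcing the
#' largest-magnitude category loading positive.
#'
#' @param onehot an indicator matrix from [encode_onehot()] with at least 3
#'   distinct rows. Categories never observed in the data are dropped (with a
#'   warning), which lowers J and hence the total inertia.
#' @return An object of class `"mca_model"`: `category_masses`,
#'   `singular_values` (all positive ones, non-increasing), `principal_axes`
#'   (J x 2 matrix V), `retained_dims = 2`, `total_inertia`, `n`, `q`,
#'   `columns` (retained category names).
#' @seealso [transform_mca()]
#' @export
fit_mca <- function(onehot) {
  z <- as.matrix(onehot)
  n <- nrow(z)
  if (n < 3L || nrow(unique(z)) < 3L) {
    stop("MCA requires at least 3 distinct rows", call. = FALSE)
  }
  q <- length(unique(attr(onehot, "block")))
  if (length(q) == 0L || q == 0L) q <- length(predictor_names())

  cmass <- colSums(z) / (n * q)
  present <- cmass > 0
  if (!all(present)) {
    warning("dropping ", sum(!present), " never-observed categor",
            if (sum(!present) == 1L) "y" else "ies", call. = FALSE)
    z <- z[, present, drop = FALSE]
    cmass <- cmass[present]
  }
  j <- ncol(z)

  # standardized residuals S = D_r^-1/2 (P - r c') D_c^-1/2 with r_i = 1/n:
  # S = (Z/(nQ) - c'/n) * sqrt(n) / sqrt(c), columnwise
  s <- sweep(z / (n * q), 2L, cmass / n, `-`) * sqrt(n)
  s <- sweep(s, 2L, sqrt(cmass), `/`)

  eig <- eigen(crossprod(s), symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  pos <- ev > max(ev) * 1e-12
  if (sum(pos) < 2L) {
    stop("fewer than 2 positive singular values; data are degenerate",
         call. = FALSE)
  }
  sv <- sqrt(ev[pos])
  v <- eig$vectors[, pos, drop = FALSE]
  # deterministic axis orientation: largest-magnitude loading positive
  for (k in seq_len(ncol(v))) {
    i <- which.max(abs(v[, k]))
    if (v[i, k] < 0) v[, k] <- -v[, k]
  }
  rownames(v) <- colnames(z)

  structure(list(
    category_masses = cmass,
    singular_values = sv,
    principal_axes = v[, 1:2, drop = FALSE],
    retained_dims = 2L,
    total_inertia = sum(ev[pos]),
    n = n, q = q, columns = colnames(z)
  ), class = "mca_model")
}

#' @export
print.mca_model <- function(x, ...) {
  cat("MCA model:", length(x$columns), "categories,", x$q, "variables, n =", x$n, "\n")
  cat("  total inertia:", format(x$total_inertia), "\n")
  expl <- x$singular_values[1:2]^2 / x$total_inertia
  cat("  first two dimensions explain",
      paste0(format(100 * expl, digits = 3), "%", collapse = " + "), "of inertia\n")
  invisible(x)
}

#' Project indicator rows onto the first two MCA dimensions
#'
#' Row principal coordinates via the transition formula from the fitted
#' category axes; works identically for the training rows and new rows.
#'
#' @param model an `"mca_model"` from [fit_mca()].
#' @param onehot indicator matrix with the same 23 columns as at fit time.
#' @return An n x 2 numeric matrix (columns `MCA1`, `MCA2`); attribute
#'   `encoding_kind = "mca"`.
#' @export
transform_mca <- function(model, onehot) {
  stopifnot(inherits(model, "mca_model"))
  z <- as.matrix(onehot)
  missing_cols <- setdiff(model$columns, colnames(z))
  if (length(missing_cols) > 0L) {
    stop("indicator matrix lacks fitted categories: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  z <- z[, model$columns, drop = FALSE]
  profile <- z / model$q
  b <- sweep(model$principal_axes, 1L, sqrt(model$category_masses), `/`)
  coords <- sweep(profile, 2L, model$category_masses, `-`) %*% b
  colnames(coords) <- c("MCA1", "MCA2")
  structure(coords, encoding_kind = "mca")
}
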