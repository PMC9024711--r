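# Shared fixtures: everything is generated in code, seeded.

# balanced benign/pathogenic training table
make_train_table <- function(n_per_class, concordance = 0.9, seed = 1,
                             missing_rate = 0) {
  spec <- synthetic_spec(n_benign = n_per_class, n_pathogenic = n_per_class,
                         concordance = concordance,
                         missing_rate = missing_rate, seed = seed)
  split_by_role(filter_complete_cases(simulate_variants(spec)))$train
}

# per-predictor concordance vector that makes every call uniform over its
# categories (class-independent noise)
uninformative_concordance <- function() {
  vapply(predictor_vocabularies(), function(v) 1 / length(v$categories),
         numeric(1))
}

# Literal-definition MCA oracle: assemble S from P, r, c and take a dense SVD;
# returns row principal coordinates (first two axes) and singular values.
mca_oracle <- function(z, q = 8) {
  z <- as.matrix(z)
  n <- nrow(z)
  P <- z / (n * q)
  r <- rowSums(P)
  cc <- colSums(P)
  keep <- cc > 0
  P <- P[, keep, drop = FALSE]; cc <- cc[keep]
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  list(coords = (diag(1 / sqrt(r)) %*% sv$u %*% diag(sv$d))[, 1:2, drop = FALSE],
       singular_values = sv$d)
}

# sign-invariant per-axis comparison
expect_axes_equal <- function(a, b, tol = 1e-8) {
  for (k in seq_len(ncol(a))) {
    d <- min(max(abs(a[, k] - b[, k])), max(abs(a[, k] + b[, k])))
    expect_lt(d, tol)
  }
}

# random complete-case table over arbitrary small category draws
random_toy_table <- function(n, seed) {
  set.seed(seed)
  vocab <- predictor_vocabularies()
  df <- data.frame(chrom = "1", pos = seq_len(n), ref = "A", alt = "C",
                   rsid = NA_character_, stringsAsFactors = FALSE)
  for (p in names(vocab)) {
    df[[p]] <- sample(vocab[[p]]$categories, n, replace = TRUE)
  }
  df$label <- sample(c("benign", "pathogenic"), n, replace = TRUE)
  class(df) <- c("feature_table", "data.frame")
  df
}
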