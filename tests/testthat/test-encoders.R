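test_that("label encoding maps categories lexicographically to 0..k-1", {
  tab <- random_toy_table(30, seed = 1)
  L <- encode_label(tab)
  expect_equal(dim(L), c(30L, 8L))
  expect_equal(unname(L[, "FATHMM"]), match(tab$FATHMM, c("D", "T")) - 1L)
  expect_equal(unname(L[, "Polyphen2_HDIV"]),
               match(tab$Polyphen2_HDIV, c("B", "D", "P")) - 1L)
  # identical rows get identical code vectors
  tab2 <- tab[c(1, 1), ]; class(tab2) <- class(tab)
  L2 <- encode_label(tab2)
  expect_equal(L2[1, ], L2[2, ])
})

test_that("one-hot encoding is 23-dimensional with one 1 per block", {
  tab <- random_toy_table(50, seed = 2)
  Z <- encode_onehot(tab)
  expect_equal(ncol(Z), 23L)
  expect_true(all(Z %in% c(0L, 1L)))
  expect_true(all(rowSums(Z) == 8))
  blocks <- attr(Z, "block")
  for (p in predictor_names()) {
    expect_true(all(rowSums(Z[, blocks == p, drop = FALSE]) == 1))
  }
  expect_equal(unname(Z[, "SIFT_D"]), as.integer(tab$SIFT == "D"))
  # empty table -> 0 x 23
  empty <- tab[0, ]; class(empty) <- class(tab)
  expect_equal(dim(encode_onehot(empty)), c(0L, 23L))
})

test_that("argmax per one-hot block recovers the label codes", {
  tab <- random_toy_table(40, seed = 3)
  Z <- encode_onehot(tab)
  L <- encode_label(tab)
  blocks <- attr(Z, "block")
  for (p in predictor_names()) {
    codes <- apply(Z[, blocks == p, drop = FALSE], 1L, which.max) - 1L
    expect_equal(codes, unname(L[, p]))
  }
})

test_that("MCA matches the literal-definition SVD oracle on random tables", {
  for (seed in 1:20) {
    n <- sample(10:40, 1)
    tab <- random_toy_table(n, seed = seed)
    Z <- encode_onehot(tab)
    fit <- suppressWarnings(fit_mca(Z))
    oracle <- mca_oracle(Z)
    co <- suppressWarnings(transform_mca(fit, Z))
    expect_axes_equal(co, oracle$coords, tol = 1e-8)
    expect_equal(fit$singular_values[1:2], oracle$singular_values[1:2],
                 tolerance = 1e-8)
  }
})

test_that("MCA total inertia equals (J - Q)/Q and Parseval holds", {
  # force every one of the 23 categories to be observed
  vocab <- predictor_vocabularies()
  base <- random_toy_table(200, seed = 5)
  for (p in names(vocab)) {
    k <- length(vocab[[p]]$categories)
    base[[p]][seq_len(k)] <- vocab[[p]]$categories
  }
  fit <- fit_mca(encode_onehot(base))
  expect_equal(fit$total_inertia, (23 - 8) / 8, tolerance = 1e-12)
  expect_equal(fit$total_inertia, 15 / 8)
  expect_equal(sum(fit$singular_values^2), fit$total_inertia, tolerance = 1e-10)
})

test_that("MCA transform is deterministic and respects duplicates", {
  tab <- random_toy_table(25, seed = 6)
  dup <- tab[c(1:25, 1), ]; class(dup) <- class(tab)
  Z <- encode_onehot(dup)
  fit <- suppressWarnings(fit_mca(Z))
  co <- suppressWarnings(transform_mca(fit, Z))
  expect_equal(co[26, ], co[1, ])
  expect_error(fit_mca(encode_onehot(tab[c(1, 1, 1), ])), "3 distinct")
})

test_that("autoencoder training reduces reconstruction loss deterministically", {
  tab <- random_toy_table(500, seed = 7)
  Z <- encode_onehot(tab)
  for (act in c("rectifier", "rectifier_dropout", "tanh")) {
    cfg <- autoencoder_config(hidden_units = 10L, activation = act,
                              epochs = 10L, seed = 0L)
    ae <- fit_autoencoder(Z, cfg)
    lh <- ae$loss_history
    expect_lt(lh[length(lh)], lh[1])    # final loss < loss at initialization
    rep1 <- transform_autoencoder(ae, Z)
    expect_equal(dim(rep1), c(500L, 2L))
    ae2 <- fit_autoencoder(Z, cfg)
    expect_identical(rep1, transform_autoencoder(ae2, Z))  # same config+seed
  }
})

test_that("autoencoder separates the two pure class patterns", {
  # concordance 1 yields exactly two distinct one-hot rows
  tab <- make_train_table(50, concordance = 1, seed = 12)
  Z <- encode_onehot(tab)
  ae <- fit_autoencoder(Z, autoencoder_config(hidden_units = 20L, epochs = 30L,
                                              activation = "tanh", seed = 0L))
  rep <- transform_autoencoder(ae, Z)
  y <- tab$y
  centers <- rbind(colMeans(rep[y == 0, , drop = FALSE]),
                   colMeans(rep[y == 1, , drop = FALSE]))
  between <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  within <- max(sd(rep[y == 0, 1]), sd(rep[y == 1, 1]),
                sd(rep[y == 0, 2]), sd(rep[y == 1, 2]), 0)
  expect_gt(between, within)
})

test_that("autoencoder config enumerations are enforced", {
  expect_error(autoencoder_config(hidden_units = 15), "10, 20, 30")
  expect_error(autoencoder_config(epochs = 5), "10, 20, 30")
  expect_error(autoencoder_config(dropout_rate = 1), "\\[0, 1\\)")
  expect_error(autoencoder_config(learning_rate = 0), "positive")
})
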