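test_that("AUC equals the exhaustive concordant-pair count on small score sets", {
  pair_auc <- function(s, y) {
    # Mann-Whitney identity: concordant pairs + half ties
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(42)
  for (i in 1:5) {
    y <- c(rep(0, 10), rep(1, 10))
    s <- round(runif(20), 2)   # rounding forces ties
    expect_equal(roc_auc(s, y), pair_auc(s, y), tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(7)
  y <- rbinom(50, 1, 0.5); s <- rnorm(50)
  a <- roc_auc(s, y)
  expect_equal(roc_auc(exp(s), y), a)
  expect_equal(roc_auc(qlogis(plogis(s)), y), a, tolerance = 1e-12)
  expect_equal(roc_auc(rank(s), y), a)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  y <- rbinom(80, 1, 0.5); s <- rnorm(80) + y
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("a separable forest has near-zero OOB error and exact vote probabilities", {
  tab <- make_train_table(100, concordance = 1, seed = 0)
  fit <- pathometa_fit(tab, "onehot", ntree = 100, mtry = 2, seed = 0)
  expect_lte(fit$oob_error, 0.02)
  p <- predict(fit, tab)
  # unanimous trees give exact 0/1 vote fractions
  expect_true(all(p$prob_pathogenic %in% c(0, 1)))
  expect_equal(p$predicted_label, ifelse(tab$y == 1, "pathogenic", "benign"))
})

test_that("permuted labels give null AUC around 0.5", {
  tab <- make_train_table(250, concordance = 0.9, seed = 1)
  X <- encode_onehot(tab)
  set.seed(5)
  y_perm <- sample(tab$y)
  ev <- kfold_auc(X, y_perm, ntree = 100, mtry = 2, k = 5, seed = 2)
  expect_gt(ev$auc, 0.40)
  expect_lt(ev$auc, 0.60)
})

test_that("single-class training data is rejected", {
  tab <- make_train_table(20, seed = 3)
  tab$y <- 1L; tab$label <- "pathogenic"
  expect_error(pathometa_fit(tab, "onehot"), "per class")
})

test_that("default mtry grid follows {2, sqrt(d), d/2, d} with floors", {
  expect_equal(default_mtry_grid(23), c(2L, 4L, 11L, 23L))
  expect_equal(default_mtry_grid(8), c(2L, 4L, 8L))
  expect_equal(default_mtry_grid(2), c(1L, 2L))
})

test_that("grid search is deterministic and ranks by AUC with tie-breaks", {
  tab <- make_train_table(60, concordance = 0.85, seed = 4)
  run <- function() grid_search(tab, encodings = "onehot",
                                tree_grid = c(50L, 100L),
                                mtry_grid = c(2L, 4L), k = 5L, seed = 9)
  g1 <- run(); g2 <- run()
  expect_equal(nrow(g1$entries), 4L)
  expect_identical(g1$entries, g2$entries)
  expect_identical(g1$best, g2$best)
  b <- g1$entries[g1$best, ]
  expect_equal(b$cv_auc, max(g1$entries$cv_auc))
  expect_error(grid_search(tab, encodings = "onehot", tree_grid = integer(0)),
               "empty")
})

test_that("Gini importance is normalized and recovers a planted predictor", {
  conc <- uninformative_concordance()
  conc[which(predictor_names() == "PROVEAN")] <- 0.9
  spec <- synthetic_spec(n_benign = 500, n_pathogenic = 500,
                         concordance = conc, seed = 0)
  tab <- split_by_role(filter_complete_cases(simulate_variants(spec)))$train
  fit <- pathometa_fit(tab, "onehot", ntree = 200, mtry = 4, seed = 0)
  imp <- gini_importance(fit)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_equal(names(which.max(imp$importance)), "PROVEAN")
  # label-encoded model reports per-predictor importance directly
  fitl <- pathometa_fit(tab, "label", ntree = 200, mtry = 2, seed = 0)
  impl <- gini_importance(fitl)
  expect_equal(sum(impl$importance), 1, tolerance = 1e-9)
  expect_equal(names(which.max(impl$importance)), "PROVEAN")
})

test_that("baselines separate a strong-signal toy and approach the Bayes AUC", {
  tab <- make_train_table(150, concordance = 0.95, seed = 6)
  X <- encode_onehot(tab)
  for (kind in c("naive_bayes", "svm_linear", "svm_rbf")) {
    bl <- train_baseline(X, tab$y, kind, k = 5, seed = 1)
    expect_gte(bl$evaluation$auc, 0.95)
  }

  # NB on class-conditionally independent calls approaches the generator's
  # Bayes-optimal AUC (closed-form likelihood ratio as oracle)
  conc <- 0.65
  tab2 <- make_train_table(1000, concordance = conc, seed = 17)
  vocab <- predictor_vocabularies()
  loglr <- rep(0, nrow(tab2))
  for (p in predictor_names()) {
    sev <- vocab[[p]]$severity; k <- length(sev)
    p_path <- ifelse(tab2[[p]] == sev[1], conc, (1 - conc) / (k - 1))
    p_ben <- ifelse(tab2[[p]] == sev[k], conc, (1 - conc) / (k - 1))
    loglr <- loglr + log(p_path) - log(p_ben)
  }
  bayes_auc <- roc_auc(loglr, tab2$y)
  nb <- train_baseline(encode_onehot(tab2), tab2$y, "naive_bayes", k = 10, seed = 2)
  expect_lt(abs(nb$evaluation$auc - bayes_auc), 0.03)
})

test_that("best-model AUC increases with generator concordance", {
  aucs <- vapply(c(0.6, 0.75, 0.9), function(conc) {
    tab <- make_train_table(300, concordance = conc, seed = 23)
    kfold_auc(encode_onehot(tab), tab$y, ntree = 100, mtry = 4,
              k = 5, seed = 3)$auc
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})
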