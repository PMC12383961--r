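make_labels <- function(n_per_group = 20) {
  factor(rep(c("NO", "preAD"), each = n_per_group), levels = c("NO", "preAD"))
}

test_that("splits are group-matched, disjoint and reproducible", {
  labels <- make_labels(20)
  plans <- make_splits(labels, n_rounds = 10, seed = 3)
  expect_length(plans, 10)
  for (p in plans) {
    expect_length(p$test, 6)
    expect_length(p$train, 34)
    expect_length(intersect(p$train, p$test), 0)
    expect_setequal(c(p$train, p$test), seq_along(labels))
    expect_equal(as.vector(table(labels[p$test])), c(3, 3))
  }
  expect_identical(plans, make_splits(labels, n_rounds = 10, seed = 3))
  expect_false(identical(plans, make_splits(labels, n_rounds = 10, seed = 4)))
  expect_length(make_splits(labels, n_rounds = 1, seed = 1), 1)
  expect_error(make_splits(make_labels(1), test_frac = 0.9), "training")
})

test_that("t-test selection finds discriminative features and skips constants", {
  set.seed(5)
  labels <- make_labels(10)
  X <- matrix(rnorm(20 * 50), nrow = 20)
  colnames(X) <- sprintf("Fz|raw|AN|f%02d", 1:50)
  X[, 1] <- 7                                    # constant everywhere
  X[, 2] <- as.integer(labels == "preAD") + rnorm(20, 0, 1e-6)  # label + tiny noise
  sel <- ttest_select(X, labels)
  expect_false(sel$mask[1])
  expect_equal(sel$p[[1]], 1)
  expect_true(sel$mask[2])
  expect_lt(sel$p[[2]], 1e-6)
  # agreement with stats::t.test on a regular column
  ref <- t.test(X[labels == "NO", 3], X[labels == "preAD", 3],
                var.equal = TRUE)$p.value
  expect_equal(sel$p[[3]], ref)
  ref_w <- t.test(X[labels == "NO", 3], X[labels == "preAD", 3])$p.value
  expect_equal(ttest_select(X, labels, var_equal = FALSE)$p[[3]], ref_w)
  expect_error(ttest_select(X[1:3, ], factor(c("NO", "NO", "preAD"))), "2 training")
})

test_that("selection under permuted labels is calibrated at alpha", {
  set.seed(17)
  n_feat <- 4000
  rates <- vapply(1:5, function(r) {
    X <- matrix(rnorm(30 * n_feat), nrow = 30)
    colnames(X) <- paste0("c|b|k|f", seq_len(n_feat))
    labels <- sample(make_labels(15))
    mean(ttest_select(X, labels, alpha = 0.01)$mask)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.01),
            3 * sqrt(0.01 * 0.99 / (5 * n_feat)) + 0.002)
})

test_that("selection marginals cross-foot to the same total", {
  spec <- tiny_spec(n_per_group = 4, effect_size = 0.9, noise_sd = 2)
  tab <- cohort_feature_table(spec, bands = c("raw", "delta"))
  sel <- ttest_select(tab, attr(tab, "labels"), alpha = 0.05)
  marg <- selection_marginals(sel)
  expect_equal(sum(marg$by_channel), sel$n_selected)
  expect_equal(sum(marg$by_band), sel$n_selected)
  expect_equal(sum(marg$by_condition), sel$n_selected)
  expect_equal(sum(marg$by_feature), sel$n_selected)
  expect_equal(sum(marg$band_by_condition), sel$n_selected)
  expect_equal(sum(marg$channel_by_condition), sel$n_selected)
})

test_that("PCA projection is centred, ordered and reconstructs rank-limited data", {
  set.seed(9)
  B <- matrix(rnorm(11 * 40), nrow = 11)
  scores <- matrix(rnorm(30 * 11), nrow = 30)
  X <- scores %*% B                      # rank 11 by construction
  colnames(X) <- paste0("f", 1:40)
  model <- fit_project(X, n_components = 11)
  Z <- project_features(model, X)
  expect_equal(dim(Z), c(30, 11))
  # variance per component is non-increasing
  v <- apply(Z, 2, var)
  expect_true(all(diff(v) <= 1e-8))
  # training mean row projects to the origin
  mu <- matrix(colMeans(X), nrow = 1, dimnames = list(NULL, colnames(X)))
  expect_equal(as.vector(project_features(model, mu)), rep(0, 11),
               tolerance = 1e-8)
  # perfect reconstruction from 11 components on rank-11 data
  recon <- Z %*% t(model$rotation)
  recon <- sweep(recon, 2, model$center, "+")
  expect_equal(recon, X, tolerance = 1e-8, ignore_attr = TRUE)
  # loadings orthonormal
  expect_equal(t(model$rotation) %*% model$rotation, diag(11),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_warning(fit_project(X[1:5, ], n_components = 11), "directions")
})

test_that("reduce_split uses training rows only (leakage guard)", {
  set.seed(30)
  labels <- make_labels(10)
  X <- matrix(rnorm(20 * 200), nrow = 20)
  X[labels == "preAD", 1:20] <- X[labels == "preAD", 1:20] + 2
  colnames(X) <- paste0("c|b|k|f", 1:200)
  train <- c(1:8, 11:18)
  red <- reduce_split(X, labels, train)
  # corrupt every held-out row and label: fitted objects must not move
  X2 <- X
  X2[-train, ] <- 1e6 * matrix(rnorm(length(X2[-train, ])), nrow = 4)
  labels2 <- labels
  labels2[-train] <- rev(labels[-train])
  red2 <- reduce_split(X2, labels2, train)
  expect_identical(red$selection, red2$selection)
  expect_identical(red$model, red2$model)
  expect_identical(red$coords[train, ], red2$coords[train, ])
})

test_that("under-selection falls back to the smallest p-values", {
  set.seed(31)
  labels <- make_labels(6)
  X <- matrix(rnorm(12 * 30), nrow = 12)
  colnames(X) <- paste0("c|b|k|f", 1:30)
  expect_message(red <- reduce_split(X, labels, seq_len(12), alpha = 1e-12),
                 "falling back")
  expect_equal(ncol(red$coords), 11)
})

test_that("8-fold cross-validation plans partition the cohort", {
  labels <- make_labels(20)
  folds <- make_kfold(labels, k = 8, seed = 2)
  expect_length(folds, 8)
  test_all <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_all, seq_along(labels))
  for (f in folds) {
    expect_setequal(c(f$train, f$test), seq_along(labels))
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_identical(folds, make_kfold(labels, k = 8, seed = 2))
})
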