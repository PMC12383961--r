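separable_data <- function(n_per_class = 20, d = 11, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
               matrix(rnorm(n_per_class * d, mean = gap), ncol = d))
    y <- factor(rep(c("NO", "preAD"), each = n_per_class),
                levels = c("NO", "preAD"))
    list(X = X, y = y)
  })
}

test_that("every classifier separates well-separated clouds perfectly", {
  dat <- separable_data()
  for (kind in classifier_kinds()) {
    model <- fit_classifier(kind, dat$X, dat$y, seed = 7)
    pred <- predict_label(model, dat$X)
    expect_equal(as.character(pred), as.character(dat$y),
                 label = paste(kind, "training accuracy"))
    s <- predict_score(model, dat$X)
    expect_true(all(s >= 0 & s <= 1), label = paste(kind, "score range"))
    # scores rank the positive class above the negative one
    expect_gt(min(s[dat$y == "preAD"]), max(s[dat$y == "NO"]))
  }
})

test_that("classifier fits are deterministic given a seed", {
  dat <- separable_data(gap = 1.5)
  for (kind in classifier_kinds()) {
    m1 <- fit_classifier(kind, dat$X, dat$y, seed = 3)
    m2 <- fit_classifier(kind, dat$X, dat$y, seed = 3)
    expect_equal(predict_score(m1, dat$X), predict_score(m2, dat$X),
                 label = kind)
  }
  expect_error(fit_classifier("logistic_regression", dat$X,
                              factor(rep("NO", 40))), "both classes")
})

test_that("labels independent of features give chance-level test accuracy", {
  accs <- vapply(1:30, function(r) {
    withr::with_seed(100 + r, {
      X <- matrix(rnorm(40 * 11), ncol = 11)
      y <- factor(rep(c("NO", "preAD"), 20), levels = c("NO", "preAD"))
      Xt <- matrix(rnorm(20 * 11), ncol = 11)
      yt <- factor(rep(c("NO", "preAD"), 10), levels = c("NO", "preAD"))
      model <- fit_classifier("lda", X, y, seed = r)
      mean(predict_label(model, Xt) == yt)
    })
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("3-NN assigns the label of a triplicated coincident point", {
  X <- rbind(matrix(rnorm(10 * 3, mean = 5), ncol = 3),
             matrix(c(0, 0, 0), nrow = 3, ncol = 3, byrow = TRUE))
  y <- factor(c(rep("NO", 10), rep("preAD", 3)), levels = c("NO", "preAD"))
  model <- fit_classifier("knn", X, y, seed = 1)
  pred <- predict_label(model, matrix(0, nrow = 1, ncol = 3))
  expect_equal(as.character(pred), "preAD")
})

test_that("trial partitions are balanced, exhaustive and disjoint", {
  p <- partition_trials(72, 31)
  expect_length(p, 31)
  sizes <- lengths(p)
  expect_equal(sort(unique(sizes)), c(2, 3))
  expect_equal(sum(sizes == 3), 10)
  expect_equal(sum(sizes == 2), 21)
  expect_equal(sort(unlist(p)), 1:72)
  expect_equal(lengths(partition_trials(31, 31)), rep(1L, 31))
  expect_error(partition_trials(30, 31), "at least")
  # interleaved and random assignments partition too
  pi_ <- partition_trials(72, 31, method = "interleaved")
  expect_equal(sort(unlist(pi_)), 1:72)
  pr <- partition_trials(72, 31, method = "random", seed = 4)
  expect_equal(sort(unlist(pr)), 1:72)
  expect_identical(pr, partition_trials(72, 31, method = "random", seed = 4))
})

test_that("majority vote picks the most frequent label", {
  lv <- c("NO", "preAD")
  expect_equal(as.character(majority_vote(rep("NO", 31), lv)), "NO")
  votes <- c(rep("preAD", 16), rep("NO", 15))
  expect_equal(as.character(majority_vote(votes, lv)), "preAD")
  expect_equal(as.character(majority_vote(c("NO", "preAD", "NO"), lv)), "NO")
  # tie with an even committee goes to the positive class
  expect_equal(as.character(majority_vote(c("NO", "preAD"), lv)), "preAD")
  m <- rbind(rep("NO", 3), rep("preAD", 3), rep("preAD", 3))
  expect_equal(as.character(majority_vote(m, lv)), c("preAD", "preAD", "preAD"))
})

test_that("metrics of a perfect predictor are all 1 and chance AUROC is 0.5", {
  truth <- factor(c("NO", "NO", "preAD", "preAD"), levels = c("NO", "preAD"))
  m <- classification_metrics(truth, truth, c(0.1, 0.2, 0.8, 0.9))
  expect_equal(unname(m), c(1, 1, 1, 1))
  m2 <- classification_metrics(truth, truth, rep(0.5, 4))
  expect_equal(m2[["auroc"]], 0.5)
  # no positive predictions: precision 0 by convention
  all_no <- factor(rep("NO", 4), levels = c("NO", "preAD"))
  m3 <- classification_metrics(truth, all_no, c(0.4, 0.3, 0.2, 0.1))
  expect_equal(m3[["precision"]], 0)
  expect_equal(m3[["recall"]], 0)
  # AUROC agrees with the rank-sum formula on a non-trivial score
  score <- c(0.2, 0.6, 0.4, 0.9)
  pos <- score[3:4]; neg <- score[1:2]
  auc_rank <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  m4 <- classification_metrics(truth, truth, score)
  expect_equal(m4[["auroc"]], auc_rank)
})

test_that("a degenerate ensemble (identical members) equals the single model", {
  spec <- tiny_spec(n_per_group = 5, effect_size = 0.8, noise_sd = 2)
  coh <- generate_cohort(spec)
  tab <- cohort_feature_table(coh, bands = c("raw", "delta"))
  labels <- attr(tab, "labels")
  plans <- make_splits(labels, n_rounds = 2, seed = 5)
  single <- evaluate_splits(tab, labels, plans, kinds = "lda", mode = "single",
                            seed = 9)
  ens <- evaluate_splits(list(tab, tab, tab), labels, plans, kinds = "lda",
                         mode = "ensemble", seed = 9)
  expect_equal(single$accuracy, ens$accuracy)
  expect_equal(single$recall, ens$recall)
})

test_that("evaluation reports are deterministic end to end", {
  spec <- tiny_spec(n_per_group = 4, effect_size = 0.7, noise_sd = 3)
  coh <- generate_cohort(spec)
  tab <- cohort_feature_table(coh, bands = "raw")
  labels <- attr(tab, "labels")
  plans <- make_splits(labels, n_rounds = 3, seed = 2)
  r1 <- evaluate_splits(tab, labels, plans, kinds = c("lda", "random_forest", "ann"),
                        seed = 11)
  r2 <- evaluate_splits(tab, labels, plans, kinds = c("lda", "random_forest", "ann"),
                        seed = 11)
  expect_identical(r1, r2)
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 1))
  expect_true(all(r1$auroc >= 0 & r1$auroc <= 1))
  agg <- aggregate_report(r1)
  expect_equal(nrow(agg), 3)
  expect_true(all(c("accuracy_mean", "auroc_sd") %in% names(agg)))
})

test_that("reduced-acquisition configurations select the documented subsets", {
  cfg5 <- evaluation_config("channels5")
  expect_equal(cfg5$channels, c("Fz", "Pz", "Cz", "Wl", "Wr"))
  cfg30 <- evaluation_config("trials30", n_trials = 72)
  expect_equal(cfg30$trials, 1:30)
  cfg3 <- evaluation_config("bands3")
  expect_equal(cfg3$bands, c("raw", "delta", "gamma"))
  full <- evaluation_config("full")
  expect_null(full$channels)
  expect_null(full$trials)
})
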