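#' Binary classification metrics
#'
#' Accuracy, precision, recall and AUROC with `preAD` as the positive
#' class. Precision is 0 when no positive predictions are made (unless
#' there are also no positive truths, in which case it is 1); AUROC of a
#' constant score is 0.5.
#'
#' @param truth Factor of true labels.
#' @param pred Factor of predicted labels.
#' @param score Numeric positive-class scores (for AUROC).
#' @param positive Positive class label (default `"preAD"`).
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `auroc`.
#' @export
classification_metrics <- function(truth, pred, score, positive = "preAD") {
  truth_pos <- truth == positive
  pred_pos <- pred == positive
  tp <- sum(truth_pos & pred_pos)
  precision <- if (sum(pred_pos) == 0) {
    if (sum(truth_pos) == 0) 1 else 0
  } else tp / sum(pred_pos)
  recall <- if (sum(truth_pos) == 0) 1 else tp / sum(truth_pos)
  auroc <- if (length(unique(score)) == 1 || length(unique(truth_pos)) == 1) {
    0.5
  } else {
    as.numeric(pROC::auc(pROC::roc(
      response = truth_pos, predictor = score,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
  }
  c(accuracy = mean(truth == pred), precision = precision,
    recall = recall, auroc = auroc)
}

fit_member <- function(X, y, train, kind, seed, alpha = 0.01,
                       n_components = 11, scale. = FALSE) {
  red <- reduce_split(X, y, train, alpha = alpha, n_components = n_components,
                      scale. = scale.)
  model <- fit_classifier(kind, red$coords[train, , drop = FALSE],
                          y[train], seed = seed)
  list(reduction = red, model = model)
}

#' Evaluate classifiers over precomputed split plans
#'
#' The workhorse evaluation loop. For every split plan and classifier kind
#' it runs the leakage-safe reduction (training-set t-test selection + PCA)
#' and classifier fit, then scores the held-out subjects. In ensemble mode
#' each trial-subgroup member re-runs the full reduction + fit on its own
#' feature table; subject predictions are the majority vote and the AUROC
#' score is the mean member score.
#'
#' @param tables A single feature matrix (mode `"single"`) or a list of
#'   per-subgroup feature matrices (mode `"ensemble"`).
#' @param labels Factor of subject labels (levels `NO`, `preAD`).
#' @param plans Split plans from [make_splits()].
#' @param kinds Classifier kinds (default all six).
#' @param mode `"single"` or `"ensemble"`.
#' @param alpha Selection threshold.
#' @param n_components PCA dimensionality.
#' @param scale. Scale features before PCA.
#' @param seed Base seed for classifier fits.
#' @return A `split_report`: data frame with one row per
#'   (round, classifier) and columns `accuracy`, `precision`, `recall`,
#'   `auroc`.
#' @export
evaluate_splits <- function(tables, labels, plans, kinds = classifier_kinds(),
                            mode = c("single", "ensemble"), alpha = 0.01,
                            n_components = 11, scale. = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "single" && is.list(tables) && !is.matrix(tables)) {
    stop("mode 'single' expects one feature matrix")
  }
  if (mode == "ensemble" && !is.list(tables)) {
    stop("mode 'ensemble' expects a list of per-subgroup feature matrices")
  }
  labels <- factor(as.character(labels), levels = c("NO", "preAD"))
  rows <- list()
  for (plan in plans) {
    train <- plan$train
    test <- plan$test
    for (kind in kinds) {
      kseed <- derive_seed(seed, plan$round, match(kind, classifier_kinds()))
      if (mode == "single") {
        mem <- fit_member(tables, labels, train, kind, kseed,
                          alpha = alpha, n_components = n_components,
                          scale. = scale.)
        pred <- predict_label(mem$model, mem$reduction$coords[test, , drop = FALSE])
        score <- predict_score(mem$model, mem$reduction$coords[test, , drop = FALSE])
      } else {
        member_labels <- matrix(NA_character_, nrow = length(tables),
                                ncol = length(test))
        member_scores <- matrix(NA_real_, nrow = length(tables),
                                ncol = length(test))
        for (s in seq_along(tables)) {
          mem <- fit_member(tables[[s]], labels, train, kind,
                            derive_seed(kseed, s), alpha = alpha,
                            n_components = n_components, scale. = scale.)
          coords_test <- mem$reduction$coords[test, , drop = FALSE]
          member_labels[s, ] <- as.character(predict_label(mem$model, coords_test))
          member_scores[s, ] <- predict_score(mem$model, coords_test)
        }
        pred <- majority_vote(member_labels, levels = levels(labels))
        score <- colMeans(member_scores)
      }
      m <- classification_metrics(labels[test], pred, score)
      rows[[length(rows) + 1L]] <- data.frame(
        round = plan$round, classifier = kind, mode = mode,
        accuracy = m[["accuracy"]], precision = m[["precision"]],
        recall = m[["recall"]], auroc = m[["auroc"]],
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("split_report", "data.frame")
  report
}

#' Aggregate a split report into mean and SD per classifier
#'
#' @param report A `split_report` from [evaluate_splits()].
#' @return Data frame with one row per classifier and `<metric>_mean`,
#'   `<metric>_sd` columns.
#' @export
aggregate_report <- function(report) {
  metrics <- c("accuracy", "precision", "recall", "auroc")
  out <- lapply(split(report, report$classifier), function(d) {
    row <- data.frame(classifier = d$classifier[1], n_rounds = nrow(d))
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]])
      row[[paste0(m, "_sd")]] <- stats::sd(d[[m]])
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$classifier, classifier_kinds())), ]
}

#' Reduced-acquisition configurations
#'
#' `full` uses all 15 channels, 6 bands, all trials; `channels5` restricts
#' to the five most informative sites (Fz, Pz, Cz, Wl, Wr); `trials30`
#' uses only the first 30 trials per condition; `bands3` keeps raw, delta
#' and gamma.
#'
#' @param config One of `"full"`, `"channels5"`, `"trials30"`, `"bands3"`.
#' @param n_trials Total trials available (for `trials30` clipping).
#' @return List with `channels`, `bands`, `trials` (NULL means all).
#' @export
evaluation_config <- function(config = c("full", "channels5", "trials30", "bands3"),
                              n_trials = 72) {
  config <- match.arg(config)
  out <- list(channels = NULL, bands = names(band_specs()), trials = NULL)
  if (config == "channels5") out$channels <- c("Fz", "Pz", "Cz", "Wl", "Wr")
  if (config == "trials30") out$trials <- seq_len(min(30, n_trials))
  if (config == "bands3") out$bands <- c("raw", "delta", "gamma")
  out
}

#' End-to-end evaluation of a cohort
#'
#' Generates (or accepts) a cohort, computes the feature table(s) for the
#' chosen configuration, draws group-matched 85/15 splits and evaluates the
#' requested classifiers, single or as the 31-subgroup majority-vote
#' ensemble.
#'
#' @param x An `erp_cohort` or `cohort_spec`.
#' @param kinds Classifier kinds (default all six).
#' @param mode `"single"` or `"ensemble"`.
#' @param config Acquisition configuration ([evaluation_config()]).
#' @param n_rounds Number of random splits (default 100).
#' @param n_subgroups Ensemble size (default 31).
#' @param seed Seed for splits and classifier fits.
#' @param ... Passed to [evaluate_splits()] (e.g. `alpha`, `n_components`).
#' @return List with `report` (per-round metrics), `summary`
#'   (mean~SD per classifier), the split `plans` and the feature `tables`
#'   (one matrix, or one per ensemble member).
#' @export
evaluate <- function(x, kinds = classifier_kinds(),
                     mode = c("single", "ensemble"),
                     config = "full", n_rounds = 100, n_subgroups = 31,
                     seed = 1L, ...) {
  mode <- match.arg(mode)
  spec <- if (inherits(x, "cohort_spec")) x else x$spec
  n_trials <- if (!is.null(spec)) spec$n_trials else dim(x$subjects[[1]]$data)[3]
  cfg <- evaluation_config(config, n_trials = n_trials)
  labels <- if (inherits(x, "erp_cohort")) x$labels else {
    factor(cohort_layout(spec)$group, levels = c("NO", "preAD"))
  }
  if (mode == "single") {
    tables <- cohort_feature_table(x, bands = cfg$bands, channels = cfg$channels,
                                   trials = cfg$trials, seed = seed)
  } else {
    avail <- cfg$trials %||% seq_len(n_trials)
    partition <- partition_trials(length(avail), n_subgroups)
    partition <- lapply(partition, function(p) avail[p])
    tables <- subgroup_feature_tables(x, partition, bands = cfg$bands,
                                      channels = cfg$channels, seed = seed)
  }
  plans <- make_splits(labels, n_rounds = n_rounds, seed = seed)
  report <- evaluate_splits(tables, labels, plans, kinds = kinds, mode = mode,
                            seed = seed, ...)
  list(report = report, summary = aggregate_report(report), plans = plans,
       tables = tables)
}
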