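#' Reproducible train/test split plans with group-matched test sets
#'
#' Each round holds out `round(test_frac * n / 2)` subjects per group
#' (at least one per group) as the test set; with 40 subjects and a 15%
#' test fraction that is 3 + 3 test subjects and 34 training subjects.
#'
#' @param labels Factor of group labels (two levels).
#' @param n_rounds Number of random splits (default 100).
#' @param test_frac Test fraction of the cohort (default 0.15).
#' @param seed Integer seed; plans are reproducible given `(labels, seed)`.
#' @return List of `split_plan`s: each a list with integer `train`, `test`
#'   index vectors and the `round` number.
#' @export
make_splits <- function(labels, n_rounds = 100, test_frac = 0.15, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  idx_by_group <- split(seq_along(labels), labels)
  n <- length(labels)
  n_test_per_group <- max(1L, round(test_frac * n / 2))
  if (any(lengths(idx_by_group) <= n_test_per_group)) {
    stop("test_frac leaves no training subjects in one group")
  }
  lapply(seq_len(n_rounds), function(r) {
    withr::with_seed(derive_seed(seed, r), {
      test <- sort(unlist(lapply(idx_by_group, sample, size = n_test_per_group)))
      structure(list(train = setdiff(seq_len(n), test), test = test, round = r),
                class = "split_plan")
    })
  })
}

#' Stratified k-fold cross-validation plans
#'
#' Assigns every subject to exactly one of `k` test folds, stratified by
#' group, and returns plans in the same shape as [make_splits()] so they can
#' be fed to [evaluate_splits()] directly.
#'
#' @param labels Factor of group labels (two levels).
#' @param k Number of folds (default 8).
#' @param seed Integer seed.
#' @return List of `k` `split_plan`s whose test sets partition the cohort.
#' @export
make_kfold <- function(labels, k = 8, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    for (g in levels(labels)) {
      idx <- sample(which(labels == g))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    structure(list(train = which(fold != f), test = which(fold == f),
                   round = f),
              class = "split_plan")
  })
}

#' Two-tailed t-test feature selection on training data
#'
#' Per-feature two-sample Student (pooled-variance) t-test between the two
#' groups, computed on training rows only; features with `p < alpha` are
#' selected. Features constant within both groups get `p = 1`. A Welch
#' variant is available.
#'
#' @param X Numeric matrix, training subjects x features (named columns).
#' @param y Factor of training group labels (two levels).
#' @param alpha Significance threshold (default 0.01).
#' @param var_equal Pooled-variance Student test if `TRUE` (default),
#'   Welch otherwise.
#' @return A `selection_result`: list with `p` (named p-values), `mask`
#'   (logical), `alpha`, and `n_selected`.
#' @export
ttest_select <- function(X, y, alpha = 0.01, var_equal = TRUE) {
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("y must have two levels")
  n1 <- sum(y == levels(y)[1])
  n2 <- sum(y == levels(y)[2])
  if (n1 < 2 || n2 < 2) stop("need at least 2 training subjects per group")
  X1 <- X[y == levels(y)[1], , drop = FALSE]
  X2 <- X[y == levels(y)[2], , drop = FALSE]
  m1 <- colMeans(X1)
  m2 <- colMeans(X2)
  v1 <- (colSums(X1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(X2^2) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0)
  v2 <- pmax(v2, 0)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0 & m1 == m2] <- 1          # constant in both groups: never selected
  p[se == 0 & m1 != m2] <- 0          # perfectly separated constant feature
  structure(list(p = p, mask = p < alpha, alpha = alpha,
                 n_selected = sum(p < alpha)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d / %d features with p < %g\n",
              x$n_selected, length(x$p), x$alpha))
  invisible(x)
}

#' Selected-count marginals by channel, band, condition and feature
#'
#' Cross-tabulates a selection mask along the key components encoded in the
#' feature names (`channel|band|condition|feature`).
#'
#' @param sel A `selection_result`.
#' @return List of named count vectors: `by_channel`, `by_band`,
#'   `by_condition`, `by_feature`, plus matrices `band_by_condition` and
#'   `channel_by_condition`.
#' @export
selection_marginals <- function(sel) {
  keys <- do.call(rbind, strsplit(names(sel$p), "|", fixed = TRUE))
  keep <- sel$mask
  tab <- function(f) {
    out <- tapply(keep, f, sum)
    out[is.na(out)] <- 0
    out
  }
  list(
    by_channel = tab(keys[, 1]),
    by_band = tab(keys[, 2]),
    by_condition = tab(keys[, 3]),
    by_feature = tab(keys[, 4]),
    band_by_condition = tapply(keep, list(keys[, 2], keys[, 3]), sum),
    channel_by_condition = tapply(keep, list(keys[, 1], keys[, 3]), sum)
  )
}

#' Fit a centred PCA projection on training rows
#'
#' Principal-component projection of the selected training features to at
#' most `n_components` dimensions. Centring (and optional scaling) uses
#' training statistics only; [project_features()] applies them unchanged to
#' new rows. If fewer than `n_components` directions exist, all available
#' directions are kept with a warning.
#'
#' @param X Training matrix (subjects x selected features).
#' @param n_components Target dimensionality (default 11).
#' @param scale. Scale features to unit variance before projection
#'   (default `FALSE`: covariance PCA).
#' @return A `projection_model`: list with `center`, `scale`, `rotation`,
#'   `sdev` and the retained column names.
#' @export
fit_project <- function(X, n_components = 11, scale. = FALSE) {
  if (ncol(X) < 1) stop("no features to project")
  keep <- min(n_components, ncol(X), nrow(X) - 1L)
  if (keep < n_components) {
    warning(sprintf("only %d projection directions available (requested %d)",
                    keep, n_components))
  }
  sds <- apply(X, 2, stats::sd)
  if (scale. && any(sds == 0)) {
    scale. <- FALSE
    warning("zero-variance feature: scaling disabled")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  # numerically-null directions (rank-deficient inputs) carry no signal and
  # break downstream covariance-based classifiers
  informative <- sum(pc$sdev > max(pc$sdev[1], 1) * 1e-8)
  if (informative < keep) keep <- max(1L, informative)
  structure(list(center = pc$center,
                 scale = if (isTRUE(scale.)) pc$scale else FALSE,
                 rotation = pc$rotation[, seq_len(keep), drop = FALSE],
                 sdev = pc$sdev[seq_len(keep)],
                 columns = colnames(X)),
            class = "projection_model")
}

#' Project rows with a fitted projection model
#'
#' @param model A `projection_model` from [fit_project()].
#' @param X Matrix with (at least) the model's feature columns.
#' @return Matrix of projected coordinates.
#' @export
project_features <- function(model, X) {
  X <- X[, model$columns, drop = FALSE]
  X <- sweep(X, 2, model$center)
  if (!isFALSE(model$scale)) X <- sweep(X, 2, model$scale, "/")
  X %*% model$rotation
}

#' Leakage-safe selection + projection on one split
#'
#' Runs [ttest_select()] and [fit_project()] on the training rows only.
#' If no feature passes the threshold, falls back to the `n_components`
#' smallest-p features (with a message), so long automated runs never
#' crash on an unlucky split.
#'
#' @param X Full feature matrix (all subjects).
#' @param y Full label factor.
#' @param train Training row indices.
#' @param alpha Selection threshold (default 0.01).
#' @param n_components Projection dimensionality (default 11).
#' @param scale. Passed to [fit_project()].
#' @return List with `selection`, `model`, and `coords` (projected rows for
#'   ALL subjects; only training rows informed the fit).
#' @export
reduce_split <- function(X, y, train, alpha = 0.01, n_components = 11,
                         scale. = FALSE) {
  sel <- ttest_select(X[train, , drop = FALSE], y[train], alpha = alpha)
  cols <- which(sel$mask)
  if (length(cols) == 0) {
    message("no feature passed selection; falling back to smallest p-values")
    cols <- order(sel$p)[seq_len(n_components)]
  }
  model <- suppressWarnings(
    fit_project(X[train, cols, drop = FALSE], n_components = n_components,
                scale. = scale.))
  list(selection = sel, model = model,
       coords = project_features(model, X))
}
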