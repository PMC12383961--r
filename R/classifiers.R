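#' The six classifier kinds
#'
#' @return Character vector: logistic regression, linear soft-margin SVM,
#'   LDA, 3-nearest-neighbour, random forest (100 trees) and a small
#'   fully-connected ReLU network.
#' @export
classifier_kinds <- function() {
  c("logistic_regression", "linear_svm", "lda", "knn", "random_forest", "ann")
}

positive_class <- function(levels) {
  if ("preAD" %in% levels) "preAD" else levels[2]
}

#' Train one classifier on projected features
#'
#' Pinned hyperparameters: logistic regression is an unpenalised binomial
#' GLM; the SVM is linear with cost 1 (no internal rescaling); LDA uses its
#' standard pooled-covariance solver; KNN uses k = 3 with Euclidean
#' distance; the random forest grows 100 trees; the neural network is one
#' hidden layer of 32 ReLU units trained full-batch with cross-entropy for
#' a fixed number of epochs. All stochastic fits are seed-controlled.
#'
#' @param kind One of [classifier_kinds()].
#' @param X Numeric matrix of training rows (e.g. 11 PCA coordinates).
#' @param y Factor of training labels (two levels, both present).
#' @param seed Integer seed.
#' @return A `wvg_classifier` object usable with [predict_label()] and
#'   [predict_score()].
#' @export
fit_classifier <- function(kind, X, y, seed = 1L) {
  kind <- match.arg(kind, classifier_kinds())
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("training labels must contain both classes")
  X <- as.matrix(X)
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  pos <- positive_class(levels(y))
  fit <- withr::with_seed(as.integer(seed), switch(kind,
    logistic_regression = {
      df <- data.frame(X, .y = as.integer(y == pos))
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    linear_svm = e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE),
    # collinearity warnings are expected when fewer features than components
    # survive selection; the PCA coordinates are orthogonal by construction
    lda = suppressWarnings(MASS::lda(X, grouping = y)),
    knn = list(X = X, y = y, k = 3L),
    random_forest = randomForest::randomForest(X, y, ntree = 100),
    ann = fit_ann(X, y, pos, hidden = 32L, epochs = 300L, lr = 0.05)
  ))
  structure(list(kind = kind, fit = fit, levels = levels(y), positive = pos,
                 seed = as.integer(seed)),
            class = "wvg_classifier")
}

#' Predict class labels
#' @param model A `wvg_classifier`.
#' @param X Matrix of rows to classify.
#' @return Factor with the training levels.
#' @export
predict_label <- function(model, X) {
  if (model$kind == "knn") {
    # honour the 3-NN vote directly rather than thresholding the score
    lab <- withr::with_seed(model$seed,
      class::knn(model$fit$X, as.matrix(X), model$fit$y, k = model$fit$k,
                 use.all = TRUE))
    return(factor(as.character(lab), levels = model$levels))
  }
  s <- predict_score(model, X)
  factor(ifelse(s > 0.5, model$positive,
                setdiff(model$levels, model$positive)),
         levels = model$levels)
}

#' Continuous positive-class score
#'
#' Returns a propensity for the positive class (`preAD`): a probability
#' where the model provides one, otherwise a monotone transform of its
#' decision value. Used for AUROC.
#'
#' @inheritParams predict_label
#' @return Numeric vector in `[0, 1]`.
#' @export
predict_score <- function(model, X) {
  X <- as.matrix(X)
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  pos <- model$positive
  switch(model$kind,
    logistic_regression = {
      as.numeric(stats::predict(model$fit, newdata = data.frame(X),
                                type = "response"))
    },
    linear_svm = {
      pr <- stats::predict(model$fit, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      s <- as.numeric(dv[, 1])
      if (!startsWith(colnames(dv)[1], pos)) s <- -s
      stats::plogis(s)
    },
    lda = {
      as.numeric(stats::predict(model$fit, X)$posterior[, pos])
    },
    knn = {
      lab <- withr::with_seed(model$seed,
        class::knn(model$fit$X, X, model$fit$y, k = model$fit$k,
                   prob = TRUE, use.all = TRUE))
      pr <- attr(lab, "prob")
      ifelse(as.character(lab) == pos, pr, 1 - pr)
    },
    random_forest = {
      as.numeric(stats::predict(model$fit, X, type = "prob")[, pos])
    },
    ann = predict_ann(model$fit, X)
  )
}

# --- minimal fully-connected ReLU network -----------------------------------
# 1 hidden layer, softmax output, full-batch gradient descent with fixed
# epochs; inputs standardised with training statistics. Deterministic given
# the RNG state at fit time.

fit_ann <- function(X, y, pos, hidden = 32L, epochs = 300L, lr = 0.05) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  n <- nrow(Z); d <- ncol(Z)
  Y <- cbind(1 - (y == pos), y == pos)       # one-hot, col 2 = positive
  W1 <- matrix(stats::rnorm(d * hidden, 0, sqrt(2 / d)), d, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden * 2, 0, sqrt(2 / hidden)), hidden, 2)
  b2 <- numeric(2)
  for (e in seq_len(epochs)) {
    H <- pmax(Z %*% W1 + matrix(b1, n, hidden, byrow = TRUE), 0)
    O <- H %*% W2 + matrix(b2, n, 2, byrow = TRUE)
    O <- O - apply(O, 1, max)
    P <- exp(O) / rowSums(exp(O))
    dO <- (P - Y) / n
    dW2 <- t(H) %*% dO
    db2 <- colSums(dO)
    dH <- dO %*% t(W2) * (H > 0)
    dW1 <- t(Z) %*% dH
    db1 <- colSums(dH)
    W2 <- W2 - lr * dW2; b2 <- b2 - lr * db2
    W1 <- W1 - lr * dW1; b1 <- b1 - lr * db1
  }
  list(mu = mu, sd = sd, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

predict_ann <- function(fit, X) {
  Z <- sweep(sweep(as.matrix(X), 2, fit$mu), 2, fit$sd, "/")
  n <- nrow(Z)
  H <- pmax(Z %*% fit$W1 + matrix(fit$b1, n, length(fit$b1), byrow = TRUE), 0)
  O <- H %*% fit$W2 + matrix(fit$b2, n, 2, byrow = TRUE)
  O <- O - apply(O, 1, max)
  P <- exp(O) / rowSums(exp(O))
  as.numeric(P[, 2])
}
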