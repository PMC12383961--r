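# Independent brute-force oracles and small fixtures used across the suite.
# These deliberately avoid the package's own algorithms.

# Build a wvg-shaped object from an adjacency (and optional weight) matrix,
# for feeding toy graphs to the feature functions.
toy_wvg <- function(A, W = NULL) {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  if (is.null(W)) W <- A * 1.0
  structure(list(n = nrow(A), A = A, W = W, strength = rowSums(W)),
            class = "wvg")
}

# Undirected adjacency from an edge list (rows i, j [, w]).
adj_from_edges <- function(n, edges, weights = NULL) {
  A <- matrix(0L, n, n)
  W <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    A[i, j] <- A[j, i] <- 1L
    W[i, j] <- W[j, i] <- if (is.null(weights)) 1 else weights[r]
  }
  list(A = A, W = W)
}

# O(N^3) literal evaluation of the visibility inequality.
brute_visibility <- function(x) {
  n <- length(x)
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- TRUE
      if (j > i + 1) {
        for (k in (i + 1):(j - 1)) {
          lhs <- (x[i] - x[k]) / (k - i)
          rhs <- (x[i] - x[j]) / (j - i)
          if (!(lhs > rhs)) { ok <- FALSE; break }
        }
      }
      if (ok) A[i, j] <- A[j, i] <- 1L
    }
  }
  A
}

# All set partitions of 1..n as membership vectors (restricted growth).
set_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxc) {
    pos <- length(prefix) + 1L
    if (pos > n) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (c in seq_len(maxc + 1L)) {
      recurse(c(prefix, c), max(maxc, c))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Newman weighted modularity, written independently (double sum form).
oracle_modularity <- function(W, membership) {
  m2 <- sum(W)
  k <- rowSums(W)
  total <- 0
  n <- nrow(W)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        total <- total + W[i, j] - k[i] * k[j] / m2
      }
    }
  }
  total / m2
}

best_partition_modularity <- function(W) {
  parts <- set_partitions(nrow(W))
  max(vapply(parts, function(p) oracle_modularity(W, p), numeric(1)))
}

all_subsets <- function(n) {
  lapply(seq_len(2^n) - 1L, function(mask) which(bitwAnd(mask, 2^(0:(n - 1))) > 0))
}

oracle_max_clique <- function(A) {
  best <- 1L
  for (s in all_subsets(nrow(A))) {
    if (length(s) > best && all(A[s, s][upper.tri(A[s, s])] == 1)) {
      best <- length(s)
    }
  }
  best
}

oracle_independence <- function(A) {
  best <- 1L
  for (s in all_subsets(nrow(A))) {
    if (length(s) > best && all(A[s, s] == 0)) best <- length(s)
  }
  best
}

oracle_chromatic <- function(A) {
  n <- nrow(A)
  edges <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  if (nrow(edges) == 0) return(1L)
  for (k in 1:n) {
    cols <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
    proper <- apply(cols, 1, function(col) {
      all(col[edges[, 1]] != col[edges[, 2]])
    })
    if (any(proper)) return(k)
  }
  n
}

oracle_min_cut <- function(A) {
  n <- nrow(A)
  best <- Inf
  for (s in all_subsets(n)) {
    if (length(s) == 0 || length(s) == n) next
    t <- setdiff(seq_len(n), s)
    best <- min(best, sum(A[s, t, drop = FALSE]))
  }
  best
}

oracle_tsp <- function(D) {
  n <- nrow(D)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- Inf
  for (p in perms(2:n)) {
    tour <- c(1, p)
    cost <- sum(D[cbind(tour, c(tour[-1], 1))])
    best <- min(best, cost)
  }
  best
}

# Small fast cohort spec for pipeline-level tests: 3 channels, 2 conditions.
tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(
    n_per_group = 4, channels = c("Fz", "Pz", "O1"),
    conditions = c("AN", "AO"), n_trials = 8, effect_size = 0.5,
    noise_sd = 5, seed = 11
  )
  defaults[names(args)] <- args
  do.call(cohort_spec, defaults)
}
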