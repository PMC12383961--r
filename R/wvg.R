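#' Natural visibility between two time points
#'
#' Points `i < j` of the series `x` (sampled on the integer grid `t_i = i`)
#' are mutually visible when every intermediate point `k` satisfies the
#' strict inequality
#' `(x[i] - x[k]) / (k - i) > (x[i] - x[j]) / (j - i)`,
#' i.e. the straight line from `i` to `j` clears all intermediate samples.
#' Adjacent points are always visible; collinear intermediate points block
#' visibility (strict inequality).
#'
#' @param x Numeric series.
#' @param i,j Node indices with `1 <= i < j <= length(x)`.
#' @return Logical.
#' @export
is_visible <- function(x, i, j) {
  n <- length(x)
  if (i < 1 || j > n) stop("indices out of range")
  if (i >= j) stop("requires i < j")
  if (j == i + 1) return(TRUE)
  k <- (i + 1):(j - 1)
  all((x[i] - x[k]) / (k - i) > (x[i] - x[j]) / (j - i))
}

#' Weight of a visibility edge
#'
#' The absolute arctangent of the chord slope in node-index time units:
#' `|atan((x[i] - x[j]) / (i - j))|`, always in `[0, pi/2)`.
#'
#' @inheritParams is_visible
#' @return Edge weight in radians.
#' @export
edge_weight <- function(x, i, j) {
  if (!is_visible(x, i, j)) stop("pair (", i, ",", j, ") is not visible")
  atan(abs(x[i] - x[j]) / abs(i - j))
}

# O(N^2) visibility scan: j is visible from i iff the slope of the chord
# (i, j) strictly exceeds the running maximum of the slopes (i, k), i < k < j.
visibility_adjacency <- function(x) {
  n <- length(x)
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    slopes <- (x[(i + 1):n] - x[i]) / seq_len(n - i)
    vis <- slopes > cummax(c(-Inf, slopes[-length(slopes)]))
    A[i, (i + 1):n][vis] <- 1L
  }
  A + t(A)
}

#' Build a weighted visibility graph from a time series
#'
#' Nodes are time points on the integer grid; two nodes are joined when
#' mutually visible ([is_visible()]); each visibility edge carries the
#' absolute arctangent of its chord slope ([edge_weight()]). Edges between
#' equal-valued points are kept in the binary adjacency with weight zero.
#' Visibility graphs always contain the path 1-2-...-N, hence are connected.
#'
#' @param x Numeric series of length >= 2 with finite values.
#' @return A `wvg`: list with `n`, binary adjacency `A`, weighted adjacency
#'   `W` and node strengths `strength` (row sums of `W`).
#' @export
build_wvg <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 points")
  if (!all(is.finite(x))) stop("series contains non-finite values")
  A <- visibility_adjacency(x)
  slope <- outer(x, x, "-") / outer(seq_len(n), seq_len(n), "-")
  W <- atan(abs(slope))
  diag(W) <- 0
  W <- W * A
  structure(list(n = n, A = A, W = W, strength = rowSums(W)), class = "wvg")
}

#' @export
print.wvg <- function(x, ...) {
  cat(sprintf("wvg: %d nodes, %d edges, mean strength %.4f\n",
              x$n, sum(x$A) / 2, mean(x$strength)))
  invisible(x)
}

# igraph view of the binary visibility adjacency (edge-list construction:
# much cheaper than graph_from_adjacency_matrix for these small graphs).
wvg_igraph <- function(g) {
  idx <- which(upper.tri(g$A) & g$A == 1, arr.ind = TRUE)
  igraph::make_graph(as.vector(t(idx)), n = g$n, directed = FALSE)
}

#' Export a weighted visibility graph as an edge list
#'
#' @param g A `wvg`.
#' @return Data frame with columns `i`, `j` (`i < j`) and `w`.
#' @export
wvg_edge_list <- function(g) {
  idx <- which(upper.tri(g$A) & g$A == 1, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], w = g$W[idx])
}
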