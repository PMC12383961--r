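#' Average weighted degree
#'
#' Mean node strength: `(1/N) * sum_i s_i`, with `s_i` the sum of the
#' arctangent edge weights incident on node `i`.
#'
#' @param g A `wvg` from [build_wvg()].
#' @return Numeric scalar.
#' @export
average_weighted_degree <- function(g) mean(g$strength)

#' Degree distribution index
#'
#' The rate `lambda` of a Poisson distribution fitted to the binary degree
#' sequence. The default maximum-likelihood fit is the mean degree; a
#' least-squares alignment of the Poisson pmf to the empirical degree
#' histogram is available as an alternative.
#'
#' @param g A `wvg`.
#' @param method `"mle"` (mean degree, default) or `"lsq"` (least-squares
#'   histogram fit).
#' @return `lambda >= 0`.
#' @export
degree_distribution_index <- function(g, method = c("mle", "lsq")) {
  method <- match.arg(method)
  deg <- colSums(g$A)
  if (method == "mle") return(mean(deg))
  emp <- tabulate(deg + 1L, nbins = max(deg) + 1L) / g$n   # P(K = 0..max)
  k <- 0:max(deg)
  obj <- function(l) sum((stats::dpois(k, l) - emp)^2)
  stats::optimize(obj, c(1e-8, max(deg) + 1))$minimum
}

#' Network entropy
#'
#' Shannon entropy (natural log) of the empirical binary-degree
#' distribution: `S = -sum_k P(k) log P(k)` with `0 log 0 := 0`.
#'
#' @param g A `wvg`.
#' @return `S >= 0`.
#' @export
network_entropy <- function(g) {
  p <- table(colSums(g$A)) / g$n
  -sum(p * log(p))
}

# Weighted Newman modularity of a membership vector on weight matrix W:
# Q = (1/2m) sum_ij (w_ij - k_i k_j / 2m) delta(C_i, C_j).
modularity_q <- function(W, membership) {
  m2 <- sum(W)                       # 2m
  if (m2 <= 0) stop("graph has zero total edge weight")
  k <- rowSums(W)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(W[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
  }
  q
}

#' Louvain community structure and modularity
#'
#' Partitions the weighted visibility graph with the Louvain method
#' (iterated local moving and aggregation until no modularity gain remains)
#' and reports the weighted modularity `Q` of the final partition, evaluated
#' directly from its definition. Zero-weight visibility edges (flat
#' segments) carry no modularity and are ignored by the optimiser.
#'
#' @param g A `wvg`.
#' @param seed Integer seed fixing the node visit order (reproducibility).
#' @return A `community_partition`: list with `membership`, `Q` and the
#'   total edge weight `m`.
#' @export
louvain_modularity <- function(g, seed = 1L) {
  W <- g$W
  if (sum(W) <= 0) stop("total edge weight m is zero")
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  ig <- igraph::make_graph(as.vector(t(idx)), n = nrow(W), directed = FALSE)
  cl <- withr::with_seed(as.integer(seed),
                         igraph::cluster_louvain(ig, weights = W[idx]))
  membership <- as.integer(igraph::membership(cl))
  structure(list(membership = membership,
                 Q = modularity_q(W, membership),
                 m = sum(W) / 2),
            class = "community_partition")
}

#' Average path length
#'
#' Mean unweighted shortest-path hop count over all ordered pairs of
#' distinct nodes: `L = (1/(N(N-1))) * sum_{i != j} l_ij`.
#'
#' @param g A `wvg`, or a precomputed hop-distance matrix.
#' @return `L >= 1`.
#' @export
average_path_length <- function(g) {
  D <- if (is.matrix(g)) g else igraph::distances(wvg_igraph(g))
  if (any(is.infinite(D))) stop("graph is disconnected")
  sum(D) / (nrow(D) * (nrow(D) - 1))
}
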