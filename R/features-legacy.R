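# The twelve "legacy" topological features carried over from earlier
# VG-based dementia work, pinned to the standard graph-theory definitions of
# their names. All operate on the binary visibility adjacency.

legacy_feature_names <- function() {
  c("CC", "GIC", "LE", "GE", "SW", "SMaC", "CTSP", "GD", "IN", "SMiC", "VCN")
}

# Node-wise local clustering coefficients (triangles over connected triples);
# nodes of degree < 2 score 0. This sequence also feeds CCSS.
local_clustering <- function(g) {
  cc <- igraph::transitivity(wvg_igraph(g), type = "local", isolates = "zero")
  as.numeric(cc)
}

# Graph index complexity: 4c(1-c) with c the largest adjacency eigenvalue
# normalised between the path-graph minimum 2cos(pi/(N+1)) and the
# complete-graph maximum N-1.
graph_index_complexity <- function(A) {
  n <- nrow(A)
  lam <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  ref <- 2 * cos(pi / (n + 1))
  cv <- (lam - ref) / (n - 1 - ref)
  4 * cv * (1 - cv)
}

# Nearest-neighbour tour from node 1 plus best-improvement 2-opt on a
# symmetric distance matrix; returns the closed-tour cost. Deterministic:
# ties go to the lowest index.
tsp_cost <- function(D) {
  n <- nrow(D)
  if (n == 2) return(2 * D[1, 2])
  tour <- integer(n)
  tour[1] <- 1L
  left <- rep(TRUE, n)
  left[1] <- FALSE
  for (s in 2:n) {
    cand <- which(left)
    tour[s] <- cand[which.min(D[tour[s - 1], cand])]
    left[tour[s]] <- FALSE
  }
  tour_cost <- function(tr) sum(D[cbind(tr, c(tr[-1], tr[1]))])
  best <- tour_cost(tour)
  repeat {
    improved <- FALSE
    best_delta <- 0
    best_ij <- NULL
    for (i in 1:(n - 1)) {
      a <- tour[if (i == 1) n else i - 1]
      b <- tour[i]
      for (j in (i + 1):n) {
        if (i == 1 && j == n) next
        cc <- tour[j]
        d <- tour[if (j == n) 1 else j + 1]
        delta <- D[a, cc] + D[b, d] - D[a, b] - D[cc, d]
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_ij <- c(i, j)
        }
      }
    }
    if (!is.null(best_ij)) {
      tour[best_ij[1]:best_ij[2]] <- rev(tour[best_ij[1]:best_ij[2]])
      best <- best + best_delta
      improved <- TRUE
    }
    if (!improved) break
  }
  best
}

# DSATUR greedy colouring: returns a colour per vertex.
dsatur_colors <- function(A) {
  n <- nrow(A)
  deg <- colSums(A)
  color <- integer(n)
  for (step in seq_len(n)) {
    un <- which(color == 0L)
    sat <- vapply(un, function(v) {
      nb <- which(A[v, ] == 1 & color > 0)
      length(unique(color[nb]))
    }, integer(1))
    pick <- un[order(-sat, -deg[un], un)][1]
    forbidden <- unique(color[A[pick, ] == 1 & color > 0])
    color[pick] <- setdiff(seq_len(n), forbidden)[1]
  }
  color
}

# Can A be properly coloured with k colours? Backtracking in decreasing-
# degree order with symmetry breaking (a vertex may open at most one new
# colour).
k_colorable <- function(A, k) {
  n <- nrow(A)
  ord <- order(-colSums(A))
  color <- integer(n)
  recurse <- function(pos, used) {
    if (pos > n) return(TRUE)
    v <- ord[pos]
    nb_colors <- unique(color[A[v, ] == 1 & color > 0])
    limit <- min(used + 1L, k)
    for (c in seq_len(limit)) {
      if (!(c %in% nb_colors)) {
        color[v] <<- c
        if (recurse(pos + 1L, max(used, c))) return(TRUE)
        color[v] <<- 0L
      }
    }
    FALSE
  }
  recurse(1L, 0L)
}

# Exact chromatic number: clique lower bound, greedy then DSATUR upper
# bounds, exact backtracking search only when bounds disagree.
chromatic_number <- function(A, lower = NULL) {
  n <- nrow(A)
  if (sum(A) == 0) return(1L)
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  ig <- igraph::make_graph(as.vector(t(idx)), n = n, directed = FALSE)
  lower <- lower %||% igraph::clique_num(ig)
  upper <- max(igraph::greedy_vertex_coloring(ig))
  if (lower >= upper) return(as.integer(upper))
  upper <- min(upper, max(dsatur_colors(A)))
  if (lower >= upper) return(as.integer(upper))
  for (k in lower:(upper - 1L)) {
    if (k_colorable(A, k)) return(as.integer(k))
  }
  as.integer(upper)
}

#' Legacy single-channel graph features
#'
#' Computes one of the eleven binary-graph features inherited from earlier
#' visibility-graph work, by its conventional definition:
#' \describe{
#'   \item{CC}{mean local clustering coefficient (triangles over triples).}
#'   \item{GIC}{graph index complexity `4c(1-c)` of the normalised largest
#'     adjacency eigenvalue.}
#'   \item{LE}{local efficiency: mean over nodes of the efficiency of the
#'     neighbour-induced subgraph.}
#'   \item{GE}{global efficiency: mean of inverse hop distances over pairs.}
#'   \item{SW}{small-worldness `(C / C_rand) / (L / L_rand)` against an
#'     Erdos-Renyi reference with `C_rand` the graph density and
#'     `L_rand = log(N) / log(mean degree)`.}
#'   \item{SMaC}{size of the maximum clique (exact).}
#'   \item{CTSP}{closed-tour cost on hop-count distances: nearest-neighbour
#'     start at node 1, then 2-opt to a local optimum.}
#'   \item{GD}{graph density `2E / (N(N-1))`.}
#'   \item{IN}{independence number (exact).}
#'   \item{SMiC}{size of the global minimum cut (unit capacities).}
#'   \item{VCN}{vertex chromatic number (exact branch-and-bound with
#'     clique/DSATUR bounds).}
#' }
#'
#' @param g A `wvg`.
#' @param name Feature name, one of [legacy_feature_names()].
#' @return Numeric scalar.
#' @export
legacy_feature <- function(g, name) {
  if (!(name %in% legacy_feature_names())) {
    stop("unknown feature '", name, "'")
  }
  ig <- wvg_igraph(g)
  D <- function() igraph::distances(ig)
  switch(name,
    CC = mean(local_clustering(g)),
    GIC = graph_index_complexity(g$A),
    LE = mean(igraph::local_efficiency(ig)),
    GE = igraph::global_efficiency(ig),
    SW = small_worldness(g, D()),
    SMaC = igraph::clique_num(ig),
    CTSP = tsp_cost(D()),
    GD = sum(g$A) / (g$n * (g$n - 1)),
    IN = igraph::independence_number(ig),
    SMiC = igraph::min_cut(ig),
    VCN = chromatic_number(g$A)
  )
}

small_worldness <- function(g, D) {
  n <- g$n
  C <- mean(local_clustering(g))
  L <- average_path_length(D)
  gd <- sum(g$A) / (n * (n - 1))
  mean_deg <- mean(colSums(g$A))
  L_rand <- log(n) / log(mean_deg)
  (C / gd) / (L / L_rand)
}
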