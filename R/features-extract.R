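#' Names of the 16 single-channel graph features
#'
#' Five weighted/distributional features (AWD, DD, NE, M, APL) plus the
#' eleven legacy binary-graph features ([legacy_feature()]).
#' @export
single_channel_features <- function() {
  c("AWD", "DD", "NE", "M", "APL", legacy_feature_names())
}

#' All 16 single-channel features of one weighted visibility graph
#'
#' Shares the igraph view and hop-distance matrix across features, so a
#' full per-graph profile costs one distance computation.
#'
#' @param g A `wvg`.
#' @param seed Seed for the Louvain node visit order.
#' @return Named numeric vector over [single_channel_features()].
#' @export
wvg_features <- function(g, seed = 1L) {
  wvg_profile(g, seed = seed)$features
}

# Features plus the node-wise clustering sequence (shared with CCSS), so the
# sequence is computed once per graph.
wvg_profile <- function(g, seed = 1L) {
  ig <- wvg_igraph(g)
  D <- igraph::distances(ig)
  n <- g$n
  cc_seq <- as.numeric(igraph::transitivity(ig, type = "local", isolates = "zero"))
  C <- mean(cc_seq)
  L <- sum(D) / (n * (n - 1))
  gd <- sum(g$A) / (n * (n - 1))
  mean_deg <- mean(colSums(g$A))
  clique <- igraph::clique_num(ig)
  offdiag <- D[upper.tri(D)]
  feats <- c(
    AWD = average_weighted_degree(g),
    DD = degree_distribution_index(g),
    NE = network_entropy(g),
    M = louvain_modularity(g, seed = seed)$Q,
    APL = L,
    CC = C,
    GIC = graph_index_complexity(g$A),
    LE = mean(igraph::local_efficiency(ig)),
    GE = mean(1 / offdiag),
    SW = (C / gd) / (L / (log(n) / log(mean_deg))),
    SMaC = clique,
    CTSP = tsp_cost(D),
    GD = gd,
    IN = igraph::independence_number(ig),
    SMiC = igraph::min_cut(ig),
    VCN = chromatic_number(g$A, lower = clique)
  )
  list(features = feats, cc_seq = cc_seq)
}

#' Clustering-coefficient sequence similarity across channels
#'
#' Mean Pearson correlation over all unordered channel pairs of the
#' node-wise local-clustering sequences of their visibility graphs. Pairs
#' involving a constant sequence (undefined correlation) contribute 0.
#'
#' @param cc_sequences List (one per channel) of equal-length numeric
#'   clustering-coefficient sequences.
#' @return Scalar in `[-1, 1]`.
#' @export
ccss <- function(cc_sequences) {
  if (length(cc_sequences) < 2) stop("need at least 2 channels")
  if (length(unique(lengths(cc_sequences))) != 1) {
    stop("clustering sequences have unequal lengths")
  }
  M <- do.call(cbind, cc_sequences)
  sds <- apply(M, 2, stats::sd)
  pairs <- utils::combn(ncol(M), 2)
  r <- apply(pairs, 2, function(p) {
    if (sds[p[1]] == 0 || sds[p[2]] == 0) {
      message("constant clustering sequence: pair contributes 0 to CCSS")
      0
    } else {
      stats::cor(M[, p[1]], M[, p[2]])
    }
  })
  mean(r)
}

#' Expected feature-vector keys for a configuration
#'
#' One key per `(channel, band, condition, single-channel feature)` plus one
#' `ALL|band|condition|CCSS` key per `(band, condition)`; keys are
#' `channel|band|condition|feature`.
#'
#' @param channels,bands,conditions Character vectors of the active
#'   configuration (band names, not specs).
#' @return Character vector of length
#'   `n_ch * n_band * 16 * n_cond + n_band * n_cond`.
#' @export
feature_names <- function(channels = standard_channels(),
                          bands = names(band_specs()),
                          conditions = standard_conditions()) {
  # order: condition slowest, then band, then channel, then feature
  grid <- expand.grid(feature = single_channel_features(), channel = channels,
                      band = bands, condition = conditions,
                      stringsAsFactors = FALSE)
  single <- sprintf("%s|%s|%s|%s", grid$channel, grid$band, grid$condition,
                    grid$feature)
  cgrid <- expand.grid(band = bands, condition = conditions,
                       stringsAsFactors = FALSE)
  c(single, sprintf("ALL|%s|%s|CCSS", cgrid$band, cgrid$condition))
}

#' Extract the full feature vector of one subject
#'
#' Builds one weighted visibility graph per `(channel, band, condition)`
#' cell of the block-averaged band series, computes the 16 single-channel
#' features on each, and one cross-channel CCSS per `(band, condition)`.
#' At the standard configuration (15 channels, 6 bands, 6 conditions) the
#' result has `15*6*16*6 + 6*6 = 8676` named entries.
#'
#' @param bs A `band_series_set` from [band_series()].
#' @param seed Seed forwarded to the Louvain step.
#' @return Named numeric vector; names as in [feature_names()].
#' @export
extract_features <- function(bs, seed = 1L) {
  dn <- dimnames(bs)
  channels <- dn$channel
  bands <- dn$band
  conditions <- dn$condition
  if (any(!is.finite(bs))) {
    bad <- which(apply(bs, 1:3, function(v) any(!is.finite(v))), arr.ind = TRUE)
    keys <- apply(bad, 1, function(r) {
      paste(channels[r[1]], bands[r[2]], conditions[r[3]], sep = "|")
    })
    stop("non-finite band series cells: ", paste(keys, collapse = ", "))
  }
  nfeat <- single_channel_features()
  out <- numeric(0)
  ccss_vals <- numeric(0)
  for (cond in conditions) {
    for (band in bands) {
      cc_seqs <- vector("list", length(channels))
      for (ci in seq_along(channels)) {
        g <- build_wvg(bs[channels[ci], band, cond, ])
        prof <- wvg_profile(g, seed = seed)
        fv <- prof$features
        names(fv) <- sprintf("%s|%s|%s|%s", channels[ci], band, cond, nfeat)
        out <- c(out, fv)
        cc_seqs[[ci]] <- prof$cc_seq
      }
      ccss_vals[sprintf("ALL|%s|%s|CCSS", band, cond)] <- ccss(cc_seqs)
    }
  }
  expected <- feature_names(channels, bands, conditions)
  out <- c(out, ccss_vals)
  if (!setequal(names(out), expected)) {
    stop("missing feature cells: ",
         paste(setdiff(expected, names(out)), collapse = ", "))
  }
  out[expected]
}

#' Feature table of a cohort
#'
#' Rows are subjects, columns the named graph features. Accepts a generated
#' cohort or a [cohort_spec()]; given a spec, subjects are generated one at
#' a time and discarded after feature extraction, keeping memory flat.
#'
#' @param x An `erp_cohort` or a `cohort_spec`.
#' @param bands Band names (default all six).
#' @param channels Channel subset (default all).
#' @param conditions Condition subset (default all).
#' @param trials Trial indices averaged per condition (default all).
#' @param seed Seed for the Louvain step.
#' @return Numeric matrix `subjects x features` with a `labels` attribute
#'   (factor, levels `NO`, `preAD`).
#' @export
cohort_feature_table <- function(x, bands = names(band_specs()),
                                 channels = NULL, conditions = NULL,
                                 trials = NULL, seed = 1L) {
  if (inherits(x, "cohort_spec")) {
    layout <- cohort_layout(x)
    get_subject <- function(i) generate_subject(x, layout$group[i], layout$subject_index[i])
    n_sub <- nrow(layout)
    labels <- factor(layout$group, levels = c("NO", "preAD"))
    ids <- sprintf("%s_%02d", layout$group, layout$subject_index)
  } else if (inherits(x, "erp_cohort")) {
    get_subject <- function(i) x$subjects[[i]]
    n_sub <- length(x$subjects)
    labels <- x$labels
    ids <- vapply(x$subjects, `[[`, "", "subject_id")
  } else {
    stop("x must be an erp_cohort or cohort_spec")
  }
  rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    ep <- get_subject(i)
    if (!is.null(channels) || !is.null(conditions)) {
      ch <- channels %||% dimnames(ep$data)$channel
      cond <- conditions %||% dimnames(ep$data)$condition
      ep$data <- ep$data[ch, cond, , , drop = FALSE]
    }
    bs <- band_series(ep, bands = band_specs(bands), trials = trials)
    rows[[i]] <- extract_features(bs, seed = seed)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- ids
  attr(tab, "labels") <- labels
  tab
}
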