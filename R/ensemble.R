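#' Partition trials into non-overlapping subgroups
#'
#' Splits `n_trials` trial indices into `n_subgroups` disjoint subgroups of
#' near-equal size (sizes differ by at most one; 72 trials into 31 subgroups
#' gives 21 subgroups of 2 and 10 of 3). The default assignment is
#' contiguous blocks in trial order; an interleaved or seeded random
#' assignment is available.
#'
#' @param n_trials Number of trials (>= `n_subgroups`).
#' @param n_subgroups Number of subgroups (default 31).
#' @param method `"contiguous"` (default), `"interleaved"` or `"random"`.
#' @param seed Seed, used only for `method = "random"`.
#' @return List of integer trial-index vectors, one per subgroup.
#' @export
partition_trials <- function(n_trials, n_subgroups = 31,
                             method = c("contiguous", "interleaved", "random"),
                             seed = 1L) {
  method <- match.arg(method)
  n_trials <- stopifnot_scalar_count(n_trials, "n_trials")
  n_subgroups <- stopifnot_scalar_count(n_subgroups, "n_subgroups")
  if (n_trials < n_subgroups) {
    stop("n_trials must be at least n_subgroups")
  }
  base <- n_trials %/% n_subgroups
  rem <- n_trials %% n_subgroups
  sizes <- c(rep(base + 1L, rem), rep(base, n_subgroups - rem))
  idx <- switch(method,
    contiguous = seq_len(n_trials),
    interleaved = order(rep(seq_len(n_subgroups), length.out = n_trials)),
    random = withr::with_seed(as.integer(seed), sample(n_trials))
  )
  if (method == "interleaved") {
    return(unname(split(seq_len(n_trials),
                        rep(seq_len(n_subgroups), length.out = n_trials))))
  }
  unname(split(idx, rep(seq_len(n_subgroups), times = sizes)))
}

#' Majority vote over member predictions
#'
#' @param member_labels Factor/character vector (or matrix with one row per
#'   member) of member predictions for one or more subjects.
#' @param levels Class levels; ties (possible only with an even member
#'   count) go to the positive class.
#' @return Factor of majority labels.
#' @export
majority_vote <- function(member_labels, levels = NULL) {
  if (is.matrix(member_labels)) {
    return(factor(apply(member_labels, 2, function(col) {
      as.character(majority_vote(col, levels = levels))
    }), levels = levels %||% sort(unique(as.character(member_labels)))))
  }
  labs <- as.character(member_labels)
  levels <- levels %||% sort(unique(labs))
  counts <- table(factor(labs, levels = levels))
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1) top <- positive_class(levels)  # pinned tie-break
  factor(top, levels = levels)
}

#' Per-subgroup feature tables for the trial ensemble
#'
#' For each trial subgroup, averages only that subgroup's trials and
#' extracts the full feature table. Members share nothing downstream:
#' selection, projection and classifier fitting are re-run per member
#' inside [evaluate_splits()].
#'
#' @inheritParams cohort_feature_table
#' @param partition List of trial-index vectors from [partition_trials()].
#' @return List of feature matrices, one per subgroup (labels attached to
#'   each).
#' @export
subgroup_feature_tables <- function(x, partition, bands = names(band_specs()),
                                    channels = NULL, conditions = NULL,
                                    seed = 1L) {
  lapply(partition, function(tr) {
    cohort_feature_table(x, bands = bands, channels = channels,
                         conditions = conditions, trials = tr, seed = seed)
  })
}
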