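# Plain-text persistence for epoch sets, cohort manifests and feature
# tables. The epoch container is a self-describing text format: a key:value
# header followed by one `trials x samples` numeric block per
# (channel, condition) cell.

#' Write an epoch set to a text container
#'
#' @param epochs An `epoch_set`.
#' @param path Output file path.
#' @export
write_epoch_set <- function(epochs, path) {
  d <- dim(epochs$data)
  dn <- dimnames(epochs$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("subject_id: %s", epochs$subject_id),
    sprintf("group: %s", epochs$group),
    sprintf("fs: %g", epochs$fs),
    sprintf("t0: %g", epochs$time[1]),
    sprintf("channels: %s", paste(dn$channel, collapse = ",")),
    sprintf("conditions: %s", paste(dn$condition, collapse = ",")),
    sprintf("n_trials: %d", d[3]),
    sprintf("n_samples: %d", d[4])
  ), con)
  for (ch in dn$channel) {
    for (cond in dn$condition) {
      writeLines(sprintf("block: %s %s", ch, cond), con)
      mat <- matrix(epochs$data[ch, cond, , ], nrow = d[3])
      utils::write.table(format(mat, digits = 8, trim = TRUE), con,
                         row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    }
  }
  invisible(path)
}

#' Read an epoch set written by [write_epoch_set()]
#'
#' @param path File path.
#' @return An `epoch_set`.
#' @export
read_epoch_set <- function(path) {
  lines <- readLines(path)
  hdr <- function(key) sub(paste0("^", key, ": "), "", grep(paste0("^", key, ": "), lines, value = TRUE)[1])
  fs <- as.numeric(hdr("fs"))
  t0 <- as.numeric(hdr("t0"))
  channels <- strsplit(hdr("channels"), ",")[[1]]
  conditions <- strsplit(hdr("conditions"), ",")[[1]]
  n_trials <- as.integer(hdr("n_trials"))
  n_samples <- as.integer(hdr("n_samples"))
  data <- array(NA_real_, dim = c(length(channels), length(conditions),
                                  n_trials, n_samples),
                dimnames = list(channel = channels, condition = conditions,
                                trial = NULL, time = NULL))
  block_starts <- grep("^block: ", lines)
  for (b in block_starts) {
    key <- strsplit(sub("^block: ", "", lines[b]), " ")[[1]]
    rows <- lines[(b + 1):(b + n_trials)]
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    data[key[1], key[2], , ] <- mat
  }
  structure(list(subject_id = hdr("subject_id"), group = hdr("group"),
                 data = data, time = t0 + (seq_len(n_samples) - 1) / fs,
                 fs = fs),
            class = "epoch_set")
}

#' Write a cohort manifest
#'
#' Tab-separated table of `subject_id`, `group`, `path`, one row per
#' subject container.
#'
#' @param cohort An `erp_cohort`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort$subjects, function(ep) {
    p <- file.path(dir, paste0(ep$subject_id, ".epochs.txt"))
    write_epoch_set(ep, p)
    p
  }, "")
  manifest <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    group = as.character(cohort$labels),
    path = paths, stringsAsFactors = FALSE)
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Write / read a feature table
#'
#' Comma-separated matrix with subjects as rows; the first two columns are
#' `subject_id` and `group`, remaining column names encode
#' `channel|band|condition|feature`.
#'
#' @param tab Feature matrix from [cohort_feature_table()].
#' @param path Output path.
#' @export
write_feature_table <- function(tab, path) {
  df <- data.frame(subject_id = rownames(tab),
                   group = as.character(attr(tab, "labels")),
                   tab, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write / read a fitted projection model
#'
#' Plain-text container: a header with the retained column names, centring
#' (and optional scaling) vectors, then the loading matrix, one component
#' per column.
#'
#' @param model A `projection_model` from [fit_project()].
#' @param path Output path.
#' @export
write_projection <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("columns: %s", paste(model$columns, collapse = ",")),
    sprintf("center: %s", paste(format(model$center, digits = 17), collapse = ",")),
    sprintf("scale: %s", if (isFALSE(model$scale)) "none" else
      paste(format(model$scale, digits = 17), collapse = ",")),
    sprintf("sdev: %s", paste(format(model$sdev, digits = 17), collapse = ","))
  ), con)
  utils::write.table(format(model$rotation, digits = 17, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  lines <- readLines(path)
  field <- function(key) sub(paste0("^", key, ": "), "",
                             grep(paste0("^", key, ": "), lines, value = TRUE)[1])
  num <- function(s) as.numeric(strsplit(s, ",")[[1]])
  columns <- strsplit(field("columns"), ",")[[1]]
  scale_raw <- field("scale")
  rot_lines <- lines[-(1:4)]
  rotation <- do.call(rbind,
                      lapply(strsplit(trimws(rot_lines), "\\s+"), as.numeric))
  rownames(rotation) <- columns
  colnames(rotation) <- paste0("PC", seq_len(ncol(rotation)))
  structure(list(center = stats::setNames(num(field("center")), columns),
                 scale = if (scale_raw == "none") FALSE else
                   stats::setNames(num(scale_raw), columns),
                 rotation = rotation,
                 sdev = num(field("sdev")),
                 columns = columns),
            class = "projection_model")
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  tab <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(tab) <- df$subject_id
  attr(tab, "labels") <- factor(df$group, levels = c("NO", "preAD"))
  tab
}
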