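# Internal helpers shared across modules.

# Derive a reproducible child seed from a base seed and one or two indices.
# Keeps results independent across subjects/rounds while staying inside the
# 32-bit signed integer range R requires for set.seed().
derive_seed <- function(seed, i, j = 0L) {
  m <- 2147483647
  s <- (as.double(seed) %% m)
  s <- (s * 48271 + as.double(i) * 1299721 + as.double(j) * 7919) %% m
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
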