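#' Frequency-band definitions
#'
#' The five canonical EEG bands plus the unfiltered `raw` band:
#' delta 1-4 Hz, theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz, gamma 30-45 Hz.
#'
#' @param names Optional subset of band names to return.
#' @return Named list of band specs (`name`, `low`, `high`; `NULL` edges for
#'   `raw`).
#' @export
band_specs <- function(names = c("raw", "delta", "theta", "alpha", "beta", "gamma")) {
  all <- list(
    raw = list(name = "raw", low = NULL, high = NULL),
    delta = list(name = "delta", low = 1, high = 4),
    theta = list(name = "theta", low = 4, high = 8),
    alpha = list(name = "alpha", low = 8, high = 13),
    beta = list(name = "beta", low = 13, high = 30),
    gamma = list(name = "gamma", low = 30, high = 45)
  )
  unknown <- setdiff(names, names(all))
  if (length(unknown)) stop("unknown band(s): ", paste(unknown, collapse = ", "))
  all[names]
}

# Transition bandwidth for a passband edge f (Hz): 25% of the edge, but at
# least 2 Hz, and never wider than the edge itself (so the 1 Hz delta edge
# gets a 1 Hz transition band and the 4 Hz edge gets 2 Hz).
transition_bw <- function(edge) min(max(0.25 * edge, 2), edge)

# Hamming-windowed sinc low-pass kernel with -6 dB (half-amplitude) point at
# `fc`. Kernel length ceil(3.3 * fs / tb), forced odd so the kernel is
# symmetric about an integer delay (exact zero phase after compensation).
fir_lowpass_kernel <- function(fc, tb, fs) {
  L <- ceiling(3.3 * fs / tb)
  if (L %% 2 == 0) L <- L + 1
  m <- (L - 1) / 2
  n <- -m:m
  x <- 2 * fc / fs * n
  h <- 2 * fc / fs * ifelse(n == 0, 1, sin(pi * x) / (pi * x))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  h <- h * w
  h / sum(h)                                # unit DC gain
}

# High-pass by spectral inversion of the complementary low-pass.
fir_highpass_kernel <- function(fc, tb, fs) {
  h <- -fir_lowpass_kernel(fc, tb, fs)
  m <- (length(h) + 1) / 2
  h[m] <- h[m] + 1
  h
}

# Zero-phase FIR filtering: linear convolution with a symmetric odd-length
# kernel, keeping the centre-aligned segment (group delay compensated).
conv_same <- function(x, h) {
  n <- length(x)
  L <- length(h)
  if (L > 2 * n) stop("kernel longer than twice the series")
  nf <- stats::nextn(n + L - 1)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - n))) *
                     stats::fft(c(h, numeric(nf - L))), inverse = TRUE)) / nf
  m <- (L - 1) / 2
  y[(m + 1):(m + n)]
}

#' Zero-phase band-pass filter
#'
#' Applies a Hamming-windowed-sinc high-pass followed by a low-pass, each
#' delay-compensated (zero phase). Transition bandwidths follow the 25%-of-
#' passband-edge rule of [transition_bw()], and the -6 dB point of each stage
#' sits at the centre of its transition band: the high-pass half-amplitude
#' frequency is `low - tb/2`, the low-pass one `high + tb/2`.
#'
#' @param x Numeric series.
#' @param band A band spec from [band_specs()]; `raw` returns `x` unchanged.
#' @param fs Sampling rate in Hz.
#' @return Filtered series, same length as `x`.
#' @export
bandpass <- function(x, band, fs) {
  if (is.character(band)) band <- band_specs(band)[[1]]
  if (is.null(band$low)) return(x)
  tb_lo <- transition_bw(band$low)
  tb_hi <- transition_bw(band$high)
  if (band$high + tb_hi / 2 >= fs / 2) {
    stop(sprintf("band edge %g Hz (+%g Hz transition) incompatible with fs = %g Hz",
                 band$high, tb_hi / 2, fs))
  }
  x <- conv_same(x, fir_highpass_kernel(band$low - tb_lo / 2, tb_lo, fs))
  conv_same(x, fir_lowpass_kernel(band$high + tb_hi / 2, tb_hi, fs))
}

#' Average trials pointwise
#'
#' @param trials List of equal-length numeric series, or a matrix with one
#'   trial per row.
#' @return The pointwise arithmetic mean series.
#' @export
average_trials <- function(trials) {
  if (is.matrix(trials)) {
    if (nrow(trials) == 0) stop("no trials to average")
    return(colMeans(trials))
  }
  if (!length(trials)) stop("no trials to average")
  len <- lengths(trials)
  if (length(unique(len)) != 1) stop("trials have unequal lengths")
  colMeans(do.call(rbind, trials))
}

#' Mirror-pad a series
#'
#' Reflects the series about each end without duplicating the boundary
#' sample: `mirror_pad(c(1,2,3), 2)` is `c(3,2,1,2,3,2,1)`.
#'
#' @param x Numeric series.
#' @param pad_samples Number of samples to add at each end
#'   (`< length(x)`).
#' @return Series of length `length(x) + 2 * pad_samples`.
#' @export
mirror_pad <- function(x, pad_samples) {
  n <- length(x)
  if (pad_samples >= n) stop("pad_samples must be smaller than the series length")
  if (pad_samples == 0) return(x)
  c(x[(pad_samples + 1):2], x, x[(n - 1):(n - pad_samples)])
}

#' Crop a series to an onset-relative time window
#'
#' Retains samples whose time lies in `[t_start, t_end)`.
#'
#' @param x Numeric series.
#' @param time Time axis of `x` in seconds relative to stimulus onset.
#' @param t_start,t_end Window limits (s); default -1 to +2.
#' @return The cropped series.
#' @export
crop_window <- function(x, time, t_start = -1, t_end = 2) {
  stopifnot(length(x) == length(time))
  if (t_start >= t_end) stop("empty window: t_start must be < t_end")
  step <- if (length(time) > 1) time[2] - time[1] else 0
  if (t_start < time[1] - 1e-9 || t_end > time[length(time)] + step + 1e-9) {
    stop("window outside the epoch span")
  }
  keep <- time >= t_start - 1e-9 & time < t_end - 1e-9
  if (!any(keep)) stop("empty window")
  x[keep]
}

#' Block-average a series
#'
#' Replaces consecutive non-overlapping blocks of `block` samples by their
#' mean; a trailing partial block is dropped.
#'
#' @param x Numeric series.
#' @param block Block length in samples (default 20, i.e. 80 ms at 250 Hz).
#' @return Series of `floor(length(x) / block)` block means.
#' @export
block_average <- function(x, block = 20) {
  block <- stopifnot_scalar_count(block, "block")
  n_blocks <- length(x) %/% block
  if (n_blocks == 0) stop("block larger than the series")
  colMeans(matrix(x[seq_len(n_blocks * block)], nrow = block))
}

#' Reduce one subject's epochs to block-averaged band series
#'
#' For each (channel, condition): averages the selected trials, mirror-pads
#' the 4-s average to 8 s, band-pass filters, crops to the analysis window
#' and block-averages into 80-ms bins. All stages are linear, so averaging
#' before filtering is exactly equivalent to filtering each trial first.
#'
#' @param epochs An `epoch_set` from [generate_subject()].
#' @param bands Band specs ([band_specs()]) or band names.
#' @param trials Trial indices to average (default: all).
#' @param window Analysis window in seconds (default `c(-1, 2)`).
#' @param block Block length in samples (default 20).
#' @return A `band_series_set`: array `channel x band x condition x time`,
#'   with attributes `step` (s per point) and `window`.
#' @export
band_series <- function(epochs, bands = band_specs(), trials = NULL,
                        window = c(-1, 2), block = 20) {
  if (is.character(bands)) bands <- band_specs(bands)
  d <- dim(epochs$data)
  channels <- dimnames(epochs$data)$channel
  conditions <- dimnames(epochs$data)$condition
  trials <- trials %||% seq_len(d[3])
  if (any(trials < 1 | trials > d[3])) stop("trial indices out of range")
  fs <- epochs$fs
  pad <- 2L * round(fs)                      # extend the 4-s epoch to 8 s
  time_pad <- (epochs$time[1] * fs - pad + seq_len(d[4] + 2 * pad) - 1) / fs
  n_out <- ((sum(epochs$time >= window[1] - 1e-9 &
                 epochs$time < window[2] - 1e-9)) %/% block)
  out <- array(NA_real_,
               dim = c(length(channels), length(bands), length(conditions), n_out),
               dimnames = list(channel = channels, band = names(bands),
                               condition = conditions, time = NULL))
  for (ch in seq_along(channels)) {
    for (k in seq_along(conditions)) {
      sub <- epochs$data[ch, k, trials, , drop = FALSE]
      dim(sub) <- c(length(trials), d[4])
      avg <- average_trials(sub)
      padded <- mirror_pad(avg, pad)
      for (b in seq_along(bands)) {
        filt <- bandpass(padded, bands[[b]], fs)
        cropped <- crop_window(filt, time_pad, window[1], window[2])
        out[ch, b, k, ] <- block_average(cropped, block)
      }
    }
  }
  structure(out, step = block / fs, window = window, class = "band_series_set")
}

#' Tidy table of a band-series set
#'
#' @param bs A `band_series_set` from [band_series()].
#' @param subject Optional subject id column value.
#' @return Data frame with columns `subject` (optional), `channel`, `band`,
#'   `condition`, `time_index`, `value`.
#' @export
band_series_table <- function(bs, subject = NULL) {
  dn <- dimnames(bs)
  grid <- expand.grid(channel = dn$channel, band = dn$band,
                      condition = dn$condition,
                      time_index = seq_len(dim(bs)[4]),
                      stringsAsFactors = FALSE)
  grid$value <- as.vector(bs)
  if (!is.null(subject)) grid <- cbind(subject = subject, grid)
  grid
}
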