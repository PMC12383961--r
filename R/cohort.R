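#' Standard 15-channel montage used by the pipeline
#'
#' Midline (Fz, Cz, Pz), lateral frontal (F7, F8), approximate Broca (Bl, Br),
#' Brodmann area 41 (L41, R41), Wernicke (Wl, Wr), temporal (T5, T6) and
#' occipital (O1, O2) sites.
#' @export
standard_channels <- function() {
  c("Fz", "Pz", "Cz", "F7", "F8", "Bl", "Br", "L41", "R41",
    "Wl", "Wr", "T5", "T6", "O1", "O2")
}

#' Word-repetition paradigm condition labels
#'
#' All New (AN), New Congruous (NC), New Incongruous (NI), All Old (AO),
#' Old Congruous (OC), Old Incongruous (OI).
#' @export
standard_conditions <- function() {
  c("AN", "NC", "NI", "AO", "OC", "OI")
}

# Per-channel gain of the two ERP components. Midline sites carry the largest
# amplitudes; the late positive component is centro-parietal, the early
# negative component centro-frontal. Channels outside the standard montage
# get a neutral 0.5 gain.
component_topography <- function(channels) {
  early <- c(Fz = 1.0, Cz = 1.0, Pz = 0.9, F7 = 0.5, F8 = 0.5, Bl = 0.45,
             Br = 0.45, L41 = 0.5, R41 = 0.5, Wl = 0.7, Wr = 0.7,
             T5 = 0.5, T6 = 0.5, O1 = 0.4, O2 = 0.4)
  late <- c(Fz = 0.9, Cz = 1.0, Pz = 1.0, F7 = 0.45, F8 = 0.45, Bl = 0.45,
            Br = 0.45, L41 = 0.5, R41 = 0.5, Wl = 0.7, Wr = 0.7,
            T5 = 0.5, T6 = 0.5, O1 = 0.4, O2 = 0.4)
  g_early <- ifelse(channels %in% names(early), early[channels], 0.5)
  g_late <- ifelse(channels %in% names(late), late[channels], 0.5)
  list(early = stats::setNames(as.numeric(g_early), channels),
       late = stats::setNames(as.numeric(g_late), channels))
}

# Condition-dependent amplitude gains: incongruous words drive the early
# negative (N400-like) component, repeated ("old") words drive the late
# positive (P600-like) component.
condition_gains <- function(conditions) {
  early <- c(AN = 0.7, NC = 0.4, NI = 1.0, AO = 0.6, OC = 0.35, OI = 0.9)
  late <- c(AN = 0.5, NC = 0.5, NI = 0.5, AO = 1.0, OC = 1.0, OI = 1.0)
  list(early = stats::setNames(ifelse(conditions %in% names(early),
                                      early[conditions], 0.7), conditions),
       late = stats::setNames(ifelse(conditions %in% names(late),
                                     late[conditions], 0.7), conditions))
}

#' Specification of a synthetic two-group ERP cohort
#'
#' Describes the recording geometry (channels, conditions, trials, sampling
#' rate, epoch span) and the generative signal model (component amplitudes,
#' group effect size, background-noise level, jitters) for a two-group
#' event-related-potential cohort. The defaults mirror a word-repetition
#' study: 20 subjects per group, 15 channels, 6 conditions with 72 trials
#' each, 4-s epochs sampled at 250 Hz.
#'
#' The signal model is a sum of (i) 1/f-amplitude-weighted band-limited
#' Gaussian background noise and (ii) two Gabor-like (Gaussian-windowed
#' cosine) components: a negative component peaking ~400 ms post-onset and a
#' positive component peaking ~600 ms. The late-component amplitude of the
#' `preAD` group is scaled by `(1 - effect_size)`, emulating the reduced
#' verbal-memory repetition effect; `effect_size = 0` makes the two groups
#' distributionally identical.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param channels Channel names; defaults to [standard_channels()].
#' @param conditions Condition labels; defaults to [standard_conditions()].
#' @param n_trials Trials per condition (default 72).
#' @param fs Sampling rate in Hz (default 250).
#' @param epoch_span Epoch limits in seconds relative to stimulus onset.
#' @param effect_size Dimensionless group effect in `[0, 1]`: the preAD
#'   late-component amplitude is multiplied by `1 - effect_size`.
#' @param noise_sd Standard deviation of the single-trial background noise
#'   process, in microvolts.
#' @param amp_early,amp_late Peak amplitudes (microvolts) of the early
#'   negative and late positive components at a unit-gain channel.
#' @param latency_jitter_sd Per-trial latency jitter SD in seconds.
#' @param amplitude_jitter_sd Per-subject log-normal amplitude jitter SD.
#' @param seed Integer seed controlling all randomness of the cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 20,
                        channels = standard_channels(),
                        conditions = standard_conditions(),
                        n_trials = 72,
                        fs = 250,
                        epoch_span = c(-2, 2),
                        effect_size = 0.5,
                        noise_sd = 10,
                        amp_early = -5,
                        amp_late = 8,
                        latency_jitter_sd = 0.02,
                        amplitude_jitter_sd = 0.1,
                        seed = 1L) {
  stopifnot_scalar_count(n_per_group, "n_per_group", min = 2L)
  stopifnot_scalar_count(n_trials, "n_trials", min = 1L)
  stopifnot(length(epoch_span) == 2L, epoch_span[1] < epoch_span[2])
  stopifnot(is.numeric(effect_size), length(effect_size) == 1L)
  stopifnot(is.numeric(noise_sd), noise_sd >= 0)
  channels <- as.character(channels)
  conditions <- as.character(conditions)
  if (anyDuplicated(channels)) stop("duplicate channel names")
  if (anyDuplicated(conditions)) stop("duplicate condition labels")
  n_samples <- round((epoch_span[2] - epoch_span[1]) * fs)
  spec <- list(
    n_per_group = as.integer(n_per_group),
    channels = channels,
    conditions = conditions,
    n_trials = as.integer(n_trials),
    fs = fs,
    epoch_span = epoch_span,
    n_samples = n_samples,
    time = epoch_span[1] + (seq_len(n_samples) - 1) / fs,
    effect_size = effect_size,
    noise_sd = noise_sd,
    amp_early = amp_early,
    amp_late = amp_late,
    latency_early = 0.4,
    latency_late = 0.6,
    width_early = 0.10,
    width_late = 0.15,
    freq_early = 2.5,
    freq_late = 1.5,
    latency_jitter_sd = latency_jitter_sd,
    amplitude_jitter_sd = amplitude_jitter_sd,
    topo = component_topography(channels),
    cond_gain = condition_gains(conditions),
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "cohort_spec: 2 x %d subjects, %d channels, %d conditions x %d trials, %g Hz, [%g, %g] s\n",
    x$n_per_group, length(x$channels), length(x$conditions), x$n_trials,
    x$fs, x$epoch_span[1], x$epoch_span[2]))
  cat(sprintf("  effect_size = %g, noise_sd = %g uV, seed = %d\n",
              x$effect_size, x$noise_sd, x$seed))
  invisible(x)
}

check_label <- function(value, valid, what) {
  if (!(value %in% valid)) {
    stop(sprintf("unknown %s '%s'", what, value), call. = FALSE)
  }
  value
}

#' Closed-form ERP component waveform
#'
#' Evaluates one of the two deterministic Gabor components (no noise, no
#' jitter) of the generative model for a given group, condition and channel:
#' `A * g_chan * g_cond * exp(-(t - t0)^2 / (2 s^2)) * cos(2 pi f (t - t0))`,
#' where for the late component of group `preAD` the amplitude `A` is scaled
#' by `(1 - effect_size)`.
#'
#' @param spec A [cohort_spec()].
#' @param component `"early"` (negative, ~400 ms) or `"late"` (positive, ~600 ms).
#' @param group `"preAD"` or `"NO"`.
#' @param condition,channel Labels present in `spec`.
#' @param t Time points (s, relative to onset); defaults to the epoch grid.
#' @param latency_shift Optional additive latency shift in seconds.
#' @return Numeric vector of the component waveform at `t` (microvolts).
#' @export
erp_component <- function(spec, component = c("early", "late"),
                          group = c("NO", "preAD"),
                          condition, channel, t = spec$time,
                          latency_shift = 0) {
  component <- match.arg(component)
  group <- match.arg(group)
  check_label(condition, spec$conditions, "condition")
  check_label(channel, spec$channels, "channel")
  amp <- if (component == "early") spec$amp_early else spec$amp_late
  t0 <- (if (component == "early") spec$latency_early else spec$latency_late) +
    latency_shift
  s <- if (component == "early") spec$width_early else spec$width_late
  f <- if (component == "early") spec$freq_early else spec$freq_late
  amp <- amp * spec$topo[[component]][[channel]] *
    spec$cond_gain[[component]][[condition]]
  if (component == "late" && group == "preAD") {
    amp <- amp * (1 - spec$effect_size)
  }
  amp * gabor(t, t0, s, f)
}

# Gaussian-windowed cosine atom, peak value 1 at t0.
gabor <- function(t, t0, s, f) {
  exp(-(t - t0)^2 / (2 * s^2)) * cos(2 * pi * f * (t - t0))
}

# 1/f-amplitude band-limited Gaussian noise, scaled so the process SD equals
# `sd` in expectation. Shaping is done in the frequency domain; the profile
# is 1/(1 + f) restricted to 0.3-45 Hz (DC removed).
pink_noise_profile <- function(n, fs) {
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  h <- ifelse(f >= 0.3 & f <= 45, 1 / (1 + f), 0)
  h / sqrt(mean(h^2))                       # unit process SD by Parseval
}

pink_noise <- function(n, fs, sd) {
  if (sd == 0) return(numeric(n))
  h <- pink_noise_profile(n, fs)
  w <- stats::rnorm(n)
  sd * Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / n
}

# One column per trial, columns independent.
pink_noise_matrix <- function(n, m, fs, sd) {
  if (sd == 0) return(matrix(0, n, m))
  h <- pink_noise_profile(n, fs)
  W <- matrix(stats::rnorm(n * m), n, m)
  sd * Re(stats::mvfft(stats::mvfft(W) * h, inverse = TRUE)) / n
}

#' Generate one synthetic ERP trial
#'
#' Draws a single-trial time series for the given group, condition and
#' channel: background noise plus the two latency-jittered ERP components.
#' Consumes the current RNG stream unless `seed` is given.
#'
#' @inheritParams erp_component
#' @param subject_gain Named multiplicative amplitude factors
#'   (`early`, `late`) for subject-level variability; default 1.
#' @param seed Optional integer seed for a self-contained reproducible draw.
#' @return Numeric vector of length `spec$n_samples` (microvolts).
#' @export
generate_trial <- function(spec, group = c("NO", "preAD"), condition, channel,
                           subject_gain = c(early = 1, late = 1),
                           seed = NULL) {
  group <- match.arg(group)
  check_label(condition, spec$conditions, "condition")
  check_label(channel, spec$channels, "channel")
  draw <- function() {
    shift <- stats::rnorm(2, 0, spec$latency_jitter_sd)
    pink_noise(spec$n_samples, spec$fs, spec$noise_sd) +
      subject_gain[["early"]] *
        erp_component(spec, "early", group, condition, channel,
                      latency_shift = shift[1]) +
      subject_gain[["late"]] *
        erp_component(spec, "late", group, condition, channel,
                      latency_shift = shift[2])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate all epochs for one subject
#'
#' Reproducible independently of other subjects: the subject's RNG stream is
#' derived from `spec$seed` and `subject_index`, so cohorts can be generated
#' subject-by-subject (streaming) with identical results.
#'
#' @param spec A [cohort_spec()].
#' @param group Group label, `"preAD"` or `"NO"`.
#' @param subject_index Integer index (1-based, unique across the cohort).
#' @return An `epoch_set`: list with `subject_id`, `group`, `data` (a
#'   `channel x condition x trial x time` array), `time`, `fs`.
#' @export
generate_subject <- function(spec, group = c("NO", "preAD"), subject_index) {
  group <- match.arg(group)
  subject_index <- stopifnot_scalar_count(subject_index, "subject_index")
  withr::with_seed(derive_seed(spec$seed, subject_index), {
    gain <- c(early = exp(stats::rnorm(1, 0, spec$amplitude_jitter_sd)),
              late = exp(stats::rnorm(1, 0, spec$amplitude_jitter_sd)))
    nc <- length(spec$channels)
    nk <- length(spec$conditions)
    data <- array(NA_real_,
                  dim = c(nc, nk, spec$n_trials, spec$n_samples),
                  dimnames = list(channel = spec$channels,
                                  condition = spec$conditions,
                                  trial = NULL, time = NULL))
    late_scale <- if (group == "preAD") 1 - spec$effect_size else 1
    noise_gain <- 0.5 + 0.5 * spec$topo$early   # scalp-wide shared noise
    for (k in seq_len(nk)) {
      amp_e <- spec$amp_early * spec$topo$early *
        spec$cond_gain$early[[k]] * gain[["early"]]
      amp_l <- spec$amp_late * spec$topo$late *
        spec$cond_gain$late[[k]] * gain[["late"]] * late_scale
      # trial-level draws shared across channels: one latency shift pair and
      # one noise realisation per (condition, trial), projected through the
      # channel topography, so channels are correlated as on a real scalp
      shifts <- matrix(stats::rnorm(2 * spec$n_trials, 0,
                                    spec$latency_jitter_sd), nrow = 2)
      noise <- pink_noise_matrix(spec$n_samples, spec$n_trials,
                                 spec$fs, spec$noise_sd)   # time x trial
      G_e <- vapply(shifts[1, ], function(s) {
        gabor(spec$time, spec$latency_early + s, spec$width_early,
              spec$freq_early)
      }, numeric(spec$n_samples))
      G_l <- vapply(shifts[2, ], function(s) {
        gabor(spec$time, spec$latency_late + s, spec$width_late,
              spec$freq_late)
      }, numeric(spec$n_samples))
      for (ch in seq_len(nc)) {
        data[ch, k, , ] <- t(noise_gain[ch] * noise +
                             amp_e[ch] * G_e + amp_l[ch] * G_l)
      }
    }
    structure(list(subject_id = sprintf("%s_%02d", group, subject_index),
                   group = group, data = data, time = spec$time, fs = spec$fs),
              class = "epoch_set")
  })
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set %s (%s): %d channels x %d conditions x %d trials x %d samples @ %g Hz\n",
              x$subject_id, x$group, d[1], d[2], d[3], d[4], x$fs))
  invisible(x)
}

#' Order of groups and subject indices within a cohort
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with `subject_index`, `group` for the full cohort
#'   (preAD first, then NO), matching [generate_cohort()].
#' @export
cohort_layout <- function(spec) {
  data.frame(
    subject_index = seq_len(2L * spec$n_per_group),
    group = rep(c("preAD", "NO"), each = spec$n_per_group),
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return An `erp_cohort`: list with `subjects` (list of `epoch_set`),
#'   `labels` (factor, levels `NO`, `preAD`) and `spec`.
#' @export
generate_cohort <- function(spec) {
  layout <- cohort_layout(spec)
  subjects <- lapply(seq_len(nrow(layout)), function(i) {
    generate_subject(spec, layout$group[i], layout$subject_index[i])
  })
  structure(list(subjects = subjects,
                 labels = factor(layout$group, levels = c("NO", "preAD")),
                 spec = spec),
            class = "erp_cohort")
}

#' @export
print.erp_cohort <- function(x, ...) {
  cat(sprintf("erp_cohort: %d subjects (%s)\n", length(x$subjects),
              paste(sprintf("%s n=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  print(x$spec)
  invisible(x)
}
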