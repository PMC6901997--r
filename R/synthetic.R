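#' Configuration of the motor-imagery EEG simulator
#'
#' The simulator emulates the statistical structure that sensorimotor-rhythm
#' decoders exploit: mu (8--12 Hz) and beta (16--26 Hz) oscillations present
#' on every channel, whose amplitude on a class-specific channel group is
#' multiplied by a gain inside an event window -- a gain below 1 is
#' event-related desynchronization (ERD), above 1 synchronization (ERS) --
#' superimposed on 1/f^a background noise. Oscillators are sinusoids with
#' per-trial frequency jitter inside the band and per-channel random phase,
#' so band-power expectations have closed forms usable as test oracles.
#'
#' The default layout mirrors a two-class left/right-hand paradigm on a
#' 22-channel montage: imagining the left hand desynchronizes the first half
#' of the channels, the right hand the second half. Default amplitudes
#' (6 uV mu, 3 uV beta, 2 uV RMS noise) give a single-trial-detectable but
#' not noise-free contrast, and the event window 0.5--3.5 s mimics a cue at
#' 0.5 s with sustained imagery.
#'
#' @param n_channels number of EEG channels.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param epoch_duration_s trial length (s).
#' @param n_trials_per_class trials generated per class.
#' @param class_specs list of class definitions, each a list with
#'   `class_name`, `channels` (1-based indices of the modulated group),
#'   `mu_gain`, `beta_gain`. `NULL` gives the default left/right layout.
#' @param mu_band,beta_band frequency bands (Hz) the oscillator frequencies
#'   are drawn from.
#' @param base_mu_amp,base_beta_amp oscillator amplitudes (uV) outside the
#'   event window.
#' @param noise_exponent spectral exponent `a` of the 1/f^a background.
#' @param noise_amp background noise RMS (uV).
#' @param erd_onset_s,erd_duration_s event window start and length (s).
#' @param seed integer seed; identical configs and seeds give identical
#'   datasets.
#' @param subject_id subject identifier stamped on generated data.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_channels = 22L, sampling_rate_hz = 250,
                         epoch_duration_s = 4.5, n_trials_per_class = 100L,
                         class_specs = NULL,
                         mu_band = c(8, 12), beta_band = c(16, 26),
                         base_mu_amp = 6, base_beta_amp = 3,
                         noise_exponent = 1, noise_amp = 2,
                         erd_onset_s = 0.5, erd_duration_s = 3,
                         seed = 1L, subject_id = "sim01") {
  if (is.null(class_specs)) {
    half <- floor(n_channels / 2)
    class_specs <- list(
      list(class_name = "left_hand", channels = seq_len(half),
           mu_gain = 0.4, beta_gain = 0.6),
      list(class_name = "right_hand",
           channels = seq(half + 1L, n_channels),
           mu_gain = 0.4, beta_gain = 0.6))
  }
  cfg <- list(n_channels = as.integer(n_channels),
              sampling_rate_hz = sampling_rate_hz,
              epoch_duration_s = epoch_duration_s,
              n_trials_per_class = as.integer(n_trials_per_class),
              class_specs = class_specs,
              mu_band = mu_band, beta_band = beta_band,
              base_mu_amp = base_mu_amp, base_beta_amp = base_beta_amp,
              noise_exponent = noise_exponent, noise_amp = noise_amp,
              erd_onset_s = erd_onset_s, erd_duration_s = erd_duration_s,
              seed = as.integer(seed), subject_id = subject_id)
  nyq <- sampling_rate_hz / 2
  for (spec in class_specs) {
    ch <- spec$channels
    if (length(ch) && (min(ch) < 1L || max(ch) > n_channels))
      stop("channel group of class '", spec$class_name,
           "' is out of range 1..", n_channels, call. = FALSE)
    if (spec$mu_gain <= 0 || spec$beta_gain <= 0)
      stop("gains must be > 0 for class '", spec$class_name, "'",
           call. = FALSE)
  }
  if (min(mu_band) <= 0 || max(mu_band) >= nyq ||
      min(beta_band) <= 0 || max(beta_band) >= nyq)
    stop("oscillator bands must lie inside (0, Nyquist)", call. = FALSE)
  class(cfg) <- "synth_config"
  cfg
}

#' Inter-subject variability specification
#'
#' Describes how much simulated subjects differ from the nominal
#' [synth_config()]. Each subject draws: a global oscillator amplitude
#' factor log-uniform in `[1/amplitude_scale, amplitude_scale]`, a band
#' shift uniform in `[-frequency_jitter_hz, +frequency_jitter_hz]`, a
#' circular rotation of the modulated channel groups by an integer offset
#' uniform in `[-channel_group_rotation, +channel_group_rotation]`, and a
#' noise amplitude factor log-uniform in `[1/noise_scale, noise_scale]`.
#' Setting `amplitude_scale = 1, frequency_jitter_hz = 0,
#' channel_group_rotation = 0, noise_scale = 1` makes subjects exchangeable
#' up to sampling noise.
#'
#' @param amplitude_scale maximal oscillator amplitude factor (`>= 1`).
#' @param frequency_jitter_hz maximal band shift (Hz).
#' @param channel_group_rotation maximal circular channel-group offset.
#' @param noise_scale maximal noise amplitude factor (`>= 1`).
#' @return a `subject_shift` list.
#' @export
subject_shift <- function(amplitude_scale = 2, frequency_jitter_hz = 1,
                          channel_group_rotation = 4L, noise_scale = 1.5) {
  if (amplitude_scale < 1 || noise_scale < 1)
    stop("amplitude_scale and noise_scale are maximal factors and must be ",
         ">= 1", call. = FALSE)
  structure(list(amplitude_scale = amplitude_scale,
                 frequency_jitter_hz = frequency_jitter_hz,
                 channel_group_rotation = as.integer(channel_group_rotation),
                 noise_scale = noise_scale),
            class = "subject_shift")
}

# one trial of 1/f^a background noise, expected RMS = noise_amp per channel
pink_noise <- function(n_channels, n_times, exponent, noise_amp) {
  freqs <- seq(0, n_times - 1) / n_times          # fractional frequencies
  half <- ceiling((n_times + 1) / 2)
  gain <- c(0, freqs[2:half]^(-exponent / 2))
  if (half < n_times) gain <- c(gain, rev(gain[2:(n_times - half + 1)]))
  gain <- gain / sqrt(mean(gain^2))               # unit expected RMS
  out <- matrix(0, n_channels, n_times)
  for (ch in seq_len(n_channels)) {
    w <- stats::rnorm(n_times)
    shaped <- Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / n_times
    out[ch, ] <- noise_amp * shaped
  }
  out
}

#' Generate a synthetic motor-imagery dataset
#'
#' Draws `n_trials_per_class` trials per class as described in
#' [synth_config()]: per trial, one mu and one beta frequency are drawn
#' uniformly from their bands, each channel receives both oscillators with
#' independent random phases at the base amplitudes, the class's channel
#' group is multiplied by the class gains inside the event window, and
#' 1/f^a noise is added. Labels are balanced; trials are ordered by class.
#'
#' @param cfg a [synth_config()].
#' @return an `eeg_epochs` dataset of
#'   `n_trials_per_class * n_classes` trials.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$sampling_rate_hz
  n_t <- round(cfg$epoch_duration_s * fs)
  tt <- seq(0, n_t - 1) / fs
  n_cl <- length(cfg$class_specs)
  n <- cfg$n_trials_per_class * n_cl
  erd <- tt >= cfg$erd_onset_s &
    tt < cfg$erd_onset_s + cfg$erd_duration_s

  data <- array(0, dim = c(n, cfg$n_channels, n_t))
  labels <- rep(seq_len(n_cl) - 1L, each = cfg$n_trials_per_class)

  withr::with_seed(cfg$seed, {
    for (i in seq_len(n)) {
      spec <- cfg$class_specs[[labels[i] + 1L]]
      f_mu <- stats::runif(1, cfg$mu_band[1], cfg$mu_band[2])
      f_beta <- stats::runif(1, cfg$beta_band[1], cfg$beta_band[2])
      trial <- pink_noise(cfg$n_channels, n_t, cfg$noise_exponent,
                          cfg$noise_amp)
      for (ch in seq_len(cfg$n_channels)) {
        gm <- rep(1, n_t); gb <- rep(1, n_t)
        if (ch %in% spec$channels) {
          gm[erd] <- spec$mu_gain
          gb[erd] <- spec$beta_gain
        }
        trial[ch, ] <- trial[ch, ] +
          cfg$base_mu_amp * gm *
            sin(2 * pi * f_mu * tt + stats::runif(1, 0, 2 * pi)) +
          cfg$base_beta_amp * gb *
            sin(2 * pi * f_beta * tt + stats::runif(1, 0, 2 * pi))
      }
      data[i, , ] <- trial
    }
  })

  eeg_epochs(data, labels,
             class_names = vapply(cfg$class_specs, `[[`, character(1),
                                  "class_name"),
             sampling_rate_hz = fs,
             subject_id = cfg$subject_id)
}

# rotate a channel group circularly on the montage
rotate_group <- function(channels, offset, n_channels) {
  ((channels - 1L + offset) %% n_channels) + 1L
}

#' Generate a family of simulated subjects
#'
#' Each subject is an independent draw from the variability model in
#' [subject_shift()] applied to the nominal configuration; class semantics
#' (which class modulates which nominal group, gain values) are preserved,
#' so transfer between subjects is possible but imperfect. Subject
#' perturbations and per-subject data seeds derive deterministically from
#' `seed`.
#'
#' @param cfg the nominal [synth_config()].
#' @param n_subjects number of subjects (`>= 2`).
#' @param shift a [subject_shift()].
#' @param seed integer seed.
#' @return list of `eeg_epochs`, subject ids `"S01", "S02", ...`.
#' @export
generate_subject_family <- function(cfg, n_subjects, shift = subject_shift(),
                                    seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"), inherits(shift, "subject_shift"))
  if (n_subjects < 2) stop("need n_subjects >= 2", call. = FALSE)
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) list(
      amp = exp(stats::runif(1, -log(shift$amplitude_scale),
                             log(shift$amplitude_scale))),
      df = stats::runif(1, -shift$frequency_jitter_hz,
                        shift$frequency_jitter_hz),
      rot = if (shift$channel_group_rotation > 0)
        sample(seq(-shift$channel_group_rotation,
                   shift$channel_group_rotation), 1) else 0L,
      noise = exp(stats::runif(1, -log(shift$noise_scale),
                               log(shift$noise_scale))),
      data_seed = sample.int(.Machine$integer.max %/% 2L, 1)
    ))
  })
  lapply(seq_len(n_subjects), function(s) {
    d <- draws[[s]]
    cfg_s <- cfg
    cfg_s$base_mu_amp <- cfg$base_mu_amp * d$amp
    cfg_s$base_beta_amp <- cfg$base_beta_amp * d$amp
    cfg_s$mu_band <- cfg$mu_band + d$df
    cfg_s$beta_band <- cfg$beta_band + d$df
    cfg_s$noise_amp <- cfg$noise_amp * d$noise
    cfg_s$class_specs <- lapply(cfg$class_specs, function(spec) {
      spec$channels <- rotate_group(spec$channels, d$rot, cfg$n_channels)
      spec
    })
    cfg_s$seed <- d$data_seed
    cfg_s$subject_id <- sprintf("S%02d", s)
    generate_dataset(cfg_s)
  })
}

#' Band power per trial and channel
#'
#' Mean squared amplitude of the band-passed signal over a time window:
#' the quantity whose class-conditional modulation defines ERD/ERS, and the
#' verification utility for the simulator's semantics. A unit-amplitude
#' sinusoid inside the band has power 0.5.
#'
#' @param ds an `eeg_epochs` object.
#' @param band `(lo, hi)` band edges in Hz, inside the Nyquist range.
#' @param window `(t0, t1)` half-open time window in seconds; `NULL` for the
#'   whole trial.
#' @param filter_order Butterworth prototype order.
#' @return matrix `[n_trials, n_channels]` of band power (uV^2).
#' @export
bandpower <- function(ds, band, window = NULL, filter_order = 4L) {
  fs <- ds$sampling_rate_hz
  if (min(band) <= 0 || max(band) >= fs / 2)
    stop("band must lie inside (0, Nyquist)", call. = FALSE)
  d <- dim(ds$data)
  if (is.null(window)) {
    keep <- seq_len(d[3])
  } else {
    i0 <- round(window[1] * fs); i1 <- round(window[2] * fs)
    if (i1 <= i0 || i0 < 0 || i1 > d[3])
      stop("empty or out-of-range window", call. = FALSE)
    keep <- (i0 + 1):i1
  }
  bf <- signal::butter(filter_order, c(band[1], band[2]) / (fs / 2),
                       type = "pass")
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1]))
    for (ch in seq_len(d[2])) {
      y <- filtfilt_padded(bf, ds$data[i, ch, ])
      out[i, ch] <- mean(y[keep]^2)
    }
  dimnames(out) <- list(NULL, ds$channel_names)
  out
}
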