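#' Preprocessing configuration
#'
#' Bundles the parameters of the motor-imagery preprocessing chain:
#' band-pass corner frequencies, target sampling rate, epoch window, and the
#' constants of the exponential moving standardization. Defaults follow
#' common practice for sensorimotor-rhythm decoding: a 4--38 Hz pass band
#' captures the mu (8--12 Hz) and beta (16--26 Hz) rhythms while rejecting
#' drift and line noise, epochs of 0--4.5 s at 250 Hz give T = 1125 samples.
#'
#' @param hp_cut_hz high-pass corner (Hz).
#' @param lp_cut_hz low-pass corner (Hz); must exceed `hp_cut_hz` and stay
#'   below the Nyquist frequency of `target_rate_hz`.
#' @param target_rate_hz sampling rate after resampling (Hz).
#' @param epoch_start_s,epoch_end_s half-open crop window `[start, end)` in
#'   seconds relative to the trial start.
#' @param ema_decay decay of the exponentially weighted running mean and
#'   variance, in (0, 1).
#' @param ema_eps variance floor of the standardization denominator.
#' @param filter_order order of the Butterworth band-pass prototype.
#' @return a `preproc_config` list.
#' @export
preproc_config <- function(hp_cut_hz = 4, lp_cut_hz = 38,
                           target_rate_hz = 250,
                           epoch_start_s = 0, epoch_end_s = 4.5,
                           ema_decay = 0.999, ema_eps = 1e-4,
                           filter_order = 4L) {
  cfg <- list(hp_cut_hz = hp_cut_hz, lp_cut_hz = lp_cut_hz,
              target_rate_hz = target_rate_hz,
              epoch_start_s = epoch_start_s, epoch_end_s = epoch_end_s,
              ema_decay = ema_decay, ema_eps = ema_eps,
              filter_order = as.integer(filter_order))
  if (!(hp_cut_hz > 0 && hp_cut_hz < lp_cut_hz &&
        lp_cut_hz < target_rate_hz / 2))
    stop("configuration error: need 0 < hp_cut_hz < lp_cut_hz < ",
         "target_rate_hz/2", call. = FALSE)
  if (epoch_end_s <= epoch_start_s)
    stop("configuration error: epoch_end_s must exceed epoch_start_s",
         call. = FALSE)
  if (!(ema_decay > 0 && ema_decay < 1))
    stop("configuration error: ema_decay must lie in (0,1)", call. = FALSE)
  class(cfg) <- "preproc_config"
  cfg
}

# zero-phase filtering with odd-reflection padding at both ends, which
# suppresses the start/end transients of plain filtfilt
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1, 250L)
  if (np < 3) return(signal::filtfilt(bf, x))
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(np + 1):(np + n)]
}

# apply f(vector) -> vector over every (trial, channel) time series
map_time_series <- function(ds, f) {
  d <- dim(ds$data)
  out <- NULL
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      y <- f(ds$data[i, c, ])
      if (is.null(out)) out <- array(0, dim = c(d[1], d[2], length(y)))
      out[i, c, ] <- y
    }
  }
  ds$data <- out
  ds
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (`hp_cut_hz`--`lp_cut_hz`) to every
#' channel of every trial, forward and backward (`signal::filtfilt`), so the
#' net phase response is zero and epoch timing is preserved. Shape is
#' unchanged.
#'
#' @param ds an `eeg_epochs` object.
#' @param cfg a [preproc_config()].
#' @return the filtered `eeg_epochs`.
#' @export
bandpass_filter <- function(ds, cfg = preproc_config()) {
  fs <- ds$sampling_rate_hz
  if (cfg$lp_cut_hz >= fs / 2)
    stop("configuration error: low-pass cutoff ", cfg$lp_cut_hz,
         " Hz is not below the Nyquist frequency ", fs / 2, " Hz",
         call. = FALSE)
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$hp_cut_hz, cfg$lp_cut_hz) / (fs / 2),
                       type = "pass")
  out <- map_time_series(ds, function(x) filtfilt_padded(bf, x))
  validate_epochs(out)
  out
}

#' Resample epochs to a lower rate
#'
#' Polyphase rational resampling (`signal::resample`) with built-in
#' anti-alias filtering. Only downsampling (or the identity) is supported:
#' the trial length becomes `floor(n_times * target/original)` and the
#' metadata rate is updated.
#'
#' @param ds an `eeg_epochs` object.
#' @param cfg a [preproc_config()]; `target_rate_hz` is the destination rate.
#' @return the resampled `eeg_epochs`.
#' @export
resample_epochs <- function(ds, cfg = preproc_config()) {
  fs <- ds$sampling_rate_hz
  target <- cfg$target_rate_hz
  if (target > fs)
    stop("upsampling (", fs, " -> ", target,
         " Hz) is not supported; only downsampling is needed", call. = FALSE)
  if (isTRUE(all.equal(target, fs))) return(ds)
  frac <- rational_ratio(target, fs)
  n_out <- floor(dim(ds$data)[3] * target / fs)
  out <- map_time_series(ds, function(x) {
    y <- signal::resample(x, frac[1], frac[2])
    y[seq_len(n_out)]
  })
  out$sampling_rate_hz <- target
  validate_epochs(out)
  out
}

# smallest integer p/q with p/q == a/b (rates may be non-integer but rational)
rational_ratio <- function(a, b, tol = 1e-9) {
  for (scale in c(1, 10, 100, 1000)) {
    p <- a * scale; q <- b * scale
    if (abs(p - round(p)) < tol && abs(q - round(q)) < tol) {
      p <- round(p); q <- round(q)
      g <- gcd_int(p, q)
      return(c(p / g, q / g))
    }
  }
  stop("cannot express rate ratio ", a, "/", b, " as a small rational",
       call. = FALSE)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Crop epochs to a time window
#'
#' Keeps the half-open window `[epoch_start_s, epoch_end_s)` of every trial,
#' so a 0--4.5 s window at 250 Hz yields exactly 1125 samples.
#'
#' @param ds an `eeg_epochs` object.
#' @param cfg a [preproc_config()] supplying the window.
#' @return the cropped `eeg_epochs`.
#' @export
crop_epochs <- function(ds, cfg = preproc_config()) {
  fs <- ds$sampling_rate_hz
  i0 <- round(cfg$epoch_start_s * fs)
  i1 <- round(cfg$epoch_end_s * fs)   # exclusive
  n <- dim(ds$data)[3]
  if (i1 <= i0)
    stop("range error: empty crop window [", cfg$epoch_start_s, ", ",
         cfg$epoch_end_s, ")", call. = FALSE)
  if (i0 < 0 || i1 > n)
    stop("range error: window [", cfg$epoch_start_s, ", ", cfg$epoch_end_s,
         ") s needs samples ", i0, "..", i1 - 1, " but trials have only ",
         n, call. = FALSE)
  ds$data <- ds$data[, , (i0 + 1):i1, drop = FALSE]
  ds
}

#' Exponential moving standardization
#'
#' Causal per-sample normalization: within each trial and channel, a running
#' mean \eqn{m_t = d\,m_{t-1} + (1-d)\,x_t} and a running variance
#' \eqn{v_t = d\,v_{t-1} + (1-d)(x_t - m_t)^2} are tracked along time, and
#' the output is \eqn{(x_t - m_t)/\sqrt{\max(v_t, \epsilon)}}. The
#' recursions start from the mean and variance of an initial block
#' (`init_block` samples), so the first samples are standardized by a
#' defined scale rather than by the variance floor. The transform removes
#' slow amplitude drift and equalizes scale across channels and subjects
#' while remaining causal, and is invariant to rescaling of the input except
#' where the variance floor engages (degenerate, near-constant signals).
#'
#' @param ds an `eeg_epochs` object with finite data.
#' @param cfg a [preproc_config()]; uses `ema_decay` and `ema_eps`.
#' @param init_block number of leading samples whose mean/variance seed the
#'   recursions.
#' @return the standardized `eeg_epochs` (shape unchanged).
#' @export
exp_moving_standardize <- function(ds, cfg = preproc_config(),
                                   init_block = 100L) {
  validate_epochs(ds)
  d <- cfg$ema_decay
  eps <- cfg$ema_eps
  out <- map_time_series(ds, function(x) {
    n <- length(x)
    k <- min(n, init_block)
    m0 <- mean(x[seq_len(k)])
    v0 <- mean((x[seq_len(k)] - m0)^2)
    # running mean via the recursive filter m_t = d m_{t-1} + (1-d) x_t
    m <- as.numeric(stats::filter((1 - d) * x, d, method = "recursive",
                                  init = m0))
    sq <- (x - m)^2
    v <- as.numeric(stats::filter((1 - d) * sq, d, method = "recursive",
                                  init = v0))
    (x - m) / sqrt(pmax(v, eps))
  })
  validate_epochs(out)
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in order: epoch cropping, resampling to the target rate,
#' zero-phase band-pass filtering, and exponential moving standardization.
#' The order is configurable through `steps`; cropping before resampling and
#' filtering keeps the arithmetic on the shortest signals, and
#' standardization runs last so the network sees unit-scale input.
#'
#' @param ds an `eeg_epochs` object.
#' @param cfg a [preproc_config()].
#' @param steps character vector choosing and ordering the steps among
#'   `"crop"`, `"resample"`, `"bandpass"`, `"standardize"`.
#' @return the preprocessed `eeg_epochs`.
#' @export
preprocess <- function(ds, cfg = preproc_config(),
                       steps = c("crop", "resample", "bandpass",
                                 "standardize")) {
  for (s in steps) {
    ds <- switch(s,
      crop = crop_epochs(ds, cfg),
      resample = resample_epochs(ds, cfg),
      bandpass = bandpass_filter(ds, cfg),
      standardize = exp_moving_standardize(ds, cfg),
      stop("unknown preprocessing step: ", s, call. = FALSE)
    )
  }
  ds
}
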