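# small in-code fixtures shared across test files

# deterministic toy dataset: n trials, c channels, t samples of white noise
toy_epochs <- function(n = 6, c = 3, t = 50, n_classes = 2, fs = 250,
                       seed = 1) {
  withr::with_seed(seed, {
    eeg_epochs(array(stats::rnorm(n * c * t), c(n, c, t)),
               labels = rep_len(seq_len(n_classes) - 1L, n),
               class_names = paste0("class", seq_len(n_classes)),
               sampling_rate_hz = fs, subject_id = "toy")
  })
}

# dataset holding one pure sinusoid on every channel of every trial
sine_epochs <- function(freq, n = 1, c = 1, t = 1125, fs = 250, amp = 1,
                        n_classes = 2) {
  tt <- seq(0, t - 1) / fs
  x <- amp * sin(2 * pi * freq * tt)
  eeg_epochs(array(rep(x, each = n * c), c(n, c, t)),
             labels = rep_len(seq_len(n_classes) - 1L, n),
             class_names = paste0("class", seq_len(n_classes)),
             sampling_rate_hz = fs, subject_id = "sine")
}

# amplitude of the FFT bin closest to freq (single trial, single channel)
fft_amplitude <- function(x, freq, fs) {
  n <- length(x)
  spec <- abs(stats::fft(x)) / n * 2
  bin <- round(freq * n / fs) + 1
  max(spec[max(1, bin - 1):min(n, bin + 1)])
}

# a small model configuration that keeps unit tests fast
tiny_model_config <- function(...) {
  defaults <- list(C = 3, T = 60, F_T = 2, N_C = 2,
                   temporal_kernel_lengths = c(8L, 6L, 5L, 4L),
                   pool_length = 12L, pool_stride = 6L)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}
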