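#' Build an untrained network
#'
#' Allocates and initializes all parameters of the multiscale filter-bank
#' network described by `cfg`. Every trainable parameter belongs to exactly
#' one of three groups -- `feature_extraction` (temporal and spatial
#' convolutions with their batch norms), `feature_reduction` (square, pool,
#' log, dropout: parameter-free), and `classifier` (final convolution and
#' bias) -- which is what the layered-learning-rate fine-tuning policy acts
#' on.
#'
#' @param cfg a [model_config()].
#' @param init initialization scheme, see [initialize_weights()].
#' @param seed integer seed; identical seeds give identical parameters.
#' @return an object of class `fbcnn_model`.
#' @export
build_model <- function(cfg, init = "paper", seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  nb <- length(cfg$temporal_kernel_lengths)
  FT4 <- nb * cfg$F_T
  model <- structure(list(
    config = cfg,
    par = list(
      Wt = lapply(cfg$temporal_kernel_lengths,
                  function(k) matrix(0, cfg$F_T, k)),
      g1 = rep(1, FT4), b1 = rep(0, FT4),
      Ws = matrix(0, cfg$F_S, FT4 * cfg$C),
      g2 = rep(1, cfg$F_S), b2 = rep(0, cfg$F_S),
      Wc = matrix(0, cfg$N_C, cfg$F_S * cfg$L),
      bc = rep(0, cfg$N_C)
    ),
    buffers = list(m1 = rep(0, FT4), v1 = rep(1, FT4),
                   m2 = rep(0, cfg$F_S), v2 = rep(1, cfg$F_S)),
    trained = FALSE
  ), class = "fbcnn_model")
  initialize_weights(model, scheme = init, seed = seed)
}

#' Map each trainable parameter to its subnetwork group
#'
#' @param model an `fbcnn_model`.
#' @return named character vector: for every parameter tensor, one of
#'   `"feature_extraction"`, `"feature_reduction"`, `"classifier"`.
#' @export
parameter_groups <- function(model) {
  c(Wt = "feature_extraction",
    g1 = "feature_extraction", b1 = "feature_extraction",
    Ws = "feature_extraction",
    g2 = "feature_extraction", b2 = "feature_extraction",
    Wc = "classifier", bc = "classifier")
}

#' Initialize (or re-initialize) network weights
#'
#' The `"paper"` scheme draws every convolution weight from the standard
#' normal distribution (zero mean, unit variance) and sets batch-norm scales
#' to 1 and shifts to 0; the batch norm that follows every convolution keeps
#' this unusually large scale trainable. The `"scaled"` scheme is a
#' fan-in-scaled alternative (`sd = 1/sqrt(fan_in)`) for situations where
#' unit-variance weights destabilize training.
#'
#' @param model an `fbcnn_model`.
#' @param scheme `"paper"` or `"scaled"`.
#' @param seed integer seed.
#' @return the model with fresh parameters, running statistics reset.
#' @export
initialize_weights <- function(model, scheme = c("paper", "scaled"),
                               seed = 1L) {
  scheme <- match.arg(scheme)
  cfg <- model$config
  nb <- length(cfg$temporal_kernel_lengths)
  FT4 <- nb * cfg$F_T
  sd_of <- function(fan_in) if (scheme == "paper") 1 else 1 / sqrt(fan_in)
  withr::with_seed(seed, {
    model$par$Wt <- lapply(cfg$temporal_kernel_lengths, function(k)
      matrix(stats::rnorm(cfg$F_T * k, sd = sd_of(k)), cfg$F_T, k))
    model$par$Ws <- matrix(
      stats::rnorm(cfg$F_S * FT4 * cfg$C, sd = sd_of(FT4 * cfg$C)),
      cfg$F_S, FT4 * cfg$C)
    model$par$Wc <- matrix(
      stats::rnorm(cfg$N_C * cfg$F_S * cfg$L, sd = sd_of(cfg$F_S * cfg$L)),
      cfg$N_C, cfg$F_S * cfg$L)
  })
  model$par$g1 <- rep(1, FT4);      model$par$b1 <- rep(0, FT4)
  model$par$g2 <- rep(1, cfg$F_S);  model$par$b2 <- rep(0, cfg$F_S)
  model$par$bc <- rep(0, cfg$N_C)
  model$buffers <- list(m1 = rep(0, FT4), v1 = rep(1, FT4),
                        m2 = rep(0, cfg$F_S), v2 = rep(1, cfg$F_S))
  model$trained <- FALSE
  model
}

#' Total trainable parameter count
#' @param model an `fbcnn_model`.
#' @return integer number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$par, function(p) {
    if (is.list(p)) sum(vapply(p, length, integer(1))) else length(p)
  }, integer(1)))
}

#' @export
print.fbcnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<fbcnn_model> C=%d T=%d F_T=%d F_S=%d N_C=%d | %d parameters%s\n",
    cfg$C, cfg$T, cfg$F_T, cfg$F_S, cfg$N_C, count_parameters(x),
    if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

# batch array [B, C, T] -> cube (C, T, B) expected by the C++ core
batch_to_cube <- function(batch) aperm(batch, c(2, 3, 1))

check_batch_dims <- function(model, dims, what = "batch") {
  cfg <- model$config
  if (dims[2] != cfg$C)
    stop("dimension error: ", what, " has ", dims[2],
         " channels on axis 2, model expects C = ", cfg$C, call. = FALSE)
  if (dims[3] != cfg$T)
    stop("dimension error: ", what, " has ", dims[3],
         " time points on axis 3, model expects T = ", cfg$T, call. = FALSE)
}

#' Forward pass
#'
#' Runs a batch through the network and returns per-trial class
#' log-probabilities. With `training = FALSE` (the default) dropout is
#' disabled and batch norm uses running statistics, so the output is
#' deterministic. The feature-reduction stage computes, for every spatial
#' filter and pooling window, the log of the windowed mean of squared
#' batch-normalized outputs -- a learned log band power.
#'
#' @param model an `fbcnn_model`.
#' @param batch numeric array `[B, C, T]`.
#' @param training use batch statistics and dropout (used internally by the
#'   training loop, which also consumes the gradients).
#' @return matrix `[B, N_C]` of log-probabilities.
#' @export
forward <- function(model, batch, training = FALSE) {
  if (length(dim(batch)) == 2L)
    batch <- array(batch, dim = c(1L, dim(batch)))
  check_batch_dims(model, dim(batch))
  if (!training)
    return(cpp_fbcnn_infer(batch_to_cube(batch), model$par, model$buffers,
                           model$config, FALSE)$logp)
  step <- cpp_fbcnn_step(batch_to_cube(batch),
                         rep(0L, dim(batch)[1]),
                         model$par, model$buffers, model$config,
                         model$config$dropout_p)
  step$logp
}

#' Predict labels and class probabilities for a dataset
#'
#' Evaluation-mode forward pass over all trials, in batches.
#'
#' @param model an `fbcnn_model`.
#' @param ds an `eeg_epochs` with matching channel/time dimensions.
#' @param batch_size trials per forward batch.
#' @return list with `labels` (integer, `0..N_C-1`), `log_prob` and `prob`
#'   matrices `[n_trials, N_C]` (probability rows sum to 1).
#' @export
predict_epochs <- function(model, ds, batch_size = 64L) {
  check_batch_dims(model, dim(ds$data), "dataset")
  n <- n_trials(ds)
  lp <- matrix(0, n, model$config$N_C)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    lp[idx, ] <- forward(model, ds$data[idx, , , drop = FALSE])
  }
  list(labels = max.col(lp, ties.method = "first") - 1L,
       log_prob = lp, prob = exp(lp))
}

#' @rdname predict_epochs
#' @param object an `fbcnn_model`.
#' @param ... passed on to `predict_epochs()` (first argument: the dataset).
#' @export
predict.fbcnn_model <- function(object, ...) predict_epochs(object, ...)

#' Extract temporal feature maps for one trial
#'
#' Returns the concatenated outputs of the four temporal convolution
#' branches after batch normalization (running statistics), the
#' representation whose per-branch maps visualize which latencies and
#' channels drive the downstream spatial filters.
#'
#' @param model an `fbcnn_model`.
#' @param trial numeric matrix `[C, T]`.
#' @return numeric array `[4*F_T, T, C]` (feature map, time, channel).
#' @export
extract_temporal_features <- function(model, trial) {
  cfg <- model$config
  if (!is.matrix(trial) || nrow(trial) != cfg$C || ncol(trial) != cfg$T)
    stop("dimension error: trial must be a ", cfg$C, " x ", cfg$T,
         " matrix (channels x time)", call. = FALSE)
  out <- cpp_fbcnn_infer(array(trial, dim = c(dim(trial), 1L)),
                         model$par, model$buffers, cfg, TRUE)
  FT4 <- length(cfg$temporal_kernel_lengths) * cfg$F_T
  # (FT4, C*T) with column index c + C*t  ->  [FT4, T, C]
  maps <- array(out$acts$temporal_bn, dim = c(FT4, cfg$C, cfg$T))
  aperm(maps, c(1, 3, 2))
}

#' Inspect intermediate activations for one trial
#'
#' Evaluation-mode forward pass returning every intermediate representation:
#' temporal maps before/after batch norm, spatially filtered signals
#' before/after batch norm, pooled band power, and its log. Mainly useful
#' for verifying the band-power semantics of the feature-reduction stage and
#' for plotting.
#'
#' @param model an `fbcnn_model`.
#' @param trial numeric matrix `[C, T]`.
#' @return named list of matrices (`temporal*`: `[4*F_T, C*T]`,
#'   `spatial*`: `[F_S, T]`, `pooled`/`log_pooled`: `[F_S, L]`), plus
#'   `logp`.
#' @export
model_activations <- function(model, trial) {
  cfg <- model$config
  if (!is.matrix(trial) || nrow(trial) != cfg$C || ncol(trial) != cfg$T)
    stop("dimension error: trial must be a ", cfg$C, " x ", cfg$T,
         " matrix (channels x time)", call. = FALSE)
  out <- cpp_fbcnn_infer(array(trial, dim = c(dim(trial), 1L)),
                         model$par, model$buffers, cfg, TRUE)
  c(out$acts, list(logp = out$logp))
}

#' Save / load a self-describing checkpoint
#'
#' A checkpoint embeds the full model (configuration, parameters, running
#' statistics), so `load_checkpoint()` needs no side information.
#'
#' @param model an `fbcnn_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint()`: `path` invisibly; `load_checkpoint()`: the
#'   model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fbcnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "fbcnn_model"))
  model
}
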