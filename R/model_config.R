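#' Network architecture configuration
#'
#' All hyperparameters of the multiscale filter-bank network. The
#' architecture has three parts:
#'
#' * feature extraction: four parallel temporal convolutions with kernel
#'   lengths `temporal_kernel_lengths` and `F_T` filters each ("same"
#'   padding), concatenated (`4*F_T` maps) and batch-normalized, followed by
#'   a spatial convolution of kernel `(1, C)` with `F_S` filters ("valid")
#'   and a second batch norm;
#' * feature reduction: square, average pooling (`pool_length` window,
#'   `pool_stride` stride, "valid"), log, and dropout -- i.e. the log of
#'   windowed band power of each spatially filtered signal;
#' * classification: a convolution whose kernel spans the whole pooled
#'   length `L = floor((T - pool_length)/pool_stride) + 1`, giving `N_C`
#'   class scores, mapped to log-probabilities by log-softmax.
#'
#' `D` is the ratio `F_T / F_S`; it may be supplied instead of `F_S`
#' (then `F_S = F_T / D`) to mirror the usual two-step hyperparameter
#' search, or alongside both as a redundant consistency check.
#'
#' @param C number of EEG channels.
#' @param T number of time points per trial.
#' @param F_T temporal filters per branch.
#' @param F_S spatial filters; defaults to `F_T / D` when `D` is given,
#'   else to `F_T`.
#' @param D optional ratio `F_T / F_S`.
#' @param N_C number of classes.
#' @param temporal_kernel_lengths integer kernel lengths of the parallel
#'   temporal branches.
#' @param pool_length,pool_stride average-pooling window and stride
#'   (time samples).
#' @param dropout_p dropout probability in `[0, 1)` applied to the pooled
#'   log-power features during training.
#' @param bn_eps batch-norm variance epsilon.
#' @param bn_momentum running-statistics momentum (weight of the current
#'   batch).
#' @return a `model_config` list with the derived pooled length `L`.
#' @export
model_config <- function(C, T, F_T = 40L, F_S = NULL, D = NULL, N_C = 2L,
                         temporal_kernel_lengths = c(64L, 40L, 26L, 16L),
                         pool_length = 75L, pool_stride = 15L,
                         dropout_p = 0.5, bn_eps = 1e-5,
                         bn_momentum = 0.1) {
  if (is.null(F_S)) F_S <- if (is.null(D)) F_T else round(F_T / D)
  if (!is.null(D) && F_T != round(D * F_S))
    stop("configuration error: F_T (", F_T, ") != round(D * F_S) = ",
         round(D * F_S), call. = FALSE)
  cfg <- list(C = as.integer(C), T = as.integer(T), F_T = as.integer(F_T),
              F_S = as.integer(F_S), D = F_T / F_S, N_C = as.integer(N_C),
              temporal_kernel_lengths = as.integer(temporal_kernel_lengths),
              pool_length = as.integer(pool_length),
              pool_stride = as.integer(pool_stride),
              dropout_p = dropout_p, bn_eps = bn_eps,
              bn_momentum = bn_momentum,
              power_floor = 1e-12)
  if (cfg$C < 1 || cfg$T < 1 || cfg$F_T < 1 || cfg$F_S < 1 || cfg$N_C < 2)
    stop("configuration error: C, T, F_T, F_S must be >= 1 and N_C >= 2",
         call. = FALSE)
  if (!(dropout_p >= 0 && dropout_p < 1))
    stop("configuration error: dropout_p must lie in [0, 1)", call. = FALSE)
  if (any(cfg$temporal_kernel_lengths > cfg$T))
    stop("configuration error: temporal kernel longer than T at layer ",
         "temporal_conv_", which.max(cfg$temporal_kernel_lengths),
         call. = FALSE)
  if (cfg$pool_length > cfg$T)
    stop("configuration error: pool_length exceeds T at layer average_pool",
         call. = FALSE)
  cfg$L <- (cfg$T - cfg$pool_length) %/% cfg$pool_stride + 1L
  class(cfg) <- "model_config"
  cfg
}

#' Analytic per-layer shape and parameter report
#'
#' Computes, without building the network, the output shape and trainable
#' parameter count of every layer. Per-layer parameter counts are
#' `kernel * F_T` for each temporal branch (no bias; batch norm follows),
#' `2 * (4*F_T)` for the first batch norm, `C * 4*F_T * F_S` for the spatial
#' convolution, `2 * F_S` for the second batch norm, and
#' `F_S * L * N_C + N_C` for the classifier (weights plus bias). The square,
#' pooling, log and dropout stages carry no parameters.
#'
#' @param cfg a [model_config()].
#' @return a tibble with columns `layer`, `output_shape` (string) and
#'   `n_params`; the attribute `"total"` holds the total count.
#' @export
compute_layer_shapes <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  k <- cfg$temporal_kernel_lengths
  nb <- length(k)
  FT4 <- nb * cfg$F_T
  L <- cfg$L
  shp <- function(...) paste0("(", paste(..., sep = ", "), ")")
  rows <- list(
    list("input", shp(cfg$C, cfg$T), 0L)
  )
  for (i in seq_len(nb))
    rows <- c(rows, list(list(paste0("temporal_conv_", i),
                              shp(cfg$F_T, cfg$T, cfg$C),
                              k[i] * cfg$F_T)))
  rows <- c(rows, list(
    list("concat", shp(FT4, cfg$T, cfg$C), 0L),
    list("batch_norm_1", shp(FT4, cfg$T, cfg$C), 2L * FT4),
    list("spatial_conv", shp(cfg$F_S, cfg$T, 1L),
         cfg$C * FT4 * cfg$F_S),
    list("batch_norm_2", shp(cfg$F_S, cfg$T, 1L), 2L * cfg$F_S),
    list("square", shp(cfg$F_S, cfg$T, 1L), 0L),
    list("average_pool", shp(cfg$F_S, L, 1L), 0L),
    list("log", shp(cfg$F_S, L, 1L), 0L),
    list("dropout", shp(cfg$F_S, L, 1L), 0L),
    list("classifier_conv", shp(cfg$N_C), cfg$F_S * L * cfg$N_C + cfg$N_C)
  ))
  out <- tibble::tibble(
    layer = vapply(rows, `[[`, character(1), 1),
    output_shape = vapply(rows, `[[`, character(1), 2),
    n_params = vapply(rows, function(r) as.integer(r[[3]]), integer(1))
  )
  attr(out, "total") <- sum(out$n_params)
  out
}
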