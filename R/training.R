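#' Optimizer and training-loop configuration
#'
#' Defaults follow the standard recipe for this architecture: Adam with
#' learning rate `1e-3`, L2 weight decay `1e-7`, batch size 64, up to 100
#' epochs, validation accuracy as the model-selection metric with
#' best-validation checkpointing (ties broken toward the earliest epoch).
#'
#' @param base_lr Adam learning rate.
#' @param weight_decay L2 penalty coefficient added to the gradient.
#' @param batch_size minibatch size.
#' @param max_epochs training epochs (no early stopping, for determinism).
#' @param seed integer seed governing shuffling and dropout.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment coefficients.
#' @return a `train_config` list.
#' @export
train_config <- function(base_lr = 1e-3, weight_decay = 1e-7,
                         batch_size = 64L, max_epochs = 100L, seed = 1L,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8) {
  if (base_lr <= 0 || batch_size < 1 || max_epochs < 1)
    stop("configuration error: need base_lr > 0, batch_size >= 1, ",
         "max_epochs >= 1", call. = FALSE)
  structure(list(base_lr = base_lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps),
            class = "train_config")
}

#' Layered learning-rate policy for fine-tuning
#'
#' When adapting a pretrained network to a new subject, earlier layers are
#' updated more cautiously than later ones: the feature-extraction,
#' feature-reduction and classifier subnetworks train at `1/27`, `1/9` and
#' `1/3` of the base learning rate respectively. The feature-reduction stage
#' of this architecture has no trainable parameters, so its factor is
#' exposed for variant architectures but is a no-op here.
#'
#' @param fe_factor,fr_factor,clf_factor multipliers in `(0, 1]` with
#'   `fe_factor <= fr_factor <= clf_factor`.
#' @return a `layered_lr_policy` list.
#' @export
layered_lr_policy <- function(fe_factor = 1 / 27, fr_factor = 1 / 9,
                              clf_factor = 1 / 3) {
  if (!(fe_factor > 0 && fe_factor <= fr_factor &&
        fr_factor <= clf_factor && clf_factor <= 1))
    stop("configuration error: need 0 < fe_factor <= fr_factor <= ",
         "clf_factor <= 1", call. = FALSE)
  structure(list(fe_factor = fe_factor, fr_factor = fr_factor,
                 clf_factor = clf_factor), class = "layered_lr_policy")
}

#' Categorical cross-entropy
#'
#' Mean over the batch of \eqn{-\sum_i p_i \log q_i}, with `p` the one-hot
#' target distribution and `q` the predicted distribution supplied as
#' log-probabilities (the network's native output, so no exponentiation is
#' needed).
#'
#' @param target_onehot matrix `[B, n]` of one-hot rows.
#' @param predicted_logprob matrix `[B, n]` of log-probabilities.
#' @return nonnegative scalar loss.
#' @export
cross_entropy <- function(target_onehot, predicted_logprob) {
  if (!identical(dim(target_onehot), dim(predicted_logprob)))
    stop("dimension mismatch: targets are ",
         paste(dim(target_onehot), collapse = "x"), ", predictions are ",
         paste(dim(predicted_logprob), collapse = "x"), call. = FALSE)
  # terms with p_i = 0 contribute nothing even when log q_i = -Inf
  contrib <- target_onehot * predicted_logprob
  contrib[target_onehot == 0] <- 0
  mean(-rowSums(contrib))
}

one_hot <- function(labels, n_classes) {
  out <- matrix(0, length(labels), n_classes)
  out[cbind(seq_along(labels), labels + 1L)] <- 1
  out
}

# per-parameter learning-rate factors under a (possibly NULL) layered policy
lr_factors <- function(model, policy = NULL) {
  groups <- parameter_groups(model)
  if (is.null(policy))
    return(stats::setNames(rep(1, length(groups)), names(groups)))
  fac <- c(feature_extraction = policy$fe_factor,
           feature_reduction = policy$fr_factor,
           classifier = policy$clf_factor)
  stats::setNames(unname(fac[groups]), names(groups))
}

# --- flat parameter-vector view used by the Adam updates -------------------

par_flatten <- function(par) {
  unlist(lapply(par, function(p) if (is.list(p)) unlist(p) else p),
         use.names = FALSE)
}

par_unflatten <- function(flat, template) {
  out <- template
  at <- 0L
  for (nm in names(template)) {
    p <- template[[nm]]
    if (is.list(p)) {
      for (i in seq_along(p)) {
        len <- length(p[[i]])
        out[[nm]][[i]][] <- flat[at + seq_len(len)]
        at <- at + len
      }
    } else {
      len <- length(p)
      out[[nm]][] <- flat[at + seq_len(len)]
      at <- at + len
    }
  }
  out
}

# expand per-tensor factors to the flat layout
lr_flatten <- function(par, factors) {
  unlist(lapply(names(par), function(nm) {
    p <- par[[nm]]
    n <- if (is.list(p)) sum(lengths(p)) else length(p)
    rep(factors[[nm]], n)
  }), use.names = FALSE)
}

#' Train a network
#'
#' Minimizes the categorical cross-entropy with Adam over shuffled
#' minibatches, evaluating validation loss and accuracy after every epoch,
#' and returns the checkpoint with the best validation accuracy (earliest
#' epoch on ties). Fully reproducible under `cfg$seed`: shuffling and
#' dropout both derive from it.
#'
#' @param model an `fbcnn_model` (its current weights are the starting
#'   point; the input object is not modified).
#' @param train_ds,valid_ds `eeg_epochs` datasets; `valid_ds` may be `NULL`,
#'   in which case no checkpoint selection happens and the final-epoch model
#'   is returned.
#' @param cfg a [train_config()].
#' @param lr_policy optional [layered_lr_policy()] scaling per-subnetwork
#'   learning rates (used by [fine_tune()]).
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint) and `history`, a tibble of
#'   per-epoch `train_loss`, `valid_loss`, `valid_accuracy` with attribute
#'   `"best_epoch"`.
#' @export
train <- function(model, train_ds, valid_ds, cfg = train_config(),
                  lr_policy = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "fbcnn_model"), inherits(cfg, "train_config"))
  if (n_trials(train_ds) == 0L)
    stop("empty training set", call. = FALSE)
  check_batch_dims(model, dim(train_ds$data), "training set")
  mcfg <- model$config
  if (length(train_ds$class_names) != mcfg$N_C)
    stop("dimension error: dataset has ", length(train_ds$class_names),
         " classes, model expects N_C = ", mcfg$N_C, call. = FALSE)

  n <- n_trials(train_ds)
  xcube <- batch_to_cube(train_ds$data)
  labels <- train_ds$labels

  flat <- par_flatten(model$par)
  lrs <- cfg$base_lr * lr_flatten(model$par, lr_factors(model, lr_policy))
  m_state <- numeric(length(flat))
  v_state <- numeric(length(flat))
  step_t <- 0L
  buffers <- model$buffers

  history <- vector("list", cfg$max_epochs)
  best <- list(acc = -Inf, epoch = NA_integer_, flat = flat,
               buffers = buffers)

  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0
      par_now <- par_unflatten(flat, model$par)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        step <- cpp_fbcnn_step(xcube[, , idx, drop = FALSE], labels[idx],
                               par_now, buffers, mcfg, mcfg$dropout_p)
        if (!is.finite(step$loss))
          stop("training diverged: non-finite loss at epoch ", epoch,
               call. = FALSE)
        buffers <- step$buffers
        g <- par_flatten(step$grads) + cfg$weight_decay * flat
        step_t <- step_t + 1L
        m_state <- cfg$adam_beta1 * m_state + (1 - cfg$adam_beta1) * g
        v_state <- cfg$adam_beta2 * v_state + (1 - cfg$adam_beta2) * g^2
        mhat <- m_state / (1 - cfg$adam_beta1^step_t)
        vhat <- v_state / (1 - cfg$adam_beta2^step_t)
        flat <- flat - lrs * mhat / (sqrt(vhat) + cfg$adam_eps)
        par_now <- par_unflatten(flat, model$par)
        ep_loss <- ep_loss + step$loss * length(idx)
      }
      ep_loss <- ep_loss / n

      vl <- NA_real_; va <- NA_real_
      if (!is.null(valid_ds) && n_trials(valid_ds) > 0L) {
        snap <- model
        snap$par <- par_now
        snap$buffers <- buffers
        pred <- predict_epochs(snap, valid_ds)
        vl <- cross_entropy(one_hot(valid_ds$labels, mcfg$N_C),
                            pred$log_prob)
        va <- mean(pred$labels == valid_ds$labels)
        if (va > best$acc) {
          best$acc <- va; best$epoch <- epoch
          best$flat <- flat; best$buffers <- buffers
        }
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_loss,
        valid_loss = vl, valid_accuracy = va)
      if (verbose)
        message(sprintf("epoch %3d  train_loss %.4f  valid_acc %s",
                        epoch, ep_loss,
                        ifelse(is.na(va), "-", sprintf("%.3f", va))))
    }
  })

  history <- do.call(rbind, history)
  if (is.null(valid_ds) || n_trials(valid_ds) == 0L) {
    best$flat <- flat; best$buffers <- buffers
    best$epoch <- cfg$max_epochs
  }
  attr(history, "best_epoch") <- best$epoch
  out <- model
  out$par <- par_unflatten(best$flat, model$par)
  out$buffers <- best$buffers
  out$trained <- TRUE
  list(model = out, history = history)
}

#' Evaluate a model on a test set
#'
#' @param model an `fbcnn_model`.
#' @param test_ds an `eeg_epochs` with at least one trial.
#' @return list with `accuracy` (fraction of correctly argmax-classified
#'   trials) and `confusion`, an `N_C x N_C` table whose rows are true
#'   classes and columns predictions (row sums equal per-class counts).
#' @export
evaluate <- function(model, test_ds) {
  if (n_trials(test_ds) == 0L)
    stop("empty test set", call. = FALSE)
  pred <- predict_epochs(model, test_ds)
  lv <- test_ds$class_names
  confusion <- table(
    truth = factor(lv[test_ds$labels + 1L], levels = lv),
    predicted = factor(lv[pred$labels + 1L], levels = lv))
  list(accuracy = mean(pred$labels == test_ds$labels),
       confusion = confusion)
}
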