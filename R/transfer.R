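#' Pretrain a coarse model on pooled source subjects
#'
#' Concatenates the trials of all source subjects, carves out an internal
#' stratified validation split (10% by default) for checkpoint selection,
#' and trains a fresh network on the remainder. The result is the "coarse"
#' model that cross-subject fine-tuning starts from.
#'
#' @param source_datasets list of `eeg_epochs` sharing channels, trial
#'   length, sampling rate and class set.
#' @param model_cfg a [model_config()] for the network to train.
#' @param cfg a [train_config()].
#' @param valid_fraction fraction of pooled trials held out for validation.
#' @param init,init_seed weight initialization passed to [build_model()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (the coarse model) and `history`.
#' @export
pretrain_pooled <- function(source_datasets, model_cfg,
                            cfg = train_config(), valid_fraction = 0.1,
                            init = "paper", init_seed = 1L,
                            verbose = FALSE) {
  stopifnot(length(source_datasets) >= 1L)
  pooled <- concat_epochs(source_datasets, subject_id = "pooled")
  parts <- split_dataset(pooled,
                         fractions = c(1 - valid_fraction, valid_fraction, 0),
                         seed = cfg$seed, stratified = TRUE)
  model <- build_model(model_cfg, init = init, seed = init_seed)
  fit <- train(model, parts$train, parts$valid, cfg, verbose = verbose)
  fit$model$subject_id <- "pooled"
  fit
}

#' Fine-tune a coarse model on a target subject
#'
#' Continues training from the coarse weights on the union of the target
#' subject's calibration trials and a seeded random selection of source
#' trials (`round(mix_ratio * n_target)` of them), mixing the open data back
#' in so the small target set does not immediately overwrite the general
#' solution. Learning rates are scaled per subnetwork by the layered policy
#' (feature extraction 1/27, feature reduction 1/9, classifier 1/3 of the
#' base rate by default). The coarse model object is left untouched.
#'
#' @param coarse a trained `fbcnn_model`.
#' @param target_train `eeg_epochs` of the target subject's calibration
#'   trials.
#' @param mix_sources list of source `eeg_epochs` to draw mixed-in trials
#'   from (may be empty or `NULL` together with `mix_ratio = 0`).
#' @param mix_ratio source trials drawn per target trial.
#' @param policy a [layered_lr_policy()].
#' @param cfg a [train_config()]; `cfg$seed` also governs the mixing draw.
#' @param valid_ds optional monitoring set; when supplied the
#'   best-validation checkpoint is returned, otherwise the final epoch.
#' @param verbose print per-epoch progress.
#' @return list with `model` (fine-tuned) and `history`.
#' @export
fine_tune <- function(coarse, target_train, mix_sources = NULL,
                      mix_ratio = 1, policy = layered_lr_policy(),
                      cfg = train_config(), valid_ds = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(coarse, "fbcnn_model"))
  if (n_trials(target_train) == 0L)
    stop("empty target training set", call. = FALSE)
  if (mix_ratio < 0) stop("mix_ratio must be >= 0", call. = FALSE)

  n_mix <- round(mix_ratio * n_trials(target_train))
  train_set <- target_train
  if (n_mix > 0) {
    if (is.null(mix_sources) || !length(mix_sources))
      stop("mix_ratio > 0 but no mix_sources supplied", call. = FALSE)
    pool <- concat_epochs(mix_sources, subject_id = "mix")
    idx <- withr::with_seed(cfg$seed,
                            sample.int(n_trials(pool),
                                       min(n_mix, n_trials(pool))))
    train_set <- concat_epochs(list(target_train, subset_epochs(pool, idx)),
                               subject_id = target_train$subject_id)
  }
  train(coarse, train_set, valid_ds, cfg, lr_policy = policy,
        verbose = verbose)
}

#' Fine-tuning with small calibration sets
#'
#' For each requested calibration-set size `n` and each seed, draws `n`
#' stratified trials from the target subject's training data, fine-tunes a
#' fresh copy of the coarse model on them (with source mixing), and scores
#' the result on the target test set. Reports per-size mean and standard
#' deviation across seeds, the learning curve of subject adaptation.
#'
#' @param coarse a trained `fbcnn_model`.
#' @param target_train,target_test `eeg_epochs` of the target subject.
#' @param sample_sizes calibration-set sizes to evaluate.
#' @param seeds integer seeds; each seed re-draws the subsample and re-runs
#'   fine-tuning.
#' @param mix_sources,mix_ratio,policy,cfg as in [fine_tune()].
#' @return list with `summary` (tibble: `n`, `mean_accuracy`, `sd_accuracy`,
#'   `n_seeds`) and `runs` (tibble of every `(n, seed, accuracy)`).
#' @export
small_sample_protocol <- function(coarse, target_train, target_test,
                                  sample_sizes = c(10L, 20L, 50L, 100L),
                                  seeds = 1:5, mix_sources = NULL,
                                  mix_ratio = 1,
                                  policy = layered_lr_policy(),
                                  cfg = train_config()) {
  if (max(sample_sizes) > n_trials(target_train))
    stop("largest sample size (", max(sample_sizes),
         ") exceeds target training trials (", n_trials(target_train), ")",
         call. = FALSE)
  runs <- list()
  for (n in sample_sizes) {
    for (sd_ in seeds) {
      sub <- stratified_subsample(target_train, n, seed = sd_)
      cfg_run <- cfg
      cfg_run$seed <- sd_
      fit <- fine_tune(coarse, sub, mix_sources = mix_sources,
                       mix_ratio = mix_ratio, policy = policy,
                       cfg = cfg_run)
      acc <- evaluate(fit$model, target_test)$accuracy
      runs[[length(runs) + 1L]] <-
        tibble::tibble(n = n, seed = sd_, accuracy = acc)
    }
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(split(runs, runs$n), function(g)
    tibble::tibble(n = g$n[1], mean_accuracy = mean(g$accuracy),
                   sd_accuracy = stats::sd(g$accuracy),
                   n_seeds = nrow(g))))
  summary <- summary[order(summary$n), ]
  list(summary = summary, runs = runs)
}
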