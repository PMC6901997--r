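#' Construct an epoched EEG dataset
#'
#' An `eeg_epochs` object holds a stack of fixed-length multichannel EEG
#' trials (`n_trials x n_channels x n_times`, microvolts) together with
#' integer class labels and recording metadata. It is the common currency of
#' the whole package: the preprocessing chain, the network, and the simulator
#' all consume and produce this container.
#'
#' Labels are zero-based (`0 .. n_classes - 1`), matching the convention of
#' the deep-learning EEG literature; `class_names[label + 1]` gives the
#' human-readable class.
#'
#' @param data numeric array `[n_trials, n_channels, n_times]` in microvolts.
#' @param labels integer vector of length `n_trials`, values in
#'   `0 .. length(class_names) - 1`.
#' @param class_names character vector naming the classes, in label order.
#' @param sampling_rate_hz positive sampling rate in Hz.
#' @param channel_names optional character vector of unique channel names;
#'   defaults to `"C1" .. "Cn"`.
#' @param unit amplitude unit string, expected `"uV"`.
#' @param subject_id identifier of the recorded subject.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, labels, class_names, sampling_rate_hz,
                       channel_names = NULL, unit = "uV",
                       subject_id = "S01") {
  data <- unname(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-axis array [n_trials, n_channels, n_times]",
         call. = FALSE)
  if (is.null(channel_names))
    channel_names <- paste0("C", seq_len(dim(data)[2]))
  ds <- structure(
    list(
      data = data,
      labels = as.integer(labels),
      class_names = as.character(class_names),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      channel_names = as.character(channel_names),
      unit = unit,
      subject_id = as.character(subject_id)
    ),
    class = "eeg_epochs"
  )
  validate_epochs(ds)
  ds
}

#' Validate an epoched dataset against its invariants
#'
#' Checks the structural invariants of [eeg_epochs()]: positive sampling
#' rate, unique non-empty channel names matching the channel axis, labels
#' indexing `class_names`, label vector aligned with the trial axis, and a
#' fully finite data array. Called by every constructor and reader; useful
#' directly after manual surgery on a dataset.
#'
#' @param ds an `eeg_epochs` object.
#' @return `ds`, invisibly; otherwise an error naming the failed invariant.
#' @export
validate_epochs <- function(ds) {
  d <- dim(ds$data)
  if (!is.numeric(ds$sampling_rate_hz) || length(ds$sampling_rate_hz) != 1L ||
      !is.finite(ds$sampling_rate_hz) || ds$sampling_rate_hz <= 0)
    stop("invariant violated: sampling_rate_hz must be a positive number",
         call. = FALSE)
  if (anyDuplicated(ds$channel_names) || any(!nzchar(ds$channel_names)))
    stop("invariant violated: channel_names must be unique and non-empty",
         call. = FALSE)
  if (d[2] != length(ds$channel_names))
    stop("invariant violated: n_channels (", d[2],
         ") != length(channel_names) (", length(ds$channel_names), ")",
         call. = FALSE)
  if (length(ds$labels) != d[1])
    stop("invariant violated: length(labels) (", length(ds$labels),
         ") != n_trials (", d[1], ")", call. = FALSE)
  if (length(ds$labels) &&
      (min(ds$labels) < 0L || max(ds$labels) >= length(ds$class_names)))
    stop("invariant violated: labels must lie in 0..",
         length(ds$class_names) - 1L, " (found ",
         paste(range(ds$labels), collapse = ".."), ")", call. = FALSE)
  if (anyNA(ds$data) || any(!is.finite(ds$data)))
    stop("invariant violated: data contains non-finite values", call. = FALSE)
  invisible(ds)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
    x$subject_id, d[1], d[2], d[3], x$sampling_rate_hz))
  tab <- table(factor(x$class_names[x$labels + 1L], levels = x$class_names))
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Number of trials in a dataset
#' @param ds an `eeg_epochs` object.
#' @return integer trial count.
#' @export
n_trials <- function(ds) dim(ds$data)[1]

# container format: magic, 4-byte header length, JSON header, float64 payload
EPOCHS_MAGIC <- charToRaw("EEGEPO01")

#' Write an epoched dataset to a single container file
#'
#' The interchange format is one self-describing binary file: an 8-byte
#' magic string, a JSON metadata block (dimensions, labels, class names,
#' sampling rate, channel names, unit, subject id), then the data array as
#' little-endian IEEE-754 doubles in R's column-major trial/channel/time
#' order. Reading the file back with [read_epochs()] reproduces the dataset
#' bit-exactly.
#'
#' @param ds a valid `eeg_epochs` object.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(ds, path) {
  validate_epochs(ds)
  header <- jsonlite::toJSON(list(
    format = "eeg-epochs", version = 1L,
    dim = dim(ds$data),
    labels = ds$labels,
    class_names = ds$class_names,
    sampling_rate_hz = ds$sampling_rate_hz,
    channel_names = ds$channel_names,
    unit = ds$unit,
    subject_id = ds$subject_id
  ), auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(EPOCHS_MAGIC, con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(as.vector(ds$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read an epoched dataset from a container file
#'
#' Counterpart of [write_epochs()]. The returned dataset is validated
#' against the `eeg_epochs` invariants.
#'
#' @param path file produced by [write_epochs()] (or conforming to the
#'   documented container layout).
#' @return an `eeg_epochs` object.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = length(EPOCHS_MAGIC))
  if (!identical(magic, EPOCHS_MAGIC))
    stop("format error: not an eeg-epochs container: ", path, call. = FALSE)
  hlen <- readBin(con, "integer", size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0L)
    stop("format error: corrupt header length", call. = FALSE)
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  req <- c("dim", "labels", "class_names", "sampling_rate_hz",
           "channel_names", "unit", "subject_id")
  missing <- setdiff(req, names(header))
  if (length(missing))
    stop("format error: header missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  d <- as.integer(header$dim)
  n <- prod(d)
  vals <- readBin(con, "double", n = n + 1L, size = 8L, endian = "little")
  if (length(vals) != n)
    stop("shape mismatch: payload has ", length(vals),
         " values, header promises ", n, call. = FALSE)
  eeg_epochs(array(vals, dim = d),
             labels = header$labels,
             class_names = header$class_names,
             sampling_rate_hz = header$sampling_rate_hz,
             channel_names = header$channel_names,
             unit = header$unit,
             subject_id = header$subject_id)
}

#' Subset trials of a dataset
#' @param ds an `eeg_epochs` object.
#' @param idx integer vector of trial indices (1-based).
#' @return an `eeg_epochs` with the selected trials, order preserved.
#' @export
subset_epochs <- function(ds, idx) {
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_trials(ds)))
    stop("trial index out of range", call. = FALSE)
  out <- ds
  out$data <- ds$data[idx, , , drop = FALSE]
  out$labels <- ds$labels[idx]
  out
}

#' Concatenate datasets along the trial axis
#'
#' All datasets must agree on channel count, trial length, sampling rate and
#' class set. Used for pooled cross-subject pretraining and for mixing source
#' trials into fine-tuning sets.
#'
#' @param ... `eeg_epochs` objects (or a single list of them).
#' @param subject_id subject identifier of the pooled result.
#' @return an `eeg_epochs` holding all trials in argument order.
#' @export
concat_epochs <- function(..., subject_id = "pooled") {
  dss <- list(...)
  if (length(dss) == 1L && !inherits(dss[[1]], "eeg_epochs")) dss <- dss[[1]]
  stopifnot(length(dss) >= 1L)
  ref <- dss[[1]]
  for (i in seq_along(dss)) {
    ds <- dss[[i]]
    if (!identical(dim(ds$data)[2:3], dim(ref$data)[2:3]) ||
        !identical(ds$class_names, ref$class_names) ||
        !isTRUE(all.equal(ds$sampling_rate_hz, ref$sampling_rate_hz)))
      stop("dataset ", i, " (subject ", ds$subject_id,
           ") is incompatible with dataset 1 (channels/times/classes/rate)",
           call. = FALSE)
  }
  eeg_epochs(
    data = do.call(abind3, lapply(dss, function(d) d$data)),
    labels = unlist(lapply(dss, function(d) d$labels)),
    class_names = ref$class_names,
    sampling_rate_hz = ref$sampling_rate_hz,
    channel_names = ref$channel_names,
    unit = ref$unit,
    subject_id = subject_id
  )
}

# bind 3-axis arrays along the first axis
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Split a dataset into train / validation / test subsets
#'
#' Trials are partitioned at the requested proportions after a seeded
#' shuffle; the three parts are disjoint and exhaustive. With
#' `stratified = TRUE` the split is performed independently within each
#' class (ties broken by the seeded within-class shuffle), so per-class
#' counts deviate from exact proportionality by less than one trial.
#'
#' @param ds an `eeg_epochs` object.
#' @param fractions numeric triple `(train, valid, test)`, each `>= 0`,
#'   summing to 1.
#' @param seed integer seed controlling the shuffle; identical seeds give
#'   identical index sets.
#' @param stratified preserve per-class proportions within each part.
#' @return named list of `eeg_epochs`: `train`, `valid`, `test` (empty parts
#'   have zero trials).
#' @export
split_dataset <- function(ds, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                          stratified = TRUE) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must be three nonnegative numbers summing to 1",
         call. = FALSE)
  n <- n_trials(ds)
  nonzero <- sum(fractions > 0)
  part_of <- function(idx) {
    # cumulative rounding keeps every part within 1 trial of proportionality
    m <- length(idx)
    cuts <- diff(c(0L, round(cumsum(fractions) * m)))
    rep.int(seq_len(3L), cuts)[seq_len(m)]
  }
  assign <- integer(n)
  withr::with_seed(seed, {
    if (stratified) {
      for (k in seq_along(ds$class_names) - 1L) {
        idx <- which(ds$labels == k)
        if (length(idx) < nonzero)
          stop("class '", ds$class_names[k + 1L], "' has ", length(idx),
               " trials, fewer than the ", nonzero,
               " nonzero splits requested under stratification",
               call. = FALSE)
        assign[sample(idx)] <- part_of(idx)
      }
    } else {
      if (n < nonzero)
        stop("fewer trials (", n, ") than nonzero splits", call. = FALSE)
      assign[sample.int(n)] <- part_of(seq_len(n))
    }
  })
  list(train = subset_epochs(ds, which(assign == 1L)),
       valid = subset_epochs(ds, which(assign == 2L)),
       test  = subset_epochs(ds, which(assign == 3L)))
}

#' Draw a stratified subsample of trials
#'
#' Selects `n` trials with per-class counts as close to balanced proportions
#' as rounding allows, by seeded shuffle within each class. Used by the
#' small-calibration-set transfer protocol.
#'
#' @param ds an `eeg_epochs` object.
#' @param n total number of trials to draw (`n >=` number of classes).
#' @param seed integer seed.
#' @return an `eeg_epochs` with `n` trials.
#' @export
stratified_subsample <- function(ds, n, seed = 1L) {
  ncl <- length(ds$class_names)
  if (n < ncl)
    stop("n = ", n, " is smaller than the number of classes (", ncl, ")",
         call. = FALSE)
  if (n > n_trials(ds))
    stop("n = ", n, " exceeds available trials (", n_trials(ds), ")",
         call. = FALSE)
  counts <- diff(c(0L, round(cumsum(rep(n / ncl, ncl)))))
  idx <- withr::with_seed(seed, {
    unlist(lapply(seq_len(ncl) - 1L, function(k) {
      pool <- which(ds$labels == k)
      if (length(pool) < counts[k + 1L])
        stop("class '", ds$class_names[k + 1L],
             "' has too few trials for a stratified draw of ", n,
             call. = FALSE)
      sample(pool, counts[k + 1L])
    }))
  })
  subset_epochs(ds, sort(idx))
}
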