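#' Labelled point-sample dataset
#'
#' The classifiers' unit of input is a point-sample: the channel-vector of
#' one epoch at one time point within a region. Spontaneous vectors are the
#' positive class (`label = 1`), ERP-bearing vectors the negative class
#' (`label = 0`).
#'
#' @param features Numeric matrix, samples x channels (µV).
#' @param label Integer vector of 0/1 labels (1 = spontaneous/positive).
#' @param trial_id Integer vector, originating trial of each sample.
#' @param time_ms Numeric vector, sample time within the epoch.
#' @param splits Optional list of disjoint index vectors `train`,
#'   `validation`, `test`.
#' @return An object of class `erp_dataset`.
#' @export
erp_dataset <- function(features, label, trial_id, time_ms, splits = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(label) == n, length(trial_id) == n, length(time_ms) == n,
            all(label %in% c(0L, 1L)))
  structure(list(features = features, label = as.integer(label),
                 trial_id = as.integer(trial_id), time_ms = time_ms,
                 splits = splits),
            class = "erp_dataset")
}

#' @export
print.erp_dataset <- function(x, ...) {
  cat(sprintf("<erp_dataset> %d samples x %d features, %d positive / %d negative\n",
              nrow(x$features), ncol(x$features),
              sum(x$label == 1L), sum(x$label == 0L)))
  if (!is.null(x$splits))
    cat(sprintf("  splits: %s\n",
                paste(sprintf("%s=%d", names(x$splits),
                              lengths(x$splits)), collapse = ", ")))
  invisible(x)
}

# Sample indices of an epoch whose times fall in [window[1], window[2]],
# widened symmetrically by one sample per side while it holds fewer than
# `need` points.
window_sample_indices <- function(epoch, window, need) {
  tt <- epoch_times(epoch)
  idx <- which(tt >= window[1L] & tt <= window[2L])
  if (length(idx) == 0L)
    idx <- nearest_sample(epoch, mean(window), clamp = TRUE)
  widened <- FALSE
  while (length(idx) < need) {
    lo <- min(idx); hi <- max(idx)
    if (lo == 1L && hi == length(tt))
      stop("epoch too short for ", need, " distinct sample points")
    idx <- seq(max(1L, lo - 1L), min(length(tt), hi + 1L))
    widened <- TRUE
  }
  if (widened)
    message("sampling window widened to ", length(idx),
            " samples to supply ", need, " distinct points")
  idx
}

#' Build a balanced point-sample dataset from paired epochs
#'
#' For each trial, `pairs_per_trial` distinct time points are chosen at
#' random (without replacement) within the latency window; at each chosen
#' point the spontaneous epoch's channel-vector is emitted as a positive
#' sample and the matched ERP-bearing epoch's vector as a negative sample.
#' Positives and negatives are therefore exactly balanced (1:1). When the
#' window holds fewer distinct samples than requested it is widened
#' symmetrically by one sample per side, with a message.
#'
#' @param noise_epochs List of spontaneous `eeg_epoch`s.
#' @param erp_epochs Matched list of ERP-bearing epochs (same trials, same
#'   geometry).
#' @param region A `region_spec`; features are the region's channels.
#' @param window Length-2 numeric (ms), the candidate-latency range
#'   (default 162–178 ms for a 170 ms N170).
#' @param pairs_per_trial Number of positive/negative pairs per trial
#'   (default 6).
#' @param seed Optional seed for the point selection.
#' @return An `erp_dataset` (without splits).
#' @export
extract_point_samples <- function(noise_epochs, erp_epochs, region,
                                  window = c(162, 178), pairs_per_trial = 6,
                                  seed = NULL) {
  if (length(noise_epochs) != length(erp_epochs) || length(noise_epochs) == 0L)
    stop("'noise_epochs' and 'erp_epochs' must be matched non-empty lists")
  if (pairs_per_trial < 1L) stop("'pairs_per_trial' must be >= 1")
  if (diff(window) < 0) stop("'window' must be ordered")
  run <- function() {
    rows <- region_rows(noise_epochs[[1L]], region)
    feats <- list(); lab <- list(); tid <- list(); tms <- list()
    for (i in seq_along(noise_epochs)) {
      idx <- window_sample_indices(noise_epochs[[i]], window, pairs_per_trial)
      pick <- if (length(idx) > pairs_per_trial)
        sort(sample(idx, pairs_per_trial)) else idx
      tt <- epoch_times(noise_epochs[[i]])[pick]
      pos <- t(noise_epochs[[i]]$data[rows, pick, drop = FALSE])
      neg <- t(erp_epochs[[i]]$data[rows, pick, drop = FALSE])
      feats[[i]] <- rbind(pos, neg)
      lab[[i]] <- rep(c(1L, 0L), each = length(pick))
      tid[[i]] <- rep(i, 2L * length(pick))
      tms[[i]] <- rep(tt, 2L)
    }
    erp_dataset(do.call(rbind, feats), unlist(lab), unlist(tid), unlist(tms))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Build a point-sample dataset from two windows of the same epochs
#'
#' Variant for paradigms where the baseline and the component live in the
#' same trial (e.g. P50 paired-click epochs of 100 ms: positives from
#' 0–16 ms, negatives from 42–58 ms). Each trial contributes
#' `pairs_per_trial` positive vectors from `positive_window` and the same
#' number of negative vectors from `negative_window`.
#'
#' @param epochs List of `eeg_epoch`s containing the component.
#' @param region A `region_spec`.
#' @param positive_window,negative_window Length-2 numeric windows (ms).
#' @param pairs_per_trial Pairs per trial.
#' @param seed Optional selection seed.
#' @return An `erp_dataset` (without splits).
#' @export
extract_point_samples_windows <- function(epochs, region,
                                          positive_window = c(0, 16),
                                          negative_window = c(42, 58),
                                          pairs_per_trial = 4, seed = NULL) {
  if (length(epochs) == 0L) stop("'epochs' must be non-empty")
  if (pairs_per_trial < 1L) stop("'pairs_per_trial' must be >= 1")
  run <- function() {
    rows <- region_rows(epochs[[1L]], region)
    feats <- list(); lab <- list(); tid <- list(); tms <- list()
    for (i in seq_along(epochs)) {
      e <- epochs[[i]]
      pick1 <- window_sample_indices(e, positive_window, pairs_per_trial)
      pick0 <- window_sample_indices(e, negative_window, pairs_per_trial)
      if (length(pick1) > pairs_per_trial) pick1 <- sort(sample(pick1, pairs_per_trial))
      if (length(pick0) > pairs_per_trial) pick0 <- sort(sample(pick0, pairs_per_trial))
      tt <- epoch_times(e)
      feats[[i]] <- rbind(t(e$data[rows, pick1, drop = FALSE]),
                          t(e$data[rows, pick0, drop = FALSE]))
      lab[[i]] <- c(rep(1L, length(pick1)), rep(0L, length(pick0)))
      tid[[i]] <- rep(i, length(pick1) + length(pick0))
      tms[[i]] <- c(tt[pick1], tt[pick0])
    }
    erp_dataset(do.call(rbind, feats), unlist(lab), unlist(tid), unlist(tms))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Split a dataset into train / validation / test
#'
#' Stratified by label: within each class, indices are shuffled and
#' partitioned at the requested proportions (largest-remainder rounding),
#' so class balance is preserved in every split to within rounding.
#'
#' @param ds An `erp_dataset`.
#' @param ratios Length-3 non-negative numeric `(train, validation, test)`
#'   summing to 1 (default the 7:1.5:1.5 protocol).
#' @param seed Optional shuffle seed; fixed seed gives identical splits.
#' @return The dataset with `$splits` set.
#' @export
split_dataset <- function(ds, ratios = c(0.7, 0.15, 0.15), seed = NULL) {
  stopifnot(inherits(ds, "erp_dataset"))
  if (length(ratios) != 3L || any(ratios < 0))
    stop("'ratios' must be three non-negative numbers")
  if (abs(sum(ratios) - 1) > 1e-9) stop("'ratios' must sum to 1")
  run <- function() {
    parts <- list(train = integer(0), validation = integer(0),
                  test = integer(0))
    for (cl in unique(ds$label)) {
      idx <- sample(which(ds$label == cl))
      cuts <- diff(c(0L, round(cumsum(ratios) * length(idx))))
      at <- cumsum(cuts)
      parts$train <- c(parts$train, idx[seq_len(cuts[1L])])
      if (cuts[2L] > 0)
        parts$validation <- c(parts$validation, idx[(at[1L] + 1L):at[2L]])
      if (cuts[3L] > 0)
        parts$test <- c(parts$test, idx[(at[2L] + 1L):at[3L]])
    }
    parts
  }
  ds$splits <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ds
}

# features/labels of one split, validated non-empty
split_part <- function(ds, part) {
  if (is.null(ds$splits)) stop("dataset has no splits; call split_dataset()")
  idx <- ds$splits[[part]]
  if (length(idx) == 0L) stop("split '", part, "' is empty")
  list(x = ds$features[idx, , drop = FALSE], y = ds$label[idx])
}
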