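#' Continuous multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples (µV).
#' @param fs Sampling rate (Hz).
#' @param events Data frame with columns `time_ms` (stimulus times from the
#'   start of the recording) and `label`; sorted by time on construction.
#' @param channel_ids Channel labels; defaults to rownames.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, events = NULL, channel_ids = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_ids)) {
    channel_ids <- rownames(data)
    if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(data)))
  }
  rownames(data) <- channel_ids
  dur <- (ncol(data) - 1L) * 1000 / fs
  if (is.null(events))
    events <- data.frame(time_ms = numeric(0), label = character(0))
  if (!all(c("time_ms", "label") %in% names(events)))
    stop("'events' needs columns time_ms and label")
  if (any(events$time_ms < 0 | events$time_ms > dur))
    stop("event times must lie inside the recording")
  events <- events[order(events$time_ms), , drop = FALSE]
  structure(list(data = data, fs = fs, events = events,
                 channel_ids = channel_ids),
            class = "eeg_recording")
}

#' Zero-phase FIR high-pass filter
#'
#' Removes slow drift and DC from a continuous recording with a
#' windowed-sinc (Hamming) FIR high-pass filter applied forward-backward
#' (zero phase). The default order targets a 0.5 Hz transition band; pass
#' `order` to override. Orders longer than a third of the recording are
#' shortened with a warning so the forward-backward padding stays
#' well-posed.
#'
#' @param rec An `eeg_recording`.
#' @param cutoff Cutoff frequency (Hz), in `(0, fs/2)`.
#' @param transition Transition-band width (Hz) used to choose the order.
#' @param order Optional even FIR order (number of taps minus one).
#' @return The filtered `eeg_recording`.
#' @export
highpass_filter <- function(rec, cutoff, transition = 0.5, order = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (cutoff <= 0 || cutoff >= rec$fs / 2)
    stop("'cutoff' must lie strictly between 0 and the Nyquist frequency")
  if (is.null(order)) order <- ceiling(3.3 * rec$fs / transition)
  if (order %% 2 == 1) order <- order + 1L   # even order -> type I, integer delay
  n <- ncol(rec$data)
  if (order > floor(n / 3)) {
    order <- max(2L, floor(n / 3) - floor(n / 3) %% 2)
    warning("FIR order shortened to ", order, " for a recording of ", n,
            " samples")
  }
  h <- signal::fir1(order, cutoff / (rec$fs / 2), type = "high")
  out <- rec
  filtered <- t(apply(rec$data, 1L, function(x) signal::filtfilt(h, x)))
  if (nrow(rec$data) == 1L) filtered <- matrix(filtered, nrow = 1L)
  out$data <- filtered
  rownames(out$data) <- rec$channel_ids
  out
}

#' Rereference to linked mastoids
#'
#' Subtracts the sample-wise mean of the two mastoid channels from every
#' channel.
#'
#' @param rec An `eeg_recording`.
#' @param mastoid_channels Character vector of the two mastoid labels.
#' @return The rereferenced `eeg_recording`.
#' @export
rereference_linked_mastoids <- function(rec, mastoid_channels) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(mastoid_channels) != 2L)
    stop("exactly two mastoid channels are required")
  idx <- match(mastoid_channels, rec$channel_ids)
  if (anyNA(idx))
    stop("mastoid channel(s) missing: ",
         paste(mastoid_channels[is.na(idx)], collapse = ", "))
  ref <- colMeans(rec$data[idx, , drop = FALSE])
  out <- rec
  out$data <- sweep(rec$data, 2L, ref, "-")
  out
}

#' Extract stimulus-locked epochs from a continuous recording
#'
#' Cuts one epoch per event over the window `[pre, post)` ms around each
#' stimulus (half-open in sample space; nearest-sample mapping of the
#' event time). Events whose window would run outside the recording are
#' dropped with a warning reporting the count.
#'
#' @param rec An `eeg_recording` with events.
#' @param window Length-2 numeric `(pre, post)` in ms, `pre < post`
#'   (e.g. `c(-100, 200)`).
#' @return List of `eeg_epoch` objects with `t0 = window[1]`.
#' @export
extract_epochs <- function(rec, window) {
  stopifnot(inherits(rec, "eeg_recording"), length(window) == 2L,
            window[1L] < window[2L])
  n_samp <- window_n_samples(window[2L] - window[1L], rec$fs)
  if (n_samp < 2L) stop("epoch window must span at least 2 samples")
  total <- ncol(rec$data)
  epochs <- list()
  dropped <- 0L
  for (k in seq_len(nrow(rec$events))) {
    ev <- rec$events$time_ms[k]
    start <- as.integer(round((ev + window[1L]) * rec$fs / 1000)) + 1L
    if (start < 1L || start + n_samp - 1L > total) {
      dropped <- dropped + 1L
      next
    }
    epochs[[length(epochs) + 1L]] <-
      eeg_epoch(rec$data[, start:(start + n_samp - 1L), drop = FALSE],
                fs = rec$fs, t0 = window[1L], channel_ids = rec$channel_ids)
  }
  if (dropped > 0L)
    warning(dropped, " event(s) dropped: epoch window outside the recording")
  epochs
}

#' Baseline-correct an epoch
#'
#' Subtracts each channel's mean over the pre-stimulus baseline window
#' `[from, to)` ms from the whole epoch: a per-channel shift, never a
#' rescaling.
#'
#' @param epoch An `eeg_epoch`.
#' @param baseline Length-2 numeric `(from, to)` ms, inside the epoch.
#' @return The corrected `eeg_epoch`.
#' @export
baseline_correct <- function(epoch, baseline = c(-100, 0)) {
  stopifnot(inherits(epoch, "eeg_epoch"), length(baseline) == 2L)
  tt <- epoch_times(epoch)
  sel <- tt >= baseline[1L] & tt < baseline[2L]
  if (!any(sel)) stop("baseline window contains no samples of the epoch")
  out <- epoch
  out$data <- epoch$data - rowMeans(epoch$data[, sel, drop = FALSE])
  out
}

#' Decimate a recording by an integer factor
#'
#' Utility for bringing high-rate acquisitions down to a working rate
#' (anti-alias low-pass then keep every `factor`-th sample).
#'
#' @param rec An `eeg_recording`.
#' @param factor Integer decimation factor (>= 2).
#' @return The decimated `eeg_recording` (events retimed are unchanged in
#'   ms, since event times are stored in ms).
#' @export
decimate_recording <- function(rec, factor) {
  stopifnot(inherits(rec, "eeg_recording"))
  factor <- as.integer(factor)
  if (factor < 2L) stop("'factor' must be >= 2")
  out <- rec
  dec <- t(apply(rec$data, 1L, function(x)
    signal::decimate(x, factor, ftype = "fir")))
  out$data <- dec
  rownames(out$data) <- rec$channel_ids
  out$fs <- rec$fs / factor
  out
}
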