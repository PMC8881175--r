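#' Construct a stimulus-locked EEG epoch
#'
#' An epoch is one fixed-length, stimulus-locked multichannel EEG segment:
#' a channels-by-samples matrix of potentials in microvolts, together with
#' its sampling rate and the time of the first sample relative to stimulus
#' onset. Times are in milliseconds throughout the package; the time axis is
#' `t0 + (0:(n-1)) * 1000 / fs`.
#'
#' @param data Numeric matrix, channels x samples (µV).
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample relative to the stimulus (ms);
#'   non-positive when a pre-stimulus baseline is present.
#' @param channel_ids Character vector of channel labels, one per row.
#'   Defaults to the matrix rownames or `"ch1"`, `"ch2"`, ...
#' @return An object of class `eeg_epoch`.
#' @examples
#' e <- eeg_epoch(matrix(0, 4, 51), fs = 256, t0 = 0)
#' epoch_times(e)[1:3]
#' @export
eeg_epoch <- function(data, fs, t0 = 0, channel_ids = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("epoch data must be numeric")
  if (nrow(data) < 1L || ncol(data) < 2L)
    stop("an epoch needs at least 1 channel and 2 samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive sampling rate in Hz")
  if (is.null(channel_ids)) {
    channel_ids <- rownames(data)
    if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_ids) != nrow(data))
    stop("'channel_ids' must have one label per channel")
  rownames(data) <- channel_ids
  structure(
    list(data = data, fs = fs, t0 = t0, channel_ids = channel_ids),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  tt <- epoch_times(x)
  cat(sprintf("<eeg_epoch> %d channels x %d samples, fs = %g Hz, t = [%g, %g] ms\n",
              nrow(x$data), ncol(x$data), x$fs, tt[1L], tt[length(tt)]))
  invisible(x)
}

#' Time axis of an epoch
#'
#' @param epoch An `eeg_epoch`.
#' @return Numeric vector of sample times in ms, stimulus-relative.
#' @export
epoch_times <- function(epoch) {
  epoch$t0 + (seq_len(ncol(epoch$data)) - 1L) * 1000 / epoch$fs
}

#' Map a stimulus-relative time to the nearest sample index
#'
#' Nearest-sample rounding is the single time-to-sample convention used
#' throughout the package.
#'
#' @param epoch An `eeg_epoch`.
#' @param time_ms Time(s) in ms.
#' @param clamp If `TRUE`, indices are clamped into the epoch; otherwise an
#'   out-of-range time is an error.
#' @return Integer sample index (1-based).
#' @export
nearest_sample <- function(epoch, time_ms, clamp = FALSE) {
  idx <- as.integer(round((time_ms - epoch$t0) * epoch$fs / 1000)) + 1L
  n <- ncol(epoch$data)
  if (clamp) {
    idx <- pmin(pmax(idx, 1L), n)
  } else if (any(idx < 1L | idx > n)) {
    stop("time outside the epoch")
  }
  idx
}

#' Parametric monophasic ERP template
#'
#' Describes an ERP component by a Gaussian bump
#' \eqn{f(t) = \exp(-(t - \tau)^2 / (2\theta^2))} with latency `tau`,
#' width `theta`, amplitude `sigma` and polarity `sign`. The width `theta`
#' is expressed in samples at the epoch's sampling rate (at 256 Hz,
#' `theta = 8` is an effective width of about 31 ms, consistent with N170
#' morphology); latency is in stimulus-relative ms.
#'
#' @param tau Latency (ms).
#' @param theta Waveform width (samples); must be positive.
#' @param sigma Peak amplitude (µV); non-negative.
#' @param sign Polarity, `+1` or `-1`.
#' @return An object of class `erp_template`.
#' @export
erp_template <- function(tau, theta, sigma = 1, sign = 1) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stop("'theta' must be a positive width in samples")
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (!sign %in% c(-1, 1)) stop("'sign' must be +1 or -1")
  structure(list(tau = tau, theta = theta, sigma = sigma, sign = sign),
            class = "erp_template")
}

#' Evaluate the unit-amplitude template waveform on a time grid
#'
#' \eqn{f(t) = \exp(-(t - \tau)^2 / (2\theta^2))} with the time difference
#' converted from ms to samples, so that `theta` is in samples.
#'
#' @param tau Latency (ms).
#' @param theta Width (samples).
#' @param times Time grid (ms); non-empty.
#' @param fs Sampling rate (Hz), used to convert ms to samples.
#' @return Numeric vector of waveform values in (0, 1], peaking at the grid
#'   point nearest `tau`.
#' @examples
#' template_waveform(170, 8, times = seq(0, 200, length.out = 52), fs = 256)
#' @export
template_waveform <- function(tau, theta, times, fs) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stop("'theta' must be a positive width in samples")
  if (length(times) == 0L) stop("'times' must be non-empty")
  dt_samples <- (times - tau) * fs / 1000
  exp(-dt_samples^2 / (2 * theta^2))
}

#' Electrode region specification
#'
#' Names a brain region and the subset of channel labels that cover it
#' (e.g. 4 electrodes over left parietal cortex). The estimation framework
#' treats the ERP component as identical across the region's channels.
#'
#' @param name Region label.
#' @param channels Character vector of channel ids; non-empty.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, channels) {
  if (length(channels) == 0L) stop("a region needs at least one channel")
  structure(list(name = name, channels = as.character(channels)),
            class = "region_spec")
}

region_rows <- function(epoch, region) {
  idx <- match(region$channels, epoch$channel_ids)
  if (anyNA(idx))
    stop("region channels missing from epoch: ",
         paste(region$channels[is.na(idx)], collapse = ", "))
  idx
}

#' Superpose an ERP template on an epoch
#'
#' Implements the simplified linear generative model
#' \eqn{E = \sigma \, s(\tau) + X}: the template waveform, scaled by
#' `sigma` and the polarity, is added identically to every channel of the
#' region; channels outside the region are untouched.
#'
#' @param epoch An `eeg_epoch` (the spontaneous EEG term `X`).
#' @param template An `erp_template` whose latency lies inside the epoch.
#' @param region A `region_spec`; defaults to all channels.
#' @return A new `eeg_epoch` containing the component.
#' @export
superpose <- function(epoch, template, region = NULL) {
  stopifnot(inherits(epoch, "eeg_epoch"), inherits(template, "erp_template"))
  tt <- epoch_times(epoch)
  if (template$tau < tt[1L] || template$tau > tt[length(tt)])
    stop("template latency lies outside the epoch")
  if (is.null(region)) region <- region_spec("all", epoch$channel_ids)
  rows <- region_rows(epoch, region)
  wave <- template$sign * template$sigma *
    template_waveform(template$tau, template$theta, tt, epoch$fs)
  out <- epoch
  out$data[rows, ] <- sweep(epoch$data[rows, , drop = FALSE], 2L, wave, "+")
  out
}

#' Signal-to-noise ratio in decibels
#'
#' EEG signal strength is amplitude-like (µV), so the ratio follows the
#' "20 log" rule: \eqn{\mathrm{SNR} = 20 \log_{10}(\delta_s / \delta_n)}.
#' Both strengths are on the same µV scale; the package reports RMS over
#' the analysis window for each (signal RMS of the scaled template, noise
#' RMS of the spontaneous epoch), but any consistent amplitude measure may
#' be passed.
#'
#' @param signal_strength,noise_strength Positive amplitude measures (µV).
#' @return SNR in dB.
#' @examples
#' snr_db(10, 10)   # 0 dB
#' snr_db(10, 1)    # 20 dB
#' @export
snr_db <- function(signal_strength, noise_strength) {
  if (any(signal_strength <= 0) || any(noise_strength <= 0))
    stop("strengths must be positive")
  20 * log10(signal_strength / noise_strength)
}

#' Number of samples in a half-open time window
#'
#' Windows are half-open in sample space: a window of `len_ms` starting
#' at a sample contains every sample time in `[0, len_ms)`, i.e.
#' `ceiling(len_ms * fs / 1000)` samples (200 ms at 256 Hz holds 52
#' samples, the last at 199.2 ms).
#'
#' @param len_ms Window length (ms).
#' @param fs Sampling rate (Hz).
#' @return Integer sample count.
#' @export
window_n_samples <- function(len_ms, fs) {
  as.integer(ceiling(len_ms * fs / 1000 - 1e-9))
}

#' Root-mean-square amplitude
#'
#' @param x Numeric vector or matrix.
#' @return RMS of all elements (µV scale for EEG data).
#' @export
rms <- function(x) sqrt(mean(x^2))
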