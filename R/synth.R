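#' Spontaneous-EEG noise model
#'
#' Parameters of the synthetic spontaneous EEG generator. Epochs are drawn
#' as 1/f^alpha colored Gaussian noise, mixed across channels through a
#' shared source to obtain a target pairwise correlation, scaled by a
#' per-trial lognormal amplitude factor (resting EEG is bursty: quiet
#' trials alternate with high-amplitude ones, and this trial-to-trial
#' heterogeneity is what lets a classifier sit near 90% accuracy on
#' strong components while still detecting weak ones on quiet trials),
#' and offset by a small per-epoch, per-channel DC drift: spontaneous EEG
#' is only approximately a zero-mean stationary process, and the drift
#' keeps the generator honest about that.
#'
#' @param n_channels Number of channels.
#' @param fs Sampling rate (Hz).
#' @param spectral_exponent Slope alpha of the 1/f^alpha power spectrum;
#'   `0` gives white noise. Default 1 (pink), the canonical broadband EEG
#'   background slope.
#' @param channel_std Per-channel standard deviation (µV), pooled over
#'   trials; positive.
#' @param cross_channel_corr Pairwise channel correlation in `[0, 1)`;
#'   default 0.3, a typical value for electrodes a few cm apart.
#' @param trial_std_spread Log-scale standard deviation of the per-trial
#'   amplitude factor (default 0.6: one-sigma trials are about 1.8x
#'   quieter or louder than the median; 0 disables the heterogeneity).
#'   The factor is normalized so the pooled RMS stays `channel_std`.
#' @param dc_drift Half-width (µV) of the uniform per-epoch DC offset;
#'   default 1.
#' @param seed Optional integer seed; when set, generation is reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(n_channels, fs, spectral_exponent = 1,
                        channel_std = 7, cross_channel_corr = 0.3,
                        trial_std_spread = 0.6, dc_drift = 1, seed = NULL) {
  if (n_channels < 1L) stop("'n_channels' must be >= 1")
  if (channel_std <= 0) stop("'channel_std' must be positive")
  if (cross_channel_corr < 0 || cross_channel_corr >= 1)
    stop("'cross_channel_corr' must lie in [0, 1)")
  if (spectral_exponent < 0) stop("'spectral_exponent' must be >= 0")
  if (trial_std_spread < 0) stop("'trial_std_spread' must be >= 0")
  if (dc_drift < 0) stop("'dc_drift' must be >= 0")
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 spectral_exponent = spectral_exponent,
                 channel_std = channel_std,
                 cross_channel_corr = cross_channel_corr,
                 trial_std_spread = trial_std_spread,
                 dc_drift = dc_drift, seed = seed),
            class = "noise_model")
}

# One unit-variance 1/f^alpha trace of length n. Coloring is applied in the
# frequency domain and rescaled by the theoretical filter gain so the output
# has unit variance in expectation (not per-trace), preserving trial-to-trial
# power variability.
colored_trace <- function(n, alpha) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w)
  k <- 0:(n - 1L)
  f <- pmin(k, n - k)          # discrete frequency magnitude
  h <- c(0, 1 / f[-1L]^(alpha / 2))   # kill DC
  gain <- sqrt(mean(h^2))
  Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / n / gain
}

#' Generate synthetic spontaneous EEG epochs
#'
#' Draws `n_trials` stimulus-free epochs from a [noise_model()]. Each
#' channel is `sqrt(1 - rho) * independent + sqrt(rho) * shared` colored
#' noise (so the pairwise correlation is `rho`), scaled to `channel_std`
#' times the trial's lognormal amplitude factor
#' `exp(s Z - s^2)` (unit mean square, `s = trial_std_spread`), and
#' shifted by the per-epoch DC drift.
#'
#' @param model A `noise_model`.
#' @param n_trials Number of epochs (>= 1).
#' @param epoch_len Epoch length (ms); must give at least 2 samples.
#' @param t0 Time of the first sample relative to the (simulated) stimulus
#'   (ms); default 0.
#' @return List of `eeg_epoch` objects.
#' @examples
#' nm <- noise_model(4, fs = 256, channel_std = 8, seed = 1)
#' ep <- generate_spontaneous(nm, n_trials = 2, epoch_len = 200)
#' @export
generate_spontaneous <- function(model, n_trials, epoch_len, t0 = 0) {
  stopifnot(inherits(model, "noise_model"))
  if (n_trials < 1L) stop("'n_trials' must be >= 1")
  n <- window_n_samples(epoch_len, model$fs)
  if (n < 2L) stop("'epoch_len' must span at least 2 samples")
  gen <- function() {
    lapply(seq_len(n_trials), function(i) {
      shared <- colored_trace(n, model$spectral_exponent)
      rho <- model$cross_channel_corr
      data <- t(vapply(seq_len(model$n_channels), function(ch) {
        indep <- colored_trace(n, model$spectral_exponent)
        sqrt(1 - rho) * indep + sqrt(rho) * shared
      }, numeric(n)))
      s <- model$trial_std_spread
      trial_scale <- if (s > 0) exp(s * stats::rnorm(1) - s^2) else 1
      data <- data * model$channel_std * trial_scale
      if (model$dc_drift > 0)
        data <- data + stats::runif(model$n_channels,
                                    -model$dc_drift, model$dc_drift)
      eeg_epoch(data, fs = model$fs, t0 = t0)
    })
  }
  if (is.null(model$seed)) gen() else withr::with_seed(model$seed, gen())
}

#' Assemble a simulated single-trial ERP study
#'
#' Builds one condition set per amplitude level by superposing the Gaussian
#' ERP template on each spontaneous epoch, keeping the pure-noise epochs as
#' the sigma = 0 control (they provide the classifier's positive,
#' spontaneous-class samples). The per-trial ground truth (sigma, tau) is
#' stored alongside each condition.
#'
#' @param noise List of spontaneous `eeg_epoch` objects.
#' @param region A `region_spec`; the component is injected into these
#'   channels only.
#' @param tau True latency (ms), inside the epoch.
#' @param theta Template width (samples).
#' @param amplitudes Numeric vector of condition amplitudes (µV), non-empty.
#' @param sign Template polarity (+1/-1), default +1.
#' @return An object of class `erp_study`: list with `noise` (the control
#'   epochs), `conditions` (one entry per amplitude, each with `epochs` and
#'   a `truth` data frame), `region`, `tau`, `theta`, `sign`, `amplitudes`.
#' @export
build_simulated_study <- function(noise, region, tau, theta, amplitudes,
                                  sign = 1) {
  if (length(noise) == 0L) stop("'noise' must be a non-empty list of epochs")
  if (length(amplitudes) == 0L) stop("'amplitudes' must be non-empty")
  stopifnot(inherits(region, "region_spec"))
  conditions <- lapply(amplitudes, function(sigma) {
    tmpl <- erp_template(tau = tau, theta = theta, sigma = sigma, sign = sign)
    epochs <- if (sigma == 0) noise else
      lapply(noise, superpose, template = tmpl, region = region)
    truth <- data.frame(trial_id = seq_along(noise), sigma = sigma, tau = tau)
    list(sigma = sigma, epochs = epochs, truth = truth)
  })
  names(conditions) <- as.character(amplitudes)
  structure(list(noise = noise, conditions = conditions, region = region,
                 tau = tau, theta = theta, sign = sign,
                 amplitudes = amplitudes),
            class = "erp_study")
}

#' @export
print.erp_study <- function(x, ...) {
  cat(sprintf(
    "<erp_study> %d trials/condition, amplitudes {%s} uV, tau = %g ms, theta = %g samples, region '%s'\n",
    length(x$noise), paste(x$amplitudes, collapse = ", "), x$tau, x$theta,
    x$region$name))
  invisible(x)
}

#' Realized noise RMS of a study
#'
#' RMS amplitude of the spontaneous (sigma = 0) epochs over the region,
#' the noise-strength term of the SNR measure.
#'
#' @param study An `erp_study`.
#' @return Scalar RMS (µV).
#' @export
study_noise_rms <- function(study) {
  rows <- region_rows(study$noise[[1L]], study$region)
  rms(vapply(study$noise, function(e) rms(e$data[rows, , drop = FALSE]),
             numeric(1)))
}
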