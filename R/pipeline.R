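#' Default simulated-study run configuration
#'
#' The reference N170 simulation: 4-channel region, 256 Hz, 200 ms
#' epochs, pink (1/f) noise of 7 µV pooled per-channel std with 0.3
#' cross-channel correlation and bursty trial-to-trial amplitude
#' heterogeneity (`trial_std_spread = 0.6`), Gaussian template of width
#' 8 ms (`theta_ms = 8`, i.e.
#' about 2 samples at 256 Hz — an N170-like deflection of ~19 ms FWHM)
#' centered at 170 ms, amplitude levels 3/6/10/15 µV, 6 point-sample
#' pairs per trial from 162–178 ms (the ±theta window around the
#' latency), 7:1.5:1.5 stratified split, MLPNN classifier, latency search
#' over 130–200 ms, amplitude bounds 0–30 µV. The noise level is
#' calibrated so that the 15 µV condition is classified at roughly 90%
#' test accuracy. Override any field by name.
#'
#' @param ... Named overrides of the default fields.
#' @return A named list (class `run_config`).
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_trials = 100L,
    n_channels = 4L,
    fs = 256,
    epoch_len = 200,
    channel_std = 7,
    spectral_exponent = 1,
    cross_channel_corr = 0.3,
    trial_std_spread = 0.6,
    dc_drift = 1,
    tau = 170,
    theta_ms = 8,
    sign = 1,
    amplitudes = c(3, 6, 10, 15),
    sample_window = c(162, 178),
    pairs_per_trial = 6L,
    split_ratios = c(0.7, 0.15, 0.15),
    classifier = "mlpnn",
    latency_window = c(130, 200),
    amplitude_bounds = c(0, 30),
    methods = "proposed"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

# one global seed fans out to per-stage child seeds (stage k -> seed + 10007*k)
child_seed <- function(seed, stage) as.integer(seed) + 10007L * as.integer(stage)

#' Simulate a study from a run configuration
#'
#' @param cfg A `run_config` from [default_run_config()].
#' @return An `erp_study`.
#' @export
simulate_study <- function(cfg) {
  nm <- noise_model(cfg$n_channels, fs = cfg$fs,
                    spectral_exponent = cfg$spectral_exponent,
                    channel_std = cfg$channel_std,
                    cross_channel_corr = cfg$cross_channel_corr,
                    trial_std_spread = cfg$trial_std_spread,
                    dc_drift = cfg$dc_drift, seed = child_seed(cfg$seed, 1L))
  noise <- generate_spontaneous(nm, cfg$n_trials, cfg$epoch_len)
  region <- region_spec("region", noise[[1L]]$channel_ids)
  build_simulated_study(noise, region, tau = cfg$tau, theta = cfg$theta_ms * cfg$fs / 1000,
                        amplitudes = cfg$amplitudes, sign = cfg$sign)
}

#' Build the labelled dataset of one study condition
#'
#' Point-sample extraction plus the stratified split, with the selection
#' and shuffle seeds derived from the run seed and the condition index.
#'
#' @param study An `erp_study`.
#' @param condition Condition name (amplitude level as character or
#'   numeric).
#' @param cfg A `run_config`.
#' @return A split `erp_dataset`.
#' @export
condition_dataset <- function(study, condition, cfg) {
  cn <- as.character(condition)
  k <- match(cn, names(study$conditions))
  if (is.na(k)) stop("no condition '", cn, "' in the study")
  ds <- extract_point_samples(study$noise, study$conditions[[cn]]$epochs,
                              study$region, window = cfg$sample_window,
                              pairs_per_trial = cfg$pairs_per_trial,
                              seed = child_seed(cfg$seed, 10L + k))
  split_dataset(ds, cfg$split_ratios, seed = child_seed(cfg$seed, 20L + k))
}

#' Train the configured classifier on one condition's dataset
#'
#' @param ds A split `erp_dataset`.
#' @param cfg A `run_config` (field `classifier`: `"lr"`, `"mlpnn"` or
#'   `"svm"`).
#' @param stage Integer mixed into the training seed (use e.g. the
#'   condition index).
#' @return A trained `erp_classifier`.
#' @export
train_condition_classifier <- function(ds, cfg, stage = 0L) {
  switch(cfg$classifier,
         lr = train_logistic(ds),
         mlpnn = train_mlpnn(ds, seed = child_seed(cfg$seed, 30L + stage)),
         svm = train_svm(ds),
         stop("unknown classifier '", cfg$classifier, "'"))
}

#' Run the full simulate/train/estimate/evaluate pipeline
#'
#' For each amplitude condition: build the balanced point-sample dataset,
#' train the configured classifier, estimate every trial with the
#' requested methods, and summarize. Deterministic under the config seed.
#' When `out_dir` is given, writes `accuracy.csv`, `estimates.csv`,
#' `summary.csv` and a `config.json` snapshot there (creating the
#' directory if needed).
#'
#' @param cfg A `run_config`.
#' @param out_dir Optional output directory.
#' @return List with `study`, `accuracy` (per-condition test accuracy),
#'   `estimates` (per-trial rows), `summary` (per condition x method),
#'   `models`.
#' @export
run_pipeline <- function(cfg = default_run_config(), out_dir = NULL) {
  study <- simulate_study(cfg)
  econf <- estimation_config(study$region, theta = cfg$theta_ms * cfg$fs / 1000,
                             sign = cfg$sign,
                             latency_window = cfg$latency_window,
                             amplitude_bounds = cfg$amplitude_bounds)
  acc <- list(); est <- list(); models <- list()
  for (k in seq_along(study$conditions)) {
    cn <- names(study$conditions)[k]
    ds <- condition_dataset(study, cn, cfg)
    model <- train_condition_classifier(ds, cfg, stage = k)
    models[[cn]] <- model
    acc[[cn]] <- data.frame(condition = study$conditions[[cn]]$sigma,
                            classifier = cfg$classifier,
                            accuracy = classification_accuracy(model, ds))
    rows <- list()
    if ("proposed" %in% cfg$methods)
      rows$proposed <- estimate_study(study, model, econf, conditions = cn)
    if ("em" %in% cfg$methods)
      rows$em <- estimate_study(study, model, econf,
                                estimator = single_trial_em,
                                conditions = cn)
    if ("woody" %in% cfg$methods) {
      wc <- woody_config(channel = study$region$channels[1L],
                         search_window = cfg$latency_window,
                         polarity = cfg$sign)
      w <- woody_filter(study$conditions[[cn]]$epochs, wc)
      rows$woody <- data.frame(condition = study$conditions[[cn]]$sigma,
                               trial_id = w$latency$trial_id,
                               sigma_hat = NA_real_,
                               tau_hat = w$latency$tau_hat,
                               D = NA_real_, method = "woody")
    }
    est[[cn]] <- do.call(rbind, rows)
  }
  accuracy <- do.call(rbind, acc)
  estimates <- do.call(rbind, est)
  rownames(accuracy) <- rownames(estimates) <- NULL
  truth <- data.frame(condition = study$amplitudes,
                      sigma = study$amplitudes, tau = study$tau)
  tmpl_rms <- rms(template_waveform(cfg$tau, cfg$theta_ms * cfg$fs / 1000,
                                    epoch_times(study$noise[[1L]]), cfg$fs))
  summary <- summarize_estimates(estimates, truth,
                                 noise_rms = study_noise_rms(study),
                                 template_rms_unit = tmpl_rms)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(accuracy, file.path(out_dir, "accuracy.csv"),
                     row.names = FALSE)
    utils::write.csv(estimates, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(study = study, accuracy = accuracy, estimates = estimates,
       summary = summary, models = models)
}

#' Simulate a paired-click sensory-gating study and test for suppression
#'
#' Emulates the P50 paired-click paradigm: each trial yields two 100 ms
#' epochs, the first click carrying a larger component than the second
#' (gating suppresses the redundant repeat). A classifier is trained on
#' point-samples drawn from the 0–16 ms (spontaneous) and 42–58 ms
#' (component) windows, per-trial amplitudes are estimated for both
#' clicks, and the paired location test is applied.
#'
#' @param n_trials Click pairs (default 20).
#' @param first_sigma,second_sigma True component amplitudes (µV) of the
#'   two clicks (defaults 3 and 1.5).
#' @param tau True latency (ms, default 50).
#' @param theta Template width in samples (default 4 at 256 Hz, ~16 ms
#'   effective width for the narrow P50).
#' @param fs Sampling rate (default 256 Hz).
#' @param n_channels Channels in the region (default 4).
#' @param channel_std Noise std (µV, default 4: auditory paired-click
#'   epochs are far less dispersive than the resting-EEG N170 setting).
#' @param seed Integer seed.
#' @param test Paired test passed to [gating_compare()].
#' @return List with the [gating_compare()] result plus the per-trial
#'   estimates (`first`, `second` data frames).
#' @export
gating_study <- function(n_trials = 20, first_sigma = 3, second_sigma = 1.5,
                         tau = 50, theta = 4, fs = 256, n_channels = 4,
                         channel_std = 4, seed = 1, test = "t") {
  nm <- noise_model(n_channels, fs = fs, channel_std = channel_std,
                    seed = child_seed(seed, 1L))
  # both clicks of a pair ride on the same ongoing-EEG state, so the two
  # epochs of a trial share the spontaneous background; that is what makes
  # the paired comparison powerful
  noise <- generate_spontaneous(nm, n_trials, epoch_len = 100)
  region <- region_spec("auditory", noise[[1L]]$channel_ids)
  mk <- function(eps, sigma)
    lapply(eps, superpose, template = erp_template(tau, theta, sigma),
           region = region)
  first <- mk(noise, first_sigma)
  second <- mk(noise, second_sigma)
  ds <- extract_point_samples_windows(c(first, second), region,
                                      positive_window = c(0, 16),
                                      negative_window = c(42, 58),
                                      pairs_per_trial = 4,
                                      seed = child_seed(seed, 2L))
  ds <- split_dataset(ds, seed = child_seed(seed, 3L))
  model <- train_logistic(ds)
  cfg <- estimation_config(region, theta = theta,
                           latency_window = c(42, 58),
                           t_plus_margin = 2L * as.integer(round(theta)),
                           amplitude_bounds = c(0, 15))
  amp <- function(eps) vapply(eps, function(e)
    estimate_trial(e, model, cfg)$sigma_hat, numeric(1))
  a1 <- amp(first); a2 <- amp(second)
  c(gating_compare(a1, a2, test = test),
    list(first = data.frame(trial_id = seq_len(n_trials), sigma_hat = a1),
         second = data.frame(trial_id = seq_len(n_trials), sigma_hat = a2)))
}
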