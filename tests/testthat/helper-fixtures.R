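# Shared fixture builders. Everything is generated in code; no files.

# a small 4-channel epoch of zeros
zero_epoch <- function(n_channels = 4, n_samples = 52, fs = 256, t0 = 0) {
  eeg_epoch(matrix(0, n_channels, n_samples), fs = fs, t0 = t0)
}

four_channel_region <- function(epoch) {
  region_spec("region", epoch$channel_ids)
}

# oracle classifier with an affine distance decreasing in the channel mean:
# adding a positive template makes a sample look less spontaneous
oracle_linear <- function(n_channels = 4, slope = -1, intercept = 0) {
  linear_classifier(rep(slope / n_channels, n_channels), intercept)
}

# a small simulated study at the default N170 conditions
small_study <- function(n_trials = 30, seed = 42, channel_std = 7,
                        trial_std_spread = 0.6, amplitudes = c(3, 15),
                        fs = 256) {
  nm <- noise_model(4, fs = fs, channel_std = channel_std,
                    trial_std_spread = trial_std_spread, seed = seed)
  noise <- generate_spontaneous(nm, n_trials, epoch_len = 200)
  region <- region_spec("region", noise[[1]]$channel_ids)
  build_simulated_study(noise, region, tau = 170, theta = 8 * fs / 1000,
                        amplitudes = amplitudes)
}

# linearly separable 2-D toy dataset with splits
separable_dataset <- function(n_per_class = 30, gap = 4, seed = 7) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
               matrix(rnorm(2 * n_per_class) + gap, ncol = 2))
    y <- rep(c(1L, 0L), each = n_per_class)
    ds <- erp_dataset(x, y, trial_id = seq_along(y), time_ms = rep(0, length(y)))
    split_dataset(ds, c(0.6, 0.2, 0.2), seed = seed)
  })
}

# independent brute-force evaluation of the latency objective: for every
# candidate, sum the distances over T^- (missing edge samples imputed with
# the candidate's T^+ mean), pick the smallest, earliest tie first
brute_force_latency <- function(epoch, model, config) {
  tt <- epoch_times(epoch)
  grid <- tt[tt >= config$latency_window[1] & tt <= config$latency_window[2]]
  rows <- match(config$region$channels, epoch$channel_ids)
  obj <- vapply(grid, function(tau) {
    center <- which.min(abs(tt - tau))
    idx <- (center - config$t_minus_halfwidth):(center + config$t_minus_halfwidth)
    valid <- idx[idx >= 1 & idx <= ncol(epoch$data)]
    post <- which(tt >= 0)
    tplus <- post[abs(post - center) > config$t_plus_margin]
    d <- vapply(valid, function(i)
      distance(model, epoch$data[rows, i]), numeric(1))
    dD <- mean(vapply(tplus, function(i)
      distance(model, epoch$data[rows, i]), numeric(1)))
    sum(d) + (length(idx) - length(valid)) * dD
  }, numeric(1))
  grid[which.min(obj)]
}
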