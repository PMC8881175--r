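test_that("window construction follows the theta-based geometry", {
  ep <- zero_epoch(n_samples = 120)  # ~465 ms, room for wide windows
  region <- four_channel_region(ep)
  cfg <- estimation_config(region, theta = 8, latency_window = c(130, 300))
  w <- make_windows(170, cfg, ep)
  expect_length(w$t_minus, 17)   # +/- 8 samples around the center
  expect_false(w$truncated)
  expect_length(intersect(w$t_minus, w$t_plus), 0)
  # all T+ samples are post-stimulus and farther than the margin
  center <- nearest_sample(ep, 170)
  expect_true(all(abs(w$t_plus - center) > cfg$t_plus_margin))
  # edge candidate: truncated and flagged
  we <- make_windows(epoch_times(ep)[118], cfg, ep)
  expect_true(we$truncated)
  expect_lt(length(we$t_minus), 17)
  # candidates 3*theta apart have disjoint near windows
  w2 <- make_windows(170 + 3 * 8 * 1000 / 256, cfg, ep)
  expect_length(intersect(w$t_minus, w2$t_minus), 0)
  # an epoch too short for any far window errors out
  tiny <- zero_epoch(n_samples = 9)
  cfg2 <- estimation_config(region, theta = 2, t_plus_margin = 50,
                            latency_window = c(0, 40))
  expect_error(make_windows(16, cfg2, tiny), "T\\+")
})

test_that("noise-free epochs are recovered exactly", {
  fs <- 256
  ep <- zero_epoch(n_samples = 128)   # 500 ms
  tau_true <- epoch_times(ep)[65]     # on-grid latency
  theta <- 8 * fs / 1000
  region <- four_channel_region(ep)
  for (sigma_true in c(15, 6)) {
    epo <- superpose(ep, erp_template(tau_true, theta, sigma_true), region)
    model <- oracle_linear()
    cfg <- estimation_config(region, theta = theta,
                             latency_window = c(130, 400),
                             t_plus_margin = 8)   # 4*theta: T+ template-free
    lat <- estimate_latency(epo, model, cfg)
    expect_equal(lat$tau_hat, tau_true)
    sig <- estimate_amplitude(epo, lat$tau_hat, model, cfg)
    expect_lt(abs(as.numeric(sig) - sigma_true), 1e-3)
  }
})

test_that("latency search equals independent brute-force minimization", {
  st <- small_study(n_trials = 6, seed = 23, amplitudes = c(3, 15))
  cfg <- estimation_config(st$region, theta = st$theta)
  models <- list(oracle_linear(), linear_classifier(c(-1, 0.2, -0.5, -0.3), 1))
  for (model in models) {
    for (cn in names(st$conditions)) {
      for (ep in st$conditions[[cn]]$epochs) {
        got <- estimate_latency(ep, model, cfg)$tau_hat
        expect_identical(got, brute_force_latency(ep, model, cfg))
      }
    }
  }
})

test_that("latency trace covers the grid and ties break earliest", {
  ep <- zero_epoch()
  region <- four_channel_region(ep)
  cfg <- estimation_config(region, theta = 2.048)
  model <- oracle_linear()
  lat <- estimate_latency(ep, model, cfg)   # flat input: all objectives equal
  expect_equal(lat$tau_hat, min(lat$trace$tau))
  tt <- epoch_times(ep)
  expect_equal(lat$trace$tau, tt[tt >= 130 & tt <= 200])
})

test_that("amplitude step matches the closed-form quadratic vertex", {
  st <- small_study(n_trials = 8, seed = 24, amplitudes = 10)
  w_vec <- c(-0.3, -0.2, -0.25, -0.25)
  model <- linear_classifier(w_vec, 0.4)
  cfg <- estimation_config(st$region, theta = st$theta)
  c_sum <- sum(w_vec)
  for (ep in st$conditions[["10"]]$epochs) {
    lat <- estimate_latency(ep, model, cfg)
    sig <- estimate_amplitude(ep, lat$tau_hat, model, cfg)
    w <- make_windows(lat$tau_hat, cfg, ep)
    delta <- distance(model, t(ep$data[, w$t_minus, drop = FALSE]))
    D <- attr(sig, "D")
    f <- template_waveform(lat$tau_hat, st$theta, epoch_times(ep), 256)[w$t_minus]
    vertex <- sum(f * (delta - D)) / (c_sum * sum(f^2))
    vertex <- min(max(vertex, cfg$amplitude_bounds[1]), cfg$amplitude_bounds[2])
    expect_lt(abs(as.numeric(sig) - vertex), 1e-3)
  }
})

test_that("pure-noise amplitude stays near zero under the oracle", {
  nm <- noise_model(4, 256, channel_std = 7, trial_std_spread = 0,
                    dc_drift = 0, seed = 26)
  noise <- generate_spontaneous(nm, 60, 200)
  region <- region_spec("region", noise[[1]]$channel_ids)
  cfg <- estimation_config(region, theta = 2.048)
  model <- oracle_linear()
  sig <- vapply(noise, function(ep)
    as.numeric(estimate_amplitude(ep, 170, model, cfg)), numeric(1))
  # truncation at 0 folds the null distribution; mean is half-normal-ish
  expect_lt(mean(sig), 2 * 7 / sqrt(5))
})

test_that("trial estimation composes the two steps and batches over studies", {
  st <- small_study(n_trials = 4, seed = 25, amplitudes = c(3, 15))
  ds <- suppressMessages(condition_dataset(
    st, "15", default_run_config(seed = 1, n_trials = 4)))
  model <- train_logistic(ds)
  cfg <- estimation_config(st$region, theta = st$theta)
  ep <- st$conditions[["15"]]$epochs[[1]]
  est <- estimate_trial(ep, model, cfg)
  lat <- estimate_latency(ep, model, cfg)
  sig <- estimate_amplitude(ep, lat$tau_hat, model, cfg)
  expect_equal(est$tau_hat, lat$tau_hat)
  expect_equal(est$sigma_hat, as.numeric(sig))
  expect_equal(est$D, attr(sig, "D"))
  expect_equal(est$method, "proposed")
  expect_true(est$tau_hat %in% lat$trace$tau)
  expect_true(est$sigma_hat >= cfg$amplitude_bounds[1] &&
                est$sigma_hat <= cfg$amplitude_bounds[2])
  res <- estimate_study(st, model, cfg)
  expect_equal(nrow(res), 8)
  expect_equal(unname(table(res$condition)), c(4L, 4L), ignore_attr = TRUE)
})

test_that("the pooled objective variant runs and differs from per-point", {
  st <- small_study(n_trials = 2, seed = 27, amplitudes = 15)
  model <- oracle_linear()
  ep <- st$conditions[["15"]]$epochs[[1]]
  cfg1 <- estimation_config(st$region, theta = st$theta)
  cfg2 <- estimation_config(st$region, theta = st$theta, objective = "pooled")
  s1 <- as.numeric(estimate_amplitude(ep, 170, model, cfg1))
  s2 <- as.numeric(estimate_amplitude(ep, 170, model, cfg2))
  expect_true(is.finite(s1) && is.finite(s2))
})

test_that("a constant distance yields the flagged lower bound", {
  ep <- small_study(n_trials = 1, seed = 28, amplitudes = 3)$conditions[["3"]]$epochs[[1]]
  region <- region_spec("region", ep$channel_ids)
  cfg <- estimation_config(region, theta = 2.048)
  flat_model <- linear_classifier(rep(0, 4), 1)
  expect_warning(sig <- estimate_amplitude(ep, 170, flat_model, cfg), "flat")
  expect_equal(as.numeric(sig), 0)
  expect_true(attr(sig, "flat"))
})
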