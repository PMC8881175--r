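test_that("point-sample extraction is exactly balanced with paired labels", {
  st <- small_study(n_trials = 50, seed = 13, amplitudes = 10)
  ds <- suppressMessages(extract_point_samples(
    st$noise, st$conditions[["10"]]$epochs, st$region,
    window = c(162, 178), pairs_per_trial = 6, seed = 1))
  expect_equal(sum(ds$label == 1L), 300)
  expect_equal(sum(ds$label == 0L), 300)
  expect_equal(ncol(ds$features), 4)
  # positives are the raw noise vectors, negatives the matched ERP vectors,
  # at identical time points per trial
  for (tr in c(1, 25)) {
    sel <- ds$trial_id == tr
    tms <- ds$time_ms[sel]
    expect_equal(sort(tms[ds$label[sel] == 1L]), sort(tms[ds$label[sel] == 0L]))
    expect_true(all(tms >= 158 & tms <= 182))
  }
  expect_error(extract_point_samples(st$noise, st$conditions[["10"]]$epochs,
                                     st$region, pairs_per_trial = 0), "pairs")
  expect_error(extract_point_samples(st$noise[1:3], st$conditions[["10"]]$epochs,
                                     st$region), "matched")
})

test_that("negative minus positive sample equals the injected template value", {
  st <- small_study(n_trials = 5, seed = 14, amplitudes = 15)
  ds <- suppressMessages(extract_point_samples(
    st$noise, st$conditions[["15"]]$epochs, st$region, seed = 2))
  tt <- epoch_times(st$noise[[1]])
  for (i in which(ds$label == 1L)[1:10]) {
    j <- which(ds$label == 0L & ds$trial_id == ds$trial_id[i] &
                 ds$time_ms == ds$time_ms[i])
    f <- 15 * template_waveform(170, st$theta, ds$time_ms[i], 256)
    expect_equal(ds$features[j, ] - ds$features[i, ], rep(f, 4),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("stratified splitting honors the 7:1.5:1.5 protocol", {
  st <- small_study(n_trials = 50, seed = 13, amplitudes = 10)
  ds <- suppressMessages(extract_point_samples(
    st$noise, st$conditions[["10"]]$epochs, st$region, seed = 1))
  sp <- split_dataset(ds, c(0.7, 0.15, 0.15), seed = 3)
  expect_length(sp$splits$train, 420)
  expect_length(sp$splits$validation, 90)
  expect_length(sp$splits$test, 90)
  # disjoint and exhaustive
  all_idx <- unname(sort(unlist(sp$splits)))
  expect_equal(all_idx, seq_len(600))
  # stratification preserves exact balance here
  for (part in names(sp$splits))
    expect_equal(mean(ds$label[sp$splits[[part]]]), 0.5)
  # determinism and sensitivity to the seed
  sp2 <- split_dataset(ds, c(0.7, 0.15, 0.15), seed = 3)
  expect_identical(sp$splits, sp2$splits)
  sp3 <- split_dataset(ds, c(0.7, 0.15, 0.15), seed = 4)
  expect_false(identical(sp$splits, sp3$splits))
  # everything-in-train and error cases
  sp4 <- split_dataset(ds, c(1, 0, 0), seed = 1)
  expect_length(sp4$splits$train, 600)
  expect_error(split_dataset(ds, c(0.9, 0.2, -0.1)), "negative")
  expect_error(split_dataset(ds, c(0.5, 0.2, 0.2)), "sum")
})

test_that("two-window variant labels baseline and component ranges", {
  nm <- noise_model(4, 256, channel_std = 4, seed = 31)
  noise <- generate_spontaneous(nm, 10, epoch_len = 100)
  region <- region_spec("aud", noise[[1]]$channel_ids)
  eps <- lapply(noise, superpose, template = erp_template(50, 2.5, 3),
                region = region)
  ds <- extract_point_samples_windows(eps, region, c(0, 16), c(42, 58),
                                      pairs_per_trial = 4, seed = 5)
  expect_equal(sum(ds$label == 1L), 40)
  expect_equal(sum(ds$label == 0L), 40)
  expect_true(all(ds$time_ms[ds$label == 1L] <= 16))
  expect_true(all(ds$time_ms[ds$label == 0L] >= 42 &
                    ds$time_ms[ds$label == 0L] <= 58))
})

test_that("narrow windows widen symmetrically to supply distinct points", {
  st <- small_study(n_trials = 2, seed = 15, amplitudes = 3)
  expect_message(
    ds <- extract_point_samples(st$noise, st$conditions[["3"]]$epochs,
                                st$region, window = c(169, 171),
                                pairs_per_trial = 5, seed = 1),
    "widened")
  expect_equal(sum(ds$label == 1L), 10)
  expect_equal(length(unique(ds$time_ms[ds$trial_id == 1])), 5)
})
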