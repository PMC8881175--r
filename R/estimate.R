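#' Configuration of the single-trial estimator
#'
#' Collects everything the two-step estimator needs: the region, the fixed
#' template shape (width and polarity; amplitude and latency stay free),
#' the candidate-latency window or explicit grid, the near/far window
#' geometry, and the amplitude search interval.
#'
#' @param region A `region_spec`.
#' @param theta Template width (samples).
#' @param sign Template polarity (+1/-1).
#' @param latency_window Length-2 numeric (ms): candidate latencies are all
#'   sample times in this window (default 130–200 ms, the plausible N170
#'   range).
#' @param latency_grid Optional explicit grid of candidate latencies (ms);
#'   overrides `latency_window`.
#' @param t_minus_halfwidth Half-width of the near-latency window T^- in
#'   samples (default `theta`).
#' @param t_plus_margin Samples a point must be from the candidate latency
#'   to belong to the far window T^+ (default `2 * theta`).
#' @param amplitude_bounds Length-2 numeric search interval for the
#'   amplitude (µV), lower bound >= 0; default `c(0, 30)`.
#' @param tol Absolute tolerance of the bounded scalar amplitude search
#'   (µV), default `1e-4`.
#' @param objective Amplitude objective form: `"per_point"` (default) sums
#'   the squared deviations of each residual distance from D;
#'   `"pooled"` squares the deviation of the summed distances.
#' @return An object of class `estimation_config`.
#' @export
estimation_config <- function(region, theta, sign = 1,
                              latency_window = c(130, 200),
                              latency_grid = NULL,
                              t_minus_halfwidth = round(theta),
                              t_plus_margin = 2 * round(theta),
                              amplitude_bounds = c(0, 30), tol = 1e-4,
                              objective = c("per_point", "pooled"),
                              edge = c("impute", "truncate")) {
  stopifnot(inherits(region, "region_spec"), theta > 0)
  if (length(amplitude_bounds) != 2L || amplitude_bounds[1L] < 0 ||
      diff(amplitude_bounds) <= 0)
    stop("'amplitude_bounds' must be ordered with lower bound >= 0")
  structure(list(region = region, theta = theta, sign = sign,
                 latency_window = latency_window,
                 latency_grid = latency_grid,
                 t_minus_halfwidth = as.integer(t_minus_halfwidth),
                 t_plus_margin = as.integer(t_plus_margin),
                 amplitude_bounds = amplitude_bounds, tol = tol,
                 objective = match.arg(objective),
                 edge = match.arg(edge)),
            class = "estimation_config")
}

#' Near/far time windows around a candidate latency
#'
#' T^- holds the samples within `t_minus_halfwidth` samples of the
#' candidate latency (where the component, if present, is strong); T^+
#' holds the post-stimulus samples farther than `t_plus_margin` samples
#' from it (where the epoch is effectively spontaneous). The two sets are
#' disjoint by construction. A T^- that runs over the epoch edge is
#' truncated to the valid samples and flagged.
#'
#' @param tau_candidate Candidate latency (ms), inside the epoch.
#' @param config An `estimation_config`.
#' @param epoch An `eeg_epoch`.
#' @return List with integer sample-index vectors `t_minus`, `t_plus` and
#'   logical `truncated`.
#' @export
make_windows <- function(tau_candidate, config, epoch) {
  center <- nearest_sample(epoch, tau_candidate)
  n <- ncol(epoch$data)
  full <- (center - config$t_minus_halfwidth):(center + config$t_minus_halfwidth)
  t_minus <- full[full >= 1L & full <= n]
  post <- which(epoch_times(epoch) >= 0)
  t_plus <- post[abs(post - center) > config$t_plus_margin]
  if (length(t_plus) == 0L)
    stop("T+ is empty: epoch too short for the configured t_plus_margin")
  list(t_minus = t_minus, t_plus = t_plus,
       truncated = length(t_minus) < length(full))
}

default_latency_grid <- function(epoch, config) {
  if (!is.null(config$latency_grid)) {
    grid <- sort(config$latency_grid)
  } else {
    tt <- epoch_times(epoch)
    grid <- tt[tt >= config$latency_window[1L] &
               tt <= config$latency_window[2L]]
  }
  if (length(grid) == 0L)
    stop("no candidate latencies fall inside the epoch")
  grid
}

# distance of every sample of the epoch (region channels) to the model
epoch_distances <- function(epoch, model, config) {
  rows <- region_rows(epoch, config$region)
  distance(model, t(epoch$data[rows, , drop = FALSE]))
}

#' Estimate the component latency of one trial
#'
#' Step one of the estimator: exhaustive search over the candidate grid of
#' \deqn{\hat\tau = \arg\min_\tau \sum_{t \in T^-} \Delta(E(t), Z),}
#' the candidate whose near window accumulates the smallest classifier
#' distance — samples near the true latency look least spontaneous. A
#' near window truncated at the epoch edge would make its candidate's sum
#' incomparable to the interior candidates', so each missing sample is
#' imputed with the candidate's far-window mean distance D (far-from-
#' latency samples approximate D, the same assumption the amplitude step
#' rests on); the objective is identical to the raw sum whenever every
#' window is full. Ties break toward the earliest candidate.
#'
#' @param epoch An `eeg_epoch`.
#' @param model A trained `erp_classifier` on the matching region.
#' @param config An `estimation_config`.
#' @return List with `tau_hat` (ms) and `trace`, a data frame of every
#'   candidate and its objective value.
#' @export
estimate_latency <- function(epoch, model, config) {
  grid <- default_latency_grid(epoch, config)
  delta <- epoch_distances(epoch, model, config)
  full_size <- 2L * config$t_minus_halfwidth + 1L
  obj <- vapply(grid, function(tau) {
    w <- make_windows(tau, config, epoch)
    missing <- full_size - length(w$t_minus)
    s <- sum(delta[w$t_minus])
    if (missing > 0L && config$edge == "impute")
      s <- s + missing * mean(delta[w$t_plus])
    s
  }, numeric(1))
  if (all(!is.finite(obj))) stop("latency objective is non-finite everywhere")
  list(tau_hat = grid[which.min(obj)],
       trace = data.frame(tau = grid, objective = obj))
}

# residual epoch columns at T^- for a trial amplitude sigma
residual_features <- function(epoch, rows, t_minus, sigma, sign, wave) {
  sweep(epoch$data[rows, t_minus, drop = FALSE], 2L,
        sign * sigma * wave[t_minus], "-")
}

#' Estimate the component amplitude of one trial
#'
#' Step two: with the latency fixed, the amplitude is the bounded scalar
#' minimizer of
#' \deqn{\hat\sigma = \arg\min_\sigma \sum_{t \in T^-}
#'   \left[\Delta(X(t), Z) - D\right]^2,}
#' where \eqn{X(t) = E(t) - \sigma\, s(t - \hat\tau)} is the epoch with a
#' trial amplitude sigma of template removed, and `D` is the mean distance
#' of the raw epoch's far-window (T^+) samples — the classifier's idea of
#' how spontaneous this trial's background looks. At the right sigma the
#' residual near-window samples look exactly that spontaneous.
#'
#' For an affine distance the objective is an exact quadratic with a
#' single minimum. For a nonlinear classifier it need not be: once sigma
#' overshoots far past the component, the residual is an extreme vector
#' the classifier never saw, and its distance can drift back toward D,
#' opening a spurious second basin at implausibly large amplitudes. The
#' estimate is therefore the *first* local basin of the objective scanned
#' upward from the lower bound — the smallest amplitude whose residual
#' looks spontaneous — located on a lightly smoothed coarse grid (0.5 µV
#' steps, 3-point moving average, so one-point noise dimples on the
#' descent do not masquerade as basins), bracketed, and
#' refined by Brent's bounded minimization ([stats::optimize()]) at
#' tolerance `config$tol`. For affine distances this coincides with the
#' global bounded minimum.
#'
#' @param epoch An `eeg_epoch`.
#' @param tau_hat Latency fixed by [estimate_latency()] (ms).
#' @param model A trained `erp_classifier`.
#' @param config An `estimation_config`.
#' @return `sigma_hat` (µV) with attributes `D` (the far-window mean
#'   distance) and `flat` (`TRUE` when the objective was degenerate and
#'   the lower bound was returned with a warning).
#' @export
estimate_amplitude <- function(epoch, tau_hat, model, config) {
  w <- make_windows(tau_hat, config, epoch)
  rows <- region_rows(epoch, config$region)
  delta_raw <- epoch_distances(epoch, model, config)
  D <- mean(delta_raw[w$t_plus])
  wave <- template_waveform(tau_hat, config$theta, epoch_times(epoch),
                            epoch$fs)
  objective <- function(sigma) {
    d_res <- distance(model, t(residual_features(epoch, rows, w$t_minus,
                                                 sigma, config$sign, wave)))
    if (config$objective == "per_point") sum((d_res - D)^2)
    else (sum(d_res) - D)^2
  }
  b <- config$amplitude_bounds
  grid <- seq(b[1L], b[2L], length.out = max(31L, ceiling(diff(b) / 0.5) + 1L))
  vals <- vapply(grid, objective, numeric(1))
  if (diff(range(vals)) < 1e-12) {
    warning("flat amplitude objective; returning the lower bound")
    return(structure(b[1L], D = D, flat = TRUE))
  }
  n <- length(grid)
  # 3-point moving average so a one-point noise dimple on a steep descent
  # does not masquerade as a basin
  sm <- (c(vals[1L], vals[-n]) + vals + c(vals[-1L], vals[n])) / 3
  minima <- which(sm <= c(Inf, sm[-n]) & sm <= c(sm[-1L], Inf))
  i <- minima[1L]
  lo <- grid[max(1L, i - 2L)]
  hi <- grid[min(n, i + 2L)]
  if (lo == hi) return(structure(lo, D = D, flat = FALSE))
  opt <- stats::optimize(objective, interval = c(lo, hi), tol = config$tol)
  sigma_hat <- if (vals[i] < opt$objective) grid[i] else opt$minimum
  structure(sigma_hat, D = D, flat = FALSE)
}

#' Estimate latency and amplitude of one trial
#'
#' Composes the two steps ([estimate_latency()] then
#' [estimate_amplitude()]) and records the diagnostics.
#'
#' @param epoch An `eeg_epoch`.
#' @param model A trained `erp_classifier`.
#' @param config An `estimation_config`.
#' @param method Method label stored in the result (default
#'   `"proposed"`).
#' @return An object of class `erp_estimate`: list with `sigma_hat`,
#'   `tau_hat`, `method`, `D`, and the latency `objective_trace`.
#' @export
estimate_trial <- function(epoch, model, config, method = "proposed") {
  lat <- estimate_latency(epoch, model, config)
  sig <- estimate_amplitude(epoch, lat$tau_hat, model, config)
  structure(list(sigma_hat = as.numeric(sig), tau_hat = lat$tau_hat,
                 method = method, D = attr(sig, "D"),
                 flat = attr(sig, "flat"),
                 objective_trace = lat$trace),
            class = "erp_estimate")
}

#' @export
print.erp_estimate <- function(x, ...) {
  cat(sprintf("<erp_estimate> method = %s: sigma_hat = %.2f uV, tau_hat = %.1f ms (D = %.3f)\n",
              x$method, x$sigma_hat, x$tau_hat, x$D))
  invisible(x)
}

#' Run an estimator over every trial of a simulated study
#'
#' @param study An `erp_study`.
#' @param model A trained `erp_classifier` (shared across conditions).
#' @param config An `estimation_config`.
#' @param estimator Function `(epoch, model, config) -> erp_estimate`;
#'   default [estimate_trial()]. Pass [single_trial_em()] or wrap
#'   [woody_filter()] for the baselines.
#' @param conditions Optional character vector of condition names
#'   (amplitude levels) to run; default all.
#' @return Data frame with one row per trial: `condition` (true sigma),
#'   `trial_id`, `sigma_hat`, `tau_hat`, `D`, `method`.
#' @export
estimate_study <- function(study, model, config, estimator = estimate_trial,
                           conditions = NULL) {
  stopifnot(inherits(study, "erp_study"))
  if (is.null(conditions)) conditions <- names(study$conditions)
  out <- lapply(conditions, function(cn) {
    cond <- study$conditions[[cn]]
    res <- lapply(cond$epochs, estimator, model, config)
    data.frame(condition = cond$sigma,
               trial_id = cond$truth$trial_id,
               sigma_hat = vapply(res, `[[`, numeric(1), "sigma_hat"),
               tau_hat = vapply(res, `[[`, numeric(1), "tau_hat"),
               D = vapply(res, function(r) r$D %||% NA_real_, numeric(1)),
               method = vapply(res, `[[`, character(1), "method"))
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
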