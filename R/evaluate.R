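#' Test-set classification accuracy
#'
#' Fraction of correctly classified point-samples on the test split only,
#' in percent.
#'
#' @param model A trained `erp_classifier`.
#' @param ds A split `erp_dataset` with a non-empty test split.
#' @return Accuracy in percent (0–100).
#' @export
classification_accuracy <- function(model, ds) {
  te <- split_part(ds, "test")
  100 * mean(predict_class(model, te$x) == te$y)
}

#' Summarize per-trial estimates against the ground truth
#'
#' Per condition (and method), the mean and sample standard deviation of
#' the amplitude and latency estimates — the performance measurement of
#' the simulation experiments. When the realized noise RMS is supplied,
#' an SNR column (20 log10 of signal RMS over noise RMS, with signal RMS
#' that of the scaled template over the epoch) is included.
#'
#' @param results Data frame from [estimate_study()] / [woody_study()]
#'   (columns `condition`, `trial_id`, `sigma_hat`, `tau_hat`, `method`).
#' @param truth Optional data frame with per-condition truth (`condition`,
#'   `sigma`, `tau`); when supplied, every result row must match a truth
#'   condition, and bias columns are added.
#' @param noise_rms Optional realized noise RMS (µV) for the SNR column.
#' @param template_rms_unit Optional RMS of the unit-amplitude template
#'   over the epoch (so signal RMS is `condition * template_rms_unit`).
#' @return Data frame with one row per condition x method:
#'   `condition`, `method`, `n`, `sigma_mean`, `sigma_sd`, `tau_mean`,
#'   `tau_sd`, and optionally `snr_db`, `sigma_bias`, `tau_bias`.
#' @export
summarize_estimates <- function(results, truth = NULL, noise_rms = NULL,
                                template_rms_unit = NULL) {
  stopifnot(all(c("condition", "sigma_hat", "tau_hat", "method") %in%
                  names(results)))
  if (!is.null(truth) &&
      !all(results$condition %in% truth$condition))
    stop("result rows with no matching truth condition")
  keys <- unique(results[, c("condition", "method")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- results$condition == keys$condition[i] &
      results$method == keys$method[i]
    r <- results[sel, ]
    out <- data.frame(condition = keys$condition[i],
                      method = keys$method[i], n = nrow(r),
                      sigma_mean = mean(r$sigma_hat),
                      sigma_sd = stats::sd(r$sigma_hat),
                      tau_mean = mean(r$tau_hat),
                      tau_sd = stats::sd(r$tau_hat))
    if (!is.null(noise_rms) && !is.null(template_rms_unit))
      out$snr_db <- snr_db(keys$condition[i] * template_rms_unit, noise_rms)
    if (!is.null(truth)) {
      tr <- truth[match(keys$condition[i], truth$condition), ]
      out$sigma_bias <- out$sigma_mean - tr$sigma
      out$tau_bias <- out$tau_mean - tr$tau
    }
    out
  })
  out <- do.call(rbind, rows)
  out[order(out$method, out$condition), , drop = FALSE]
}

#' Paired sensory-gating comparison
#'
#' Tests whether the component amplitude evoked by the first click of a
#' pair exceeds that evoked by the second (sensory gating: the brain
#' suppresses the redundant repeat). A paired two-sided location test on
#' the per-trial amplitude differences: Student's t by default, Wilcoxon
#' signed-rank on request. Degenerate input (all differences identical,
#' e.g. identical lists) cannot be tested; the P value is reported as 1
#' with `degenerate = TRUE` when the common difference is 0, as per the
#' exact rule `P = as.numeric(all(diff == 0))` otherwise 0 for a nonzero
#' constant shift.
#'
#' @param first_amps,second_amps Equal-length (>= 2) numeric vectors of
#'   per-trial amplitude estimates (µV), paired by trial.
#' @param test `"t"` (default) or `"wilcoxon"`.
#' @return List with `first_mean`, `first_sd`, `second_mean`, `second_sd`,
#'   `mean_difference`, `p_value`, `test`, `degenerate`.
#' @export
gating_compare <- function(first_amps, second_amps,
                           test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(first_amps) != length(second_amps))
    stop("paired amplitude lists must have equal length")
  if (length(first_amps) < 2L) stop("at least 2 paired trials are required")
  d <- first_amps - second_amps
  degenerate <- stats::sd(d) == 0
  p <- if (degenerate) {
    as.numeric(all(d == 0))   # no-difference pairs -> P = 1; constant shift -> P = 0
  } else if (test == "t") {
    stats::t.test(first_amps, second_amps, paired = TRUE)$p.value
  } else {
    stats::wilcox.test(first_amps, second_amps, paired = TRUE,
                       exact = FALSE)$p.value
  }
  list(first_mean = mean(first_amps), first_sd = stats::sd(first_amps),
       second_mean = mean(second_amps), second_sd = stats::sd(second_amps),
       mean_difference = mean(d), p_value = p, test = test,
       degenerate = degenerate)
}
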