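#' @title Binary point-sample classifiers and the distance they expose
#' @description Three interchangeable classifiers (logistic regression,
#'   multilayer perceptron, Gaussian-kernel SVM) trained to separate
#'   spontaneous (positive) from ERP-bearing (negative) channel-vectors.
#'   Every trained model exposes the same scalar distance
#'   \eqn{\Delta(x, Z)}: a score strictly increasing in the model's
#'   probability that `x` is spontaneous, zero on the decision boundary.
#'   The single-trial estimators only ever touch the model through
#'   [distance()], so the back-ends are interchangeable.
#' @name classifiers
NULL

new_classifier <- function(kind, ..., meta = list()) {
  structure(c(list(kind = kind), list(...), list(meta = meta)),
            class = "erp_classifier")
}

#' @export
print.erp_classifier <- function(x, ...) {
  cat(sprintf("<erp_classifier> kind = %s", x$kind))
  if (!is.null(x$meta$validation_accuracy))
    cat(sprintf(", validation accuracy = %.1f%%",
                x$meta$validation_accuracy))
  cat("\n")
  invisible(x)
}

as_feature_matrix <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$n_features)
    stop("feature dimension ", ncol(x), " does not match the model's ",
         model$n_features)
  x
}

# ridge-penalized logistic log-likelihood fit, used when glm reports
# (quasi-)separation
ridge_logistic <- function(x, y, lambda = 1e-2) {
  d <- ncol(x)
  nll <- function(par) {
    eta <- drop(x %*% par[1:d]) + par[d + 1L]
    sum(log1p(exp(-(2 * y - 1) * eta))) + lambda * sum(par[1:d]^2) / 2
  }
  fit <- stats::optim(rep(0, d + 1L), nll, method = "BFGS",
                      control = list(maxit = 500))
  list(w = fit$par[1:d], b = fit$par[d + 1L])
}

#' Train a logistic regression classifier
#'
#' Maximum-likelihood fit of
#' \eqn{\log[p(y=1|x)/p(y=0|x)] = w^\top x + b} on the training split
#' (via [stats::glm()] with a binomial family and logit link). If the
#' training data are perfectly separable the MLE diverges; the fit then
#' falls back to a lightly ridge-penalized likelihood maximum and the model
#' is flagged.
#'
#' @param ds A split `erp_dataset` with both classes in the training split.
#' @return An `erp_classifier` of kind `"lr"` with fields `w`, `b`.
#' @export
train_logistic <- function(ds) {
  tr <- split_part(ds, "train")
  if (length(unique(tr$y)) < 2L)
    stop("training split must contain both classes")
  separable <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, tr$x), tr$y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("0 or 1", conditionMessage(w))) separable <<- TRUE
      invokeRestart("muffleWarning")
    })
  p <- fit$fitted.values
  if (all(p[tr$y == 1L] > 1 - 1e-6) && all(p[tr$y == 0L] < 1e-6))
    separable <- TRUE   # divergent MLE: every point fit perfectly
  if (separable || anyNA(fit$coefficients) ||
      any(abs(fit$coefficients) > 1e3)) {
    rf <- ridge_logistic(tr$x, tr$y)
    w <- rf$w; b <- rf$b; separable <- TRUE
  } else {
    w <- fit$coefficients[-1L]; b <- fit$coefficients[1L]
  }
  m <- new_classifier("lr", w = unname(w), b = unname(b),
                      n_features = ncol(tr$x),
                      meta = list(separable = separable))
  m$meta$validation_accuracy <- try_validation_accuracy(m, ds)
  m
}

try_validation_accuracy <- function(model, ds) {
  if (is.null(ds$splits) || length(ds$splits$validation) == 0L) return(NULL)
  va <- split_part(ds, "validation")
  100 * mean(predict_class(model, va$x) == va$y)
}

# weights of a skip-layer net: hidden layer + output + direct input-output
n_mlp_weights <- function(d, size) (d + 1L) * size + (size + 1L) + d

#' Train a multilayer perceptron classifier with structure selection
#'
#' There is no prior knowledge of the right network structure, so each
#' candidate hidden-layer size is trained and the validation split picks
#' the winner. Networks carry skip-layer (input-to-output) connections,
#' so the logistic-regression solution is nested inside every candidate
#' and hidden units only add nonlinear corrections. Training uses `nnet`'s batch quasi-Newton (BFGS) optimizer
#' on the cross-entropy loss, run in chunks with early stopping: after
#' each chunk the validation accuracy is measured, and training stops once
#' it has not improved for `patience` consecutive chunks (the best-seen
#' weights are kept). The candidate with the highest validation accuracy
#' wins; ties break toward the network with fewer weights.
#'
#' @param ds A split `erp_dataset` with a non-empty validation split.
#' @param candidate_sizes Integer vector of hidden-layer sizes to try
#'   (default 2, 4, 8, 16).
#' @param seed Integer seed; fixes weight initialization, so the same seed
#'   and data give an identical selected structure and weights.
#' @param n_starts Random restarts per candidate structure (the BFGS loss
#'   surface is multimodal; the best restart by validation accuracy is
#'   kept).
#' @param decays Candidate L2 weight-decay values, selected on the
#'   validation split alongside the structure; the largest value shrinks
#'   the net toward its skip-layer (linear) part, which is what low-SNR
#'   conditions favor.
#' @param chunk_iters Optimizer iterations per chunk.
#' @param max_chunks Maximum chunks per candidate.
#' @param patience Chunks without validation improvement before stopping.
#' @return An `erp_classifier` of kind `"mlpnn"` with the fitted `nnet`
#'   object, the selected `size`, and validation accuracy in `meta`.
#'   Features are standardized internally (training-split mean/sd, stored
#'   in the model and applied by [distance()]).
#' @export
train_mlpnn <- function(ds, candidate_sizes = c(2, 4, 8, 16), seed = 1,
                        n_starts = 3, decays = c(0.01, 0.1, 1),
                        chunk_iters = 100, max_chunks = 5, patience = 2) {
  if (length(candidate_sizes) == 0L) stop("'candidate_sizes' must be non-empty")
  tr <- split_part(ds, "train")
  va <- split_part(ds, "validation")
  d <- ncol(tr$x)
  center <- colMeans(tr$x)
  scale <- apply(tr$x, 2L, stats::sd)
  scale[scale == 0] <- 1
  zx <- scale(tr$x, center, scale)
  zv <- scale(va$x, center, scale)
  val_acc <- function(fit) {
    p <- as.vector(stats::predict(fit, zv))
    mean(as.integer(p > 0.5) == va$y)
  }
  cand <- expand.grid(size = candidate_sizes, start = seq_len(n_starts),
                      decay = decays)
  best <- NULL
  for (k in seq_len(nrow(cand))) {
    size <- cand$size[k]
    fit <- withr::with_seed(seed + k, nnet::nnet(
      zx, tr$y, size = size, entropy = TRUE, decay = cand$decay[k],
      skip = TRUE, maxit = chunk_iters, trace = FALSE))
    cand_best <- list(fit = fit, acc = val_acc(fit))
    stale <- 0L
    for (chunk in seq_len(max_chunks - 1L)) {
      fit <- nnet::nnet(zx, tr$y, size = size, entropy = TRUE,
                        decay = cand$decay[k], skip = TRUE,
                        maxit = chunk_iters, Wts = fit$wts, trace = FALSE)
      a <- val_acc(fit)
      if (a > cand_best$acc) {
        cand_best <- list(fit = fit, acc = a)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
    nw <- n_mlp_weights(d, size)
    if (is.null(best) || cand_best$acc > best$acc ||
        (cand_best$acc == best$acc && nw < best$nweights)) {
      best <- list(fit = cand_best$fit, acc = cand_best$acc, size = size,
                   nweights = nw, decay = cand$decay[k])
    }
  }
  new_classifier("mlpnn", fit = best$fit, size = best$size,
                 n_features = d, center = center, scale = scale,
                 meta = list(validation_accuracy = 100 * best$acc,
                             seed = seed, nweights = best$nweights,
                             decay = best$decay))
}

#' Train a Gaussian-kernel support vector machine
#'
#' Soft-margin SVM with the Gaussian kernel
#' \eqn{\kappa(x_i, x_j) = \exp(-\lVert x_i - x_j \rVert^2 / 2\sigma_k^2)}.
#' When `kernel_width` or `box_constraint` is `NULL` they are tuned on the
#' validation split over a logged grid (widths around the median pairwise
#' feature distance; costs 0.1, 1, 10). The decision value is oriented so
#' that the positive (spontaneous) class gets positive distances.
#'
#' @param ds A split `erp_dataset`.
#' @param kernel_width Gaussian kernel width \eqn{\sigma_k} (feature
#'   units); positive, or `NULL` to tune.
#' @param box_constraint Soft-margin cost `C`; positive, or `NULL` to tune.
#' @return An `erp_classifier` of kind `"svm"`.
#' @export
train_svm <- function(ds, kernel_width = NULL, box_constraint = NULL) {
  if (!is.null(kernel_width) && kernel_width <= 0)
    stop("'kernel_width' must be positive")
  if (!is.null(box_constraint) && box_constraint <= 0)
    stop("'box_constraint' must be positive")
  tr <- split_part(ds, "train")
  tune <- is.null(kernel_width) || is.null(box_constraint)
  widths <- if (is.null(kernel_width)) {
    sub <- tr$x[seq_len(min(200L, nrow(tr$x))), , drop = FALSE]
    med <- stats::median(stats::dist(sub))
    med * c(0.5, 1, 2)
  } else kernel_width
  costs <- if (is.null(box_constraint)) c(0.1, 1, 10) else box_constraint
  fit_one <- function(w, C)
    e1071::svm(tr$x, factor(tr$y, levels = c(0L, 1L)),
               kernel = "radial", gamma = 1 / (2 * w^2), cost = C,
               scale = FALSE)
  grid <- expand.grid(width = widths, cost = costs)
  if (tune) {
    va <- split_part(ds, "validation")
    accs <- vapply(seq_len(nrow(grid)), function(i) {
      f <- fit_one(grid$width[i], grid$cost[i])
      mean(as.integer(as.character(stats::predict(f, va$x))) == va$y)
    }, numeric(1))
    pick <- which.max(accs)
  } else pick <- 1L
  fit <- fit_one(grid$width[pick], grid$cost[pick])
  dv <- as.vector(attr(stats::predict(fit, tr$x, decision.values = TRUE),
                       "decision.values"))
  orientation <- if (mean(dv[tr$y == 1L]) >= mean(dv[tr$y == 0L])) 1 else -1
  m <- new_classifier("svm", fit = fit, orientation = orientation,
                      n_features = ncol(tr$x),
                      meta = list(kernel_width = grid$width[pick],
                                  box_constraint = grid$cost[pick],
                                  tuned = tune))
  m$meta$validation_accuracy <- try_validation_accuracy(m, ds)
  m
}

#' Wrap fixed linear weights as a classifier
#'
#' Builds a model whose distance is the affine score
#' \eqn{\Delta(x) = w^\top x + b} without any training. Useful for
#' analytic/oracle studies of the estimators, where a known linear
#' distance makes the amplitude objective an exact quadratic.
#'
#' @param weights Numeric weight vector `w`.
#' @param intercept Scalar intercept `b` (default 0).
#' @return An `erp_classifier` of kind `"linear"`.
#' @export
linear_classifier <- function(weights, intercept = 0) {
  new_classifier("linear", w = as.numeric(weights), b = intercept,
                 n_features = length(weights))
}

clamp_prob <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

#' Classifier distance of point-samples
#'
#' The scalar \eqn{\Delta(x, Z)} separating the two classes: strictly
#' increasing in the model's predicted probability that `x` is a
#' spontaneous (positive) sample, and zero on the decision boundary. For
#' logistic regression and fixed linear models it is the logit
#' \eqn{w^\top x + b}; for the MLP it is the log-odds of the positive
#' output; for the SVM it is the signed decision value oriented
#' positive-toward-spontaneous.
#'
#' @param model A trained `erp_classifier`.
#' @param x Feature vector, or matrix with one sample per row; the
#'   dimension must match the training dimension.
#' @return Numeric vector of distances, one per sample.
#' @export
distance <- function(model, x) {
  stopifnot(inherits(model, "erp_classifier"))
  x <- as_feature_matrix(model, x)
  switch(model$kind,
    lr = ,
    linear = drop(x %*% model$w) + model$b,
    mlpnn = {
      z <- scale(x, model$center, model$scale)
      p <- clamp_prob(as.vector(stats::predict(model$fit, z)))
      log(p / (1 - p))
    },
    svm = {
      dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
                 "decision.values")
      model$orientation * as.vector(dv)
    },
    stop("unknown classifier kind: ", model$kind))
}

#' Predicted class labels
#'
#' A sample is predicted spontaneous (label 1) when its distance is
#' positive.
#'
#' @inheritParams distance
#' @return Integer vector of 0/1 predictions.
#' @export
predict_class <- function(model, x) as.integer(distance(model, x) > 0)
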