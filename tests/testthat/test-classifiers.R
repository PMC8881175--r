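# iterative grid-search maximizer of the logistic log-likelihood,
# independent of glm
grid_ml_logistic <- function(x, y, rounds = 9, span = 8, steps = 13) {
  loglik <- function(w1, w2, b) {
    eta <- x[, 1] * w1 + x[, 2] * w2 + b
    sum(y * eta - log1p(exp(eta)))
  }
  center <- c(0, 0, 0)
  for (r in seq_len(rounds)) {
    g1 <- center[1] + seq(-span, span, length.out = steps)
    g2 <- center[2] + seq(-span, span, length.out = steps)
    g3 <- center[3] + seq(-span, span, length.out = steps)
    best <- c(NA, NA, NA); best_ll <- -Inf
    for (w1 in g1) for (w2 in g2) for (b in g3) {
      ll <- loglik(w1, w2, b)
      if (ll > best_ll) { best_ll <- ll; best <- c(w1, w2, b) }
    }
    center <- best
    span <- span * 2 / (steps - 1)   # keep neighbors of the best cell
  }
  center
}

test_that("logistic regression matches a grid-search likelihood oracle", {
  # overlapping classes so the MLE is finite
  withr::with_seed(101, {
    x <- matrix(rnorm(40), ncol = 2)
    y <- rbinom(20, 1, plogis(x[, 1] - x[, 2] + 0.3))
  })
  ds <- erp_dataset(x, y, trial_id = 1:20, time_ms = rep(0, 20),
                    splits = list(train = 1:20, validation = integer(0),
                                  test = integer(0)))
  m <- train_logistic(ds)
  expect_false(m$meta$separable)
  oracle <- grid_ml_logistic(x, y)
  expect_equal(unname(m$w), oracle[1:2], tolerance = 1e-3)
  expect_equal(unname(m$b), oracle[3], tolerance = 1e-3)
})

test_that("logistic distance is the logit and zero on the boundary", {
  m <- linear_classifier(c(2, -1), intercept = 0.5)
  x0 <- c(0.5, 1.5)   # 2*0.5 - 1.5 + 0.5 = 0
  expect_equal(distance(m, x0), 0)
  expect_equal(predict_class(m, rbind(c(1, 0), c(-1, 0))), c(1L, 0L))
  expect_error(distance(m, c(1, 2, 3)), "dimension")
})

test_that("a symmetric two-point problem puts the boundary through the origin", {
  v <- c(1, 2)
  x <- rbind(v, -v, v * 1.01, -v * 1.01)
  y <- c(0L, 1L, 0L, 1L)
  ds <- erp_dataset(x, y, 1:4, rep(0, 4),
                    splits = list(train = 1:4, validation = integer(0),
                                  test = integer(0)))
  m <- train_logistic(ds)
  expect_equal(unname(m$b) / max(abs(m$w)), 0, tolerance = 1e-3)
})

test_that("relabeling the classes flips every distance", {
  ds <- separable_dataset(gap = 2)
  flipped <- ds
  flipped$label <- 1L - ds$label
  m1 <- train_logistic(ds)
  m2 <- train_logistic(flipped)
  x <- ds$features[1:20, ]
  expect_equal(distance(m1, x), -distance(m2, x), tolerance = 1e-4)
})

test_that("MLP solves XOR where the linear model cannot", {
  withr::with_seed(17, {
    n <- 60
    cl <- sample(rep(0:3, n / 4))
    centers <- rbind(c(0, 0), c(3, 3), c(0, 3), c(3, 0))
    x <- centers[cl + 1, ] + matrix(rnorm(2 * n, sd = 0.4), ncol = 2)
    y <- as.integer(cl < 2)   # diagonal pairs: not linearly separable
  })
  ds <- erp_dataset(x, y, seq_len(n), rep(0, n))
  ds <- split_dataset(ds, c(0.5, 0.25, 0.25), seed = 1)
  mlp <- train_mlpnn(ds, seed = 1)
  lr <- train_logistic(ds)
  expect_gt(classification_accuracy(mlp, ds), 90)
  expect_lt(classification_accuracy(lr, ds), 70)
})

test_that("MLP training is deterministic under a fixed seed", {
  ds <- separable_dataset()
  m1 <- train_mlpnn(ds, seed = 5)
  m2 <- train_mlpnn(ds, seed = 5)
  expect_identical(m1$size, m2$size)
  expect_identical(m1$fit$wts, m2$fit$wts)
  expect_error(train_mlpnn(ds, candidate_sizes = numeric(0)), "non-empty")
})

test_that("classifiers separate an easy problem and expose oriented distances", {
  ds <- separable_dataset(gap = 5)
  for (m in list(train_logistic(ds), train_mlpnn(ds, seed = 2),
                 train_svm(ds, kernel_width = 2, box_constraint = 1))) {
    expect_equal(classification_accuracy(m, ds), 100)
    te <- ds$features[ds$splits$test, ]
    ye <- ds$label[ds$splits$test]
    d <- distance(m, te)
    expect_true(all(d[ye == 1] > 0))
    expect_true(all(d[ye == 0] < 0))
  }
  expect_error(train_svm(ds, kernel_width = -1), "kernel_width")
  expect_error(train_svm(ds, kernel_width = 1, box_constraint = 0), "box")
})

test_that("distance orders samples exactly as the predicted probability", {
  ds <- separable_dataset(gap = 2)
  mlp <- train_mlpnn(ds, seed = 3)
  withr::with_seed(29, x <- matrix(rnorm(200, mean = 2, sd = 2), ncol = 2))
  d <- distance(mlp, x)
  z <- scale(x, mlp$center, mlp$scale)
  p <- as.vector(predict(mlp$fit, z))
  ord_pairs <- cbind(sample(100), sample(100))
  for (k in 1:100) {
    i <- ord_pairs[k, 1]; j <- ord_pairs[k, 2]
    if (p[i] != p[j]) expect_equal(d[i] > d[j], p[i] > p[j])
  }
  # the MLP distance is the log-odds: p = 0.5 maps to 0
  expect_equal(d[which.min(abs(p - 0.5))],
               log(p[which.min(abs(p - 0.5))] / (1 - p[which.min(abs(p - 0.5))])))
})

test_that("separable data triggers the flagged ridge fallback", {
  x <- rbind(c(-2, 0), c(-3, 1), c(2, 0), c(3, -1))
  y <- c(1L, 1L, 0L, 0L)
  ds <- erp_dataset(x, y, 1:4, rep(0, 4),
                    splits = list(train = 1:4, validation = integer(0),
                                  test = integer(0)))
  m <- train_logistic(ds)
  expect_true(m$meta$separable)
  expect_true(all(is.finite(m$w)))
  expect_equal(predict_class(m, x), y)
})
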