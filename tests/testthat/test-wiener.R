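# Independent ridge oracle: augmented-rows least squares solved by QR
# (a different computational path from the normal-equation Cholesky solve).
ridge_qr_oracle <- function(X, Y, lambda, bias_col = ncol(X)) {
  n <- nrow(X)
  pen <- diag(sqrt(n * lambda), ncol(X))
  pen[bias_col, bias_col] <- 0
  fit <- lm.fit(rbind(X, pen), rbind(Y, matrix(0, ncol(X), ncol(Y))))
  unname(coef(fit))
}

test_that("the lagged design stacks M windows and a bias column", {
  set.seed(1)
  F16 <- matrix(rnorm(40 * 112), 40)   # 16 channels x 7 features
  X <- build_lagged_design(F16, M = 6)
  expect_equal(ncol(X), 672 + 1)
  expect_equal(attr(X, "bias_col"), 673)
  # 12 channels x 7 features
  expect_equal(ncol(build_lagged_design(F16[, 1:84], M = 6)), 504 + 1)
  # M = 1 reduces to the feature matrix plus bias
  X1 <- build_lagged_design(F16, M = 1)
  expect_equal(unname(X1[, 1:112]), unname(F16))
  expect_true(all(X1[, 113] == 1))
  # early rows are zero-padded for missing lags
  expect_true(all(X[1, 113:672] == 0))
  expect_equal(unname(X[3, 113:224]), unname(F16[2, ]))
  expect_error(build_lagged_design(F16, M = 50), "exceeds")
})

test_that("the Wiener solve matches noiseless truth and the QR ridge oracle", {
  set.seed(2)
  X <- cbind(matrix(rnorm(60 * 7), 60), 1)
  attr(X, "bias_col") <- 8
  H_true <- matrix(rnorm(8 * 3), 8)
  Y <- X %*% H_true
  expect_equal(fit_wiener(X, Y, 0), H_true, tolerance = 1e-6,
               ignore_attr = TRUE)

  # oracle equivalence on random instances across the lambda range
  for (i in 1:5) {
    Xr <- cbind(matrix(rnorm(50 * 8), 50), 1)
    attr(Xr, "bias_col") <- 9
    Yr <- matrix(rnorm(50 * 2), 50)
    for (lam in c(0.01, 0.1, 1, 100)) {
      expect_equal(fit_wiener(Xr, Yr, lam),
                   ridge_qr_oracle(Xr, Yr, lam, 9), tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  }

  # monotone shrinkage of the non-bias weights
  Xs <- cbind(matrix(rnorm(80 * 10), 80), 1); attr(Xs, "bias_col") <- 11
  Ys <- matrix(rnorm(80 * 2), 80)
  norms <- vapply(10^seq(-3, 5), function(l) {
    sqrt(sum(fit_wiener(Xs, Ys, l)[1:10, ]^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))

  # a singular unregularized system asks for lambda > 0
  Xsing <- cbind(1:10, 1:10, 1)
  attr(Xsing, "bias_col") <- 3
  expect_error(fit_wiener(Xsing, matrix(rnorm(10)), 0), "lambda > 0")
  expect_error(fit_wiener(Xs * NA, Ys, 1), "non-finite")
})

test_that("exponential smoothing follows the recursion and contracts", {
  y <- matrix(rnorm(50 * 3), 50)
  expect_identical(exp_smooth(y, 1), y)
  s0 <- exp_smooth(y, 0)
  expect_true(all(s0 == rep(y[1, ], each = 50)))
  expect_equal(exp_smooth(c(1, 0, 0), 0.5), c(1, 0.5, 0.25))
  expect_error(exp_smooth(y, 1.2), "\\[0, 1\\]")

  # smoothing never increases variance
  for (a in seq(0, 1, by = 0.1)) {
    s <- exp_smooth(y, a)
    expect_true(all(apply(s, 2, var) <= apply(y, 2, var) + 1e-12))
  }
})

test_that("multivariate R2 is the pooled coefficient of determination", {
  set.seed(3)
  Y <- matrix(rnorm(40 * 5), 40)
  expect_equal(multivariate_r2(Y, Y), 1)
  means <- matrix(colMeans(Y), 40, 5, byrow = TRUE)
  expect_equal(multivariate_r2(Y, means), 0)
  # hand-computed toy: SSE = 0.5, SStot = 1
  Yt <- rbind(c(0, 0), c(1, 1))
  Yp <- rbind(c(0, 0.5), c(1, 0.5))
  expect_equal(multivariate_r2(Yt, Yp), 0.5)
  expect_error(multivariate_r2(matrix(1, 5, 2), matrix(1, 5, 2)), "constant")
  expect_error(multivariate_r2(Y, Y[1:10, ]), "shape")
})

test_that("prediction is causal, clipped, and bias-driven at zero weights", {
  fit <- fx_small_model()
  te <- fx_small_sessions()$test
  pred <- predict(fit, te$emg)
  m <- doa_matrix(pred)
  expect_true(all(m >= 0 & m <= 1))

  # zero weights with bias b predict the constant b
  zero <- fit
  zero$weights[] <- 0
  zero$weights[nrow(zero$weights), ] <- 0.3
  mz <- doa_matrix(predict(zero, te$emg))
  expect_true(all(mz == 0.3))

  expect_error(predict(fit, te$emg$signal[, 1:3, drop = FALSE]), "channels")
})

test_that("streaming and batch prediction agree bit-for-bit", {
  fit <- fx_small_model()
  te <- fx_small_sessions()$test
  n_keep <- 142 + 56 * 60
  sig <- te$emg$signal[seq_len(n_keep), ]
  batch <- doa_matrix(predict(fit, sig))
  st <- decoder_stream_init(fit)
  preds <- list(decoder_stream_feed(fit, st, sig[1:142, ]))
  for (k in seq_len(60)) {
    preds[[k + 1]] <- decoder_stream_feed(fit, st,
                                          sig[142 + (k - 1) * 56 + 1:56, ])
  }
  stream <- do.call(rbind, preds)
  expect_identical(unname(stream), unname(batch))
})
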