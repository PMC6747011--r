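# Build tiny feature/target fixtures where only some channels carry signal:
# each channel contributes `fpc` feature columns; informative channels get
# the target plus noise, noise channels pure noise.
make_selection_data <- function(n, n_channels, informative, fpc = 2,
                                noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  # fixed channel -> target projections shared by both splits
  proj <- lapply(seq_len(n_channels * fpc), function(i) rnorm(5))
  build <- function() {
    Y <- matrix(runif(n * 5), n)
    vals <- matrix(rnorm(n * n_channels * fpc), n)
    for (ch in informative) {
      for (f in seq_len(fpc)) {
        col <- (ch - 1) * fpc + f
        vals[, col] <- Y %*% proj[[col]] + rnorm(n, sd = noise_sd)
      }
    }
    fm <- list(values = matrix(as.numeric(scale(vals)), n),
               n_channels = n_channels, features_per_channel = fpc)
    list(fm = fm, y = Y)
  }
  tr <- build(); va <- build()
  list(train = tr$fm, train_y = tr$y, valid = va$fm, valid_y = va$y)
}

test_that("forward selection finds the informative channels and stops", {
  d <- make_selection_data(300, 6, informative = c(2, 5), seed = 10)
  res <- sequential_forward_sensors(d$train, d$train_y, d$valid, d$valid_y,
                                    M = 2)
  expect_true(all(c(2, 5) %in% res$sensors))
  expect_s3_class(res$trace, "tbl_df")
  # accepted steps never decrease the running best validation score
  acc <- res$trace[res$trace$accepted, ]
  expect_true(all(diff(acc$r2) >= 0) || nrow(acc) <= 1)

  # a single candidate channel is returned as-is
  d1 <- make_selection_data(200, 1, informative = 1, seed = 11)
  res1 <- sequential_forward_sensors(d1$train, d1$train_y, d1$valid,
                                     d1$valid_y, M = 2)
  expect_equal(res1$sensors, 1L)

  # pure-noise channels: no sustained improvement, few channels kept
  dn <- make_selection_data(200, 6, informative = integer(0), seed = 12)
  resn <- sequential_forward_sensors(dn$train, dn$train_y, dn$valid,
                                     dn$valid_y, M = 2)
  expect_lte(length(resn$sensors), 2)
})

test_that("the lambda search uses the 8-point log grid with smallest-tie rule", {
  d <- make_selection_data(250, 4, informative = 1:4, seed = 13)
  res <- grid_search_lambda(d$train, d$train_y, d$valid, d$valid_y,
                            sensors = 1:4, M = 2)
  expect_equal(nrow(res$trace), 8)
  expect_equal(sort(res$trace$value), 10^(-6:1))
  expect_true(res$lambda %in% 10^(-6:1))

  # duplicated (perfectly collinear) channels need regularization
  dd <- make_selection_data(250, 2, informative = 1:2, noise_sd = 0,
                            seed = 14)
  dd$train$values[, 3:4] <- dd$train$values[, 1:2]
  dd$valid$values[, 3:4] <- dd$valid$values[, 1:2]
  resc <- grid_search_lambda(dd$train, dd$train_y, dd$valid, dd$valid_y,
                             sensors = 1:2, M = 2)
  expect_gt(resc$lambda, 1e-6)

  # whitened, noiseless features: the smallest lambda wins
  set.seed(15)
  n <- 400
  V <- qr.Q(qr(matrix(rnorm(n * 8), n))) * sqrt(n)
  fmw <- list(values = V, n_channels = 4, features_per_channel = 2)
  H <- matrix(rnorm(8 * 5), 8)
  Yw <- V %*% H
  resw <- grid_search_lambda(fmw, Yw, fmw, Yw, sensors = 1:4, M = 1)
  expect_equal(resw$lambda, 1e-6)
})

test_that("the alpha line search scans 101 values with largest-tie rule", {
  set.seed(16)
  Y <- matrix(runif(200 * 5), 200)
  res <- line_search_alpha(Y, Y)
  expect_equal(nrow(res$trace), 101)
  expect_equal(res$trace$value, seq(0, 1, by = 0.01))
  # targets equal raw predictions: the identity (alpha = 1) is optimal
  expect_equal(res$alpha, 1)

  # high-frequency alternating noise rewards smoothing
  noise <- matrix(rep(c(0.2, -0.2), 100), 200, 5)
  resn <- line_search_alpha(Y * 0.6 + 0.2 + noise, Y * 0.6 + 0.2)
  expect_lt(resn$alpha, 1)
})

test_that("select_and_finalize runs the stages in order without test leakage", {
  fit <- select_and_finalize(fx_small_sessions()$train,
                             fx_small_sessions()$valid)
  tr <- fit$trace
  expect_equal(tr$stage_order, c("sensors", "lambda", "alpha"))
  expect_equal(sort(unique(tr$evaluations$stage)),
               sort(c("sensors", "lambda", "alpha")))
  # the model's sensor list is exactly the stage-1 output
  stage1 <- tr$evaluations[tr$evaluations$stage == "sensors" &
                             tr$evaluations$accepted, ]
  expect_setequal(fit$sensors, stage1$candidate)
  expect_equal(tr$chosen$sensors, fit$sensors)
  expect_equal(tr$chosen$lambda, fit$lambda)
  expect_equal(tr$chosen$alpha, fit$alpha)

  # determinism: same inputs give an identical trace and weights
  fit2 <- select_and_finalize(fx_small_sessions()$train,
                              fx_small_sessions()$valid)
  expect_identical(fit$weights, fit2$weights)
  expect_equal(fit$trace$evaluations, fit2$trace$evaluations)

  # the test split is only touched after finalization, and generalizes
  best_valid <- max(tr$evaluations$r2[tr$evaluations$accepted])
  test_r2 <- evaluate_offline(fit, fx_small_sessions()$test)
  expect_gte(test_r2, best_valid - 0.05)
})

test_that("tidy and glance expose the fitted decoder", {
  fit <- fx_small_model()
  g <- glance(fit)
  expect_equal(g$d_lagged, 672)
  expect_equal(g$lags, 6)
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(fit$weights) * 5)
  expect_true(all(c("term", "channel", "feature", "lag", "doa",
                    "estimate") %in% names(td)))
  expect_equal(sum(td$term == "(bias)"), 5)
})
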