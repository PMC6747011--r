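test_that("block PCA is deterministic with orthonormal sign-fixed components", {
  set.seed(1)
  # data on one direction: PC1 explains everything
  dir <- c(1, 2, -1, 0.5)
  X <- outer(rnorm(500), dir)
  p <- block_pca(X)
  expect_equal(p$ev_ratio[1], 1)
  expect_equal(abs_cosine_similarity(p$rotation[, 1], dir), 1)

  # isotropic noise: all ratios near 1/channels
  Xi <- matrix(rnorm(1e5 * 4), ncol = 4)
  pi4 <- block_pca(Xi)
  expect_true(all(abs(pi4$ev_ratio - 0.25) < 0.02))

  # orthonormal rotation, identical blocks give identical components
  expect_true(max(abs(crossprod(pi4$rotation) - diag(4))) < 1e-10)
  expect_identical(block_pca(Xi)$rotation, pi4$rotation)

  expect_error(block_pca(matrix(1, 10, 3)), "zero variance")
})

test_that("absolute cosine similarity matches hand geometry", {
  expect_equal(abs_cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(abs_cosine_similarity(c(1, 2, 3), -c(1, 2, 3)), 1)
  expect_equal(abs_cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(abs_cosine_similarity(c(1, 1), c(1, 0)), sqrt(2) / 2)
  expect_error(abs_cosine_similarity(c(0, 0), c(1, 0)), "zero")
})

test_that("component matching recovers permutations and rotations", {
  set.seed(2)
  X <- matrix(rnorm(2000 * 4), ncol = 4) %*% diag(c(3, 2, 1, 0.5))
  ref <- block_pca(X)

  ident <- match_components(ref, ref, k = 3)
  expect_equal(ident$matched_pc, 1:3)
  expect_equal(ident$similarity, rep(1, 3))

  # swap PC1/PC2 in the other block
  sw <- ref
  sw$rotation <- ref$rotation[, c(2, 1, 3, 4)]
  msw <- match_components(ref, sw, k = 2)
  expect_equal(msw$matched_pc, c(2, 1))
  expect_equal(msw$similarity, rep(1, 2))

  # 45-degree rotation in the PC1-PC2 plane
  rot <- ref
  theta <- pi / 4
  rot$rotation[, 1] <- cos(theta) * ref$rotation[, 1] +
    sin(theta) * ref$rotation[, 2]
  rot$rotation[, 2] <- -sin(theta) * ref$rotation[, 1] +
    cos(theta) * ref$rotation[, 2]
  mr <- match_components(ref, rot, k = 2)
  expect_equal(mr$similarity, rep(sqrt(2) / 2, 2), tolerance = 1e-9)
})

test_that("reference-projected variance behaves like a projection", {
  set.seed(3)
  X <- matrix(rnorm(1000 * 5), ncol = 5) %*% diag(c(3, 2, 1.5, 1, 0.5))
  p <- block_pca(X)
  # complete basis explains 100%
  expect_equal(variance_explained_by_reference(X, p, k = 5), 100)
  # same data: reference projection equals the own explained-variance ratio
  expect_equal(variance_explained_by_reference(X, p, k = 2),
               100 * sum(p$ev_ratio[1:2]), tolerance = 1e-9)
  # a reference orthogonal to the data explains nothing
  dir <- c(1, 0, 0)
  Y <- cbind(0, outer(rnorm(200), c(1, 1)))
  ref <- list(rotation = matrix(c(1, 0, 0), 3), ev_ratio = 1, n_channels = 3)
  class(ref) <- "block_pca"
  expect_equal(variance_explained_by_reference(Y, ref, k = 1), 0)
  expect_error(variance_explained_by_reference(Y[, 1:2], p, 1), "channel")

  # projection optimality: own top-k never loses to another block's PCs
  for (i in 1:10) {
    A <- matrix(rnorm(300 * 6), ncol = 6) %*% matrix(rnorm(36), 6)
    B <- matrix(rnorm(300 * 6), ncol = 6) %*% matrix(rnorm(36), 6)
    pa <- block_pca(A)
    for (k in c(1, 2, 3)) {
      own <- 100 * sum(block_pca(B)$ev_ratio[seq_len(k)])
      expect_lte(variance_explained_by_reference(B, pa, k), own + 1e-9)
    }
  }
})

test_that("channel power scales quadratically and splits by sensor group", {
  set.seed(4)
  pw <- tibble::tibble(block = rep(1:2, each = 4),
                       channel = rep(1:4, 2),
                       power = c(0, 1, 4, 9, 0, 2, 8, 18))
  out <- channel_power_by_block(pw, used = c(2, 3), non_used = 4)
  expect_equal(out$power[out$group == "used"], c(2.5, 5))
  expect_equal(out$power[out$group == "non_used"], c(9, 18))
  expect_error(channel_power_by_block(pw, used = 1:2, non_used = 2:3),
               "disjoint")
  expect_warning(channel_power_by_block(pw, used = 1:4,
                                        non_used = integer(0)), "empty")

  # mean squared raw sample: unit-variance noise has power ~ 1,
  # doubling the amplitude quadruples it
  x <- rnorm(1e5)
  expect_equal(mean(x^2), 1, tolerance = 0.02)
  expect_equal(mean((2 * x)^2) / mean(x^2), 4, tolerance = 1e-9)
})

test_that("DOA variability is the population SD averaged over DOAs", {
  frozen <- matrix(0.4, 30, 5)
  expect_equal(doa_variability(list(frozen))$sd, 0)
  alt <- matrix(rep(c(0, 1), 15), 30, 5)
  expect_equal(doa_variability(list(alt))$sd, 0.5)
  # scaling the trajectory scales the SD
  set.seed(5)
  tr <- matrix(runif(30 * 5), 30)
  expect_equal(doa_variability(list(tr * 0.3))$sd,
               0.3 * doa_variability(list(tr))$sd, tolerance = 1e-12)
  expect_warning(v1 <- doa_variability(list(tr[1, , drop = FALSE])),
                 "single-sample")
  expect_equal(v1$sd, 0)
})

test_that("the omnibus normality test matches the reference implementation", {
  x <- c(0.12, -0.54, 1.3, 2.1, -0.3, 0.7, -1.1, 0.45, 0.02, 1.9, -0.8,
         0.33)
  got <- dagostino_pearson(x)
  expect_equal(got$statistic, 0.7166727134904894, tolerance = 1e-10)
  expect_equal(got$p.value, 0.6988379766030115, tolerance = 1e-10)
  expect_equal(got$z_skew, 0.759101186108811, tolerance = 1e-10)
  expect_equal(got$z_kurt, -0.3747507207980868, tolerance = 1e-10)

  y <- exp(seq(0, 3, length.out = 12))
  goty <- dagostino_pearson(y)
  expect_equal(goty$statistic, 3.8158948491419875, tolerance = 1e-10)

  expect_error(dagostino_pearson(rnorm(6)), "at least 8")
  expect_error(dagostino_pearson(rep(1, 12)), "zero variance")
})

test_that("the early/late comparison gates on normality and sizes effects", {
  set.seed(6)
  # identical samples: degenerate null result
  e <- runif(12)
  null_res <- early_late_comparison(e, e)
  expect_equal(null_res$p.value, 1)
  expect_equal(null_res$effect_size, 0.5)

  # constant shift with normal noise: significant paired t, large d
  early <- rnorm(12, 50, 3)
  late <- early - 10 + rnorm(12, 0, 1)
  shift <- early_late_comparison(early, late)
  expect_equal(shift$test, "paired_t")
  expect_lt(shift$p.value, 0.001)
  expect_gt(shift$effect_size, 2)

  # CLES enumeration: pairs (2,1), (3,1), (1,2) -> 2/3
  expect_equal(cles(c(2, 3, 1), c(1, 1, 2)), 2 / 3)
  expect_equal(cohens_d_paired(c(5, 7, 9), c(4, 5, 6)), mean(c(1, 2, 3)) /
                 sd(c(1, 2, 3)))
})

test_that("offline/real-time correlation handles exact and null cases", {
  x <- c(0.4, 0.5, 0.6, 0.7, 0.55, 0.62, 0.48, 0.58, 0.66, 0.52, 0.44, 0.6)
  r1 <- offline_realtime_correlation(x, x, n_boot = 50, seed = 1)
  expect_equal(r1$r, 1)
  r2 <- offline_realtime_correlation(x, -x, n_boot = 50, seed = 1)
  expect_equal(r2$r, -1)
  expect_error(offline_realtime_correlation(x, rep(1, 12)), "zero variance")
  expect_error(offline_realtime_correlation(x[1:2], x[1:2]), "at least 3")

  # independent pairs: mean correlation near 0
  set.seed(7)
  rs <- replicate(2000, {
    offline_realtime_correlation(rnorm(12), rnorm(12), n_boot = 2,
                                 seed = 1)$r
  })
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("the adaptation report tracks co-activation drift", {
  # rotating mixing columns: PC1 similarity to block 1 decays with block
  user <- synergy_model(noise_sd0 = 0.05, adaptation_rate = 0,
                        rotation_rate = 0.15, seed = 9)
  set.seed(10)
  intent <- matrix(runif(500 * 5), 500)
  env_blocks <- lapply(1:6, function(b) {
    emgdecode:::simulate_envelope(intent, user, fs = 25, block = b)
  })
  rep_rot <- analyze_adaptation(env_blocks)
  expect_equal(rep_rot$sim_pc1[1], 1)
  expect_lt(rep_rot$sim_pc1[6], rep_rot$sim_pc1[1])
  expect_lt(cor(rep_rot$block, rep_rot$sim_pc1, method = "spearman"), 0)
  # own-block explained variance never loses to the block-1 projection
  expect_true(all(rep_rot$var_own_pc12 >= rep_rot$var_ref_pc12 - 1e-9))

  # frozen mixing: similarity stays essentially 1
  user0 <- synergy_model(noise_sd0 = 0.05, adaptation_rate = 0,
                         rotation_rate = 0, seed = 9)
  env0 <- lapply(1:6, function(b) {
    emgdecode:::simulate_envelope(intent, user0, fs = 25, block = b)
  })
  rep0 <- analyze_adaptation(env0)
  expect_true(all(rep0$sim_pc1 > 0.95))
})
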