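test_that("intent trajectories follow the posture templates", {
  # index flexion drives only the index DOA, peaking at full flexion
  traj <- make_intent_trajectory(3, duration_s = 7, rate_hz = 25)
  m <- doa_matrix(traj)
  expect_equal(max(m[, "index"]), 1)
  expect_true(all(m[, setdiff(colnames(m), "index")] == 0))

  # cylindrical grip reaches all five DOAs at 1 at the peak
  m7 <- doa_matrix(make_intent_trajectory(7, duration_s = 7, rate_hz = 25))
  expect_equal(unname(m7[which.max(rowSums(m7)), ]), rep(1, 5))

  # every motion starts and ends at the rest pose
  for (id in 1:9) {
    m <- doa_matrix(make_intent_trajectory(id, duration_s = 5, rate_hz = 25))
    expect_equal(unname(m[1, ]), rep(0, 5))
    expect_equal(unname(m[nrow(m), ]), rep(0, 5))
    expect_true(all(m >= 0 & m <= 1))
  }

  expect_error(make_intent_trajectory(12), "1\\.\\.9")
})

test_that("simulated EMG is an amplitude-modulated envelope with baseline rest", {
  rest <- doa_trajectory(matrix(0, 100, 5), (0:99) / 25)
  user <- synergy_model(noise_sd0 = 0, seed = 5)
  env <- emgdecode:::simulate_envelope(doa_matrix(rest), user, fs = 25,
                                       block = 1)
  expect_true(all(env == user$baseline))

  # determinism under a fixed seed
  traj <- make_intent_trajectory(7, 3, 25)
  e1 <- simulate_emg(traj, user, seed = 9)
  e2 <- simulate_emg(traj, user, seed = 9)
  expect_identical(e1$signal, e2$signal)

  expect_error(simulate_emg(traj, user, fs = -1), "positive")
})

test_that("a zeroed mixing column decouples that DOA from the envelopes", {
  mix <- matrix(runif(16 * 5, 0.2, 1), 16, 5)
  mix[, 1] <- 0
  mix[1:15, 1] <- c(rep(0, 14), 1e-9)  # keep full column rank
  user <- synergy_model(mixing = mix, noise_sd0 = 0, seed = 6)
  n <- 10000
  set.seed(42)
  intent <- matrix(runif(n * 5), n)
  env <- emgdecode:::simulate_envelope(intent, user, fs = 100, block = 1)
  cors <- abs(cor(intent[, 1], env))
  expect_true(all(cors < 0.1))
})

test_that("calibration sessions have the protocol's segment structure", {
  u <- fx_user_small()
  s <- fx_small_sessions()
  # test split: 9 motions x 2 repetitions
  expect_equal(nrow(s$test$segments), 18)
  expect_setequal(unique(s$test$segments$motion_id), 1:9)
  expect_true(all(table(s$test$segments$motion_id) == 2))
  # labels agree with the segment schedule
  expect_setequal(unique(s$test$labels), 0:9)

  # full-size training split: 90 segments and >= 90 x (7 + 3) s of signal
  full_train <- generate_calibration_session(fx_user_small(), "training",
                                             seed = 1)
  expect_equal(nrow(full_train$segments), 90)
  expect_gte(nrow(full_train$emg$signal) / full_train$emg$fs, 90 * 10)
})

test_that("execution-noise power decreases across blocks when adapting", {
  user <- synergy_model(noise_sd0 = 0.2, adaptation_rate = 0.4, seed = 3)
  expect_equal(noise_sd_at_block(user, 1), 0.2)
  expect_equal(noise_sd_at_block(user, 4), 0.2 * exp(-0.4 * 3))
  set.seed(7)
  intent <- matrix(runif(2000 * 5), 2000)
  clean <- emgdecode:::simulate_envelope(
    intent, synergy_model(mixing = user$mixing, noise_sd0 = 0, seed = 3),
    fs = 100, block = 1)
  noise_power <- vapply(1:6, function(b) {
    set.seed(b)
    env <- emgdecode:::simulate_envelope(intent, user, fs = 100, block = b)
    mean((env - clean)^2)
  }, numeric(1))
  expect_true(all(diff(noise_power) < 0))
})

test_that("virtual user corrections close the loop on the target", {
  user <- synergy_model(noise_sd0 = 0, seed = 2)
  target <- c(0.8, 0.2, 1, 0, 0.5)
  intent <- rep(0.4, 5)
  # observed == target: intent unchanged without noise
  expect_equal(virtual_user_command(intent, target, target, user, 0.5), intent)
  # gain 0: intent constant
  expect_equal(virtual_user_command(intent, target, rep(0, 5), user, 0), intent)
  # gain 1 with an identity decoder reaches the target in one step
  expect_equal(virtual_user_command(intent, target, intent, user, 1), target)
  expect_error(virtual_user_command(intent, target, intent, user, 1.5),
               "\\[0, 1\\]")
})

test_that("amputee presets reduce the electrode count", {
  expect_equal(synergy_model_preset("amputee1")$n_channels, 13)
  expect_equal(synergy_model_preset("amputee2")$n_channels, 12)
  expect_equal(synergy_model_preset("able_bodied")$n_channels, 16)
})

test_that("session serialization round-trips through the CSV+JSON dialect", {
  s <- fx_small_sessions()$test
  dir <- withr::local_tempdir()
  write_session(s, dir)
  r <- read_session(dir)
  expect_equal(r$emg$signal, s$emg$signal, ignore_attr = TRUE)
  expect_equal(r$glove$signal, s$glove$signal, ignore_attr = TRUE)
  expect_identical(r$labels, s$labels)
  expect_equal(r$split, s$split)
  expect_equal(r$meta$seed, s$meta$seed)
})
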