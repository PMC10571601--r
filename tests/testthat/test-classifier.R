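test_that("parameter count matches the closed form for arbitrary configs", {
  expect_equal(n_parameters(model_config()), 17932)
  tiny <- model_config(n_channels = 1, history_len = 1, lstm_units = 1,
                       fc1_units = 1, fc2_units = 2)
  expect_equal(n_parameters(tiny), 18)   # 4*(1+1+1) + (1+1) + (2+2)
  set.seed(12)
  for (i in 1:8) {
    cfg <- model_config(n_channels = sample(1:6, 1),
                        history_len = sample(1:4, 1),
                        lstm_units = sample(1:5, 1),
                        fc1_units = sample(1:4, 1),
                        fc2_units = 2)
    m <- build_model(cfg)
    direct <- sum(vapply(m[c("W", "U", "b", "W1", "b1", "W2", "b2")],
                         length, 0L))
    expect_equal(n_parameters(cfg), direct)
  }
})

test_that("weight initialization and prediction are deterministic", {
  cfg <- model_config(n_channels = 4, lstm_units = 3, seed = 9)
  m1 <- build_model(cfg); m2 <- build_model(cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$W1, m2$W1)
  x <- matrix(rnorm(10 * 4), 10, 4)
  expect_identical(predict(m1, x), predict(m1, x))
})

test_that("softmax probabilities sum to one and ties break toward rest", {
  m <- build_model(model_config(n_channels = 4, lstm_units = 3, seed = 1))
  set.seed(2)
  X <- array(rnorm(5 * 10 * 4), c(5, 10, 4))
  P <- predict(m, X)
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  m0 <- m
  m0$W2[] <- 0; m0$b2[] <- 0
  P0 <- predict(m0, X)
  expect_equal(unname(P0), matrix(0.5, 5, 2))
  expect_true(all(predict(m0, X, type = "class") == "rest"))
  expect_error(predict(m, matrix(0, 3, 4)), "history x channels")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- model_config(n_channels = 3, history_len = 4, lstm_units = 3,
                      fc1_units = 3, seed = 2)
  m <- build_model(cfg)
  set.seed(1)
  X <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  Y <- matrix(c(1, 0, 0, 1), 2, 2)
  loss <- function(mm) {
    P <- ecogclick:::model_forward(mm, X)$P
    -mean(log(rowSums(P * Y)))
  }
  fw <- ecogclick:::model_forward(m, X, want_cache = TRUE)
  bk <- ecogclick:::model_backward(m, fw$cache, (fw$P - Y) / 2, want_dX = TRUE)
  eps <- 1e-6
  for (p in c("W", "U", "b", "W1", "b1", "W2", "b2")) {
    idx <- seq(1, length(m[[p]]), length.out = min(6, length(m[[p]])))
    for (i in round(idx)) {
      m2 <- m; m2[[p]][i] <- m2[[p]][i] + eps
      m3 <- m; m3[[p]][i] <- m3[[p]][i] - eps
      expect_equal(bk$grads[[p]][i], (loss(m2) - loss(m3)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
  # input gradient of the grasp probability
  gX <- input_gradient(m, X)
  pg <- function(XX) sum(ecogclick:::model_forward(m, XX)$P[, 2])
  i <- 11
  X2 <- X; X2[i] <- X2[i] + eps
  X3 <- X; X3[i] <- X3[i] - eps
  expect_equal(gX[i], (pg(X2) - pg(X3)) / (2 * eps), tolerance = 1e-5)
})

test_that("training reduces loss and is seed-deterministic", {
  fx <- fx_small()
  m <- train_model(build_model(model_config(n_channels = 8, seed = 3)),
                   fx$dataset, epochs = 10)
  expect_lte(utils::tail(m$training_log$loss, 1), m$training_log$loss[1])
  m2 <- train_model(build_model(model_config(n_channels = 8, seed = 3)),
                    fx$dataset, epochs = 10)
  expect_identical(m$W, m2$W)
  expect_identical(m$training_log, m2$training_log)
  expect_error(train_model(m, fx$dataset, sample_idx = integer(0)), "empty")
})

test_that("a high-SNR dataset is decoded well above chance on held-out folds", {
  fx <- fx_small()
  tr <- which(fx$dataset$fold_ids != 4)
  va <- which(fx$dataset$fold_ids == 4)
  m <- train_model(build_model(model_config(n_channels = 8, seed = 5)),
                   fx$dataset, sample_idx = tr)
  expect_gte(evaluate_accuracy(m, fx$dataset, va), 0.85)
})

test_that("cross-validation bookkeeping: confusion normalization and validation coverage", {
  # perfectly separable toy problem: two constant, disjoint patterns
  n <- 48
  seqs <- array(0, c(n, 10, 4))
  labs <- rep(c("rest", "grasp"), n / 2)   # alternating: every fold balanced
  for (i in seq_len(n)) seqs[i, , ] <- if (labs[i] == "grasp") 5 else -5
  toy <- structure(list(sequences = seqs,
                        labels = factor(labs, c("rest", "grasp")),
                        fold_ids = rep(1:4, each = n / 4),
                        history_len = 10), class = "labeled_dataset")
  cv <- cross_validate(toy, model_config(n_channels = 4, lstm_units = 4),
                       repetitions = 2, epochs = 15, seed = 8)
  expect_equal(sum(cv$confusion_pct), 100, tolerance = 0.01)
  expect_equal(cv$mean_accuracy, 1.0)
  expect_equal(dim(cv$fold_accuracy), c(2, 4))
  # every sample validated once per repetition
  expect_equal(sum(table(toy$fold_ids)), n)
  bad <- toy; bad$labels <- factor(rep("rest", n), c("rest", "grasp"))
  expect_error(cross_validate(bad, model_config(n_channels = 4)), "single class")
})

test_that("decoding accuracy is monotone in effect size with chance at zero", {
  accs <- vapply(c(0, 1, 3), function(z) {
    cfg <- sim_config(n_channels = 8, active_channels = c(3, 4), n_trials = 24,
                      isi_bounds_s = c(2.2, 3.0), hg_effect_z = z,
                      calib_duration_s = 20, seed = 11)
    stats <- compute_calibration_stats(generate_calibration(cfg))
    blk <- generate_training_block(cfg)
    ft <- feature_stream(blk, stats)
    ds <- build_dataset(ft, assign_stream_labels(ft, event_times(blk, "cue")),
                        n_folds = 4)
    cross_validate(ds, model_config(n_channels = 8), epochs = 40,
                   seed = 7)$mean_accuracy
  }, 0)
  expect_lt(abs(accs[1] - 0.5), 0.12)
  expect_gte(accs[2], accs[1] - 0.05)
  expect_gte(accs[3], accs[2] - 0.05)
  expect_gt(accs[3], 0.85)
})
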