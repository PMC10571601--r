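test_that("calibration recording has the configured geometry and is seed-reproducible", {
  cfg <- sim_config(n_channels = 2, active_channels = 1, seed = 5)
  rec <- generate_calibration(cfg, duration_s = 60)
  expect_equal(ncol(rec$data), 60000)   # duration x rate
  expect_equal(nrow(rec$data), 2)
  expect_equal(nrow(rec$events), 0)
  expect_false(anyNA(rec$data))
  rec2 <- generate_calibration(cfg, duration_s = 60)
  expect_identical(rec$data, rec2$data)
  cfg2 <- cfg; cfg2$seed <- 6
  expect_false(identical(generate_calibration(cfg2, duration_s = 60)$data,
                         rec$data))
})

test_that("rest recording is trial-free: band power has no step changes", {
  cfg <- sim_config(n_channels = 2, active_channels = 1, hg_effect_z = 10,
                    seed = 8, calib_duration_s = 40)
  rec <- generate_calibration(cfg)
  stats <- compute_calibration_stats(rec)
  ft <- feature_stream(rec, stats)
  for (ch in 1:2) {
    v <- ft$values[, ch]
    # step changes = jumps between successive 1 s block means; an actual
    # event-related burst at this effect size would jump by tens of SDs
    nb <- length(v) %/% 10
    bm <- colMeans(matrix(v[1:(nb * 10)], 10))
    expect_lt(max(abs(diff(bm))), 4 * stats::sd(v))
  }
})

test_that("training block carries the configured cue/ISI schedule", {
  cfg <- sim_config(n_channels = 2, active_channels = 1, n_trials = 260,
                    isi_bounds_s = c(0.5, 0.9), hg_effect_z = 0,
                    hg_duration_s = 0.3, seed = 3)
  blk <- generate_training_block(cfg)
  cues <- event_times(blk, "cue")
  expect_length(cues, 260)
  isi <- diff(cues) - cfg$cue_duration_s
  expect_true(all(isi >= 0.5 - 1e-9 & isi <= 0.9 + 1e-9))
  # uniform mean within 3 SE of the midpoint
  se <- (0.9 - 0.5) / sqrt(12) / sqrt(length(isi))
  expect_lt(abs(mean(isi) - 0.7), 3 * se)
  onsets <- event_times(blk, "movement_onset")
  expect_length(onsets, 260)
  jit <- onsets - cues - cfg$hg_onset_s
  expect_true(all(abs(jit) <= 2 * cfg$reaction_jitter_sd_s + 1e-9))
})

test_that("null effect size leaves active channels at baseline", {
  cfg <- sim_config(n_channels = 4, active_channels = 2, n_trials = 30,
                    isi_bounds_s = c(2.2, 3.0), hg_effect_z = 0,
                    calib_duration_s = 30, seed = 21)
  stats <- compute_calibration_stats(generate_calibration(cfg))
  blk <- generate_training_block(cfg)
  ft <- feature_stream(blk, stats)
  g <- assign_stream_labels(ft, event_times(blk, "cue")) == "grasp"
  # trial-averaged per-bin z on the active channel (feature / 15 band bins)
  n_bins <- length(ecogclick:::hg_band_bins(spectral_config(), cfg$fs))
  expect_lt(abs(mean(ft$values[g, 2]) / n_bins), 3 / sqrt(cfg$n_trials))
})

test_that("event-locked modulation is spatially specific to active channels", {
  fx <- fx_small()
  g <- fx$labels == "grasp"
  act <- mean(fx$feats$values[g, 3]) - mean(fx$feats$values[!g, 3])
  inact <- mean(fx$feats$values[g, 7]) - mean(fx$feats$values[!g, 7])
  expect_gt(act, 10 * abs(inact))
  expect_lt(abs(inact), 3 * stats::sd(fx$feats$values[!g, 7]) / sqrt(fx$cfg$n_trials))
})

test_that("background spectrum has the configured 1/f slope over 10-400 Hz", {
  cfg <- sim_config(n_channels = 1, active_channels = 1,
                    noise_exponent = 1.5, seed = 13, calib_duration_s = 40)
  rec <- generate_calibration(cfg)
  x <- rec$data[1, ]
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (0:(n - 1)) * cfg$fs / n
  sel <- f >= 10 & f <= 400
  # average log power in log-spaced frequency bands before fitting
  bands <- cut(log(f[sel]), 24)
  lp <- tapply(log(p[sel]), bands, mean)
  lf <- tapply(log(f[sel]), bands, mean)
  slope <- stats::coef(stats::lm(lp ~ lf))[2]
  expect_lt(abs(slope - (-1.5)), 0.3)
})

test_that("closed-loop stream echoes requested grasp times and validates input", {
  cfg <- sim_config(n_channels = 2, active_channels = 1, seed = 4)
  s <- generate_closed_loop_stream(cfg, c(5, 10))
  expect_equal(event_times(s, "movement_onset"), c(5, 10))
  s0 <- generate_closed_loop_stream(cfg, numeric(0))
  expect_length(event_times(s0, "movement_onset"), 0)
  expect_error(generate_closed_loop_stream(cfg, c(5, 5.5)),
               "separated by more than")
  expect_error(generate_closed_loop_stream(cfg, c(10, 5)), "increasing")
})

test_that("burst energy is localized at grasps on every active channel", {
  skip_if_not_installed("signal")
  cfg <- sim_config(n_channels = 4, active_channels = c(2, 3), hg_effect_z = 3,
                    seed = 17)
  grasps <- c(5, 10, 15)
  rec <- generate_closed_loop_stream(cfg, grasps)
  bf <- signal::butter(4, c(110, 170) / (cfg$fs / 2), type = "pass")
  for (ch in c(2, 3)) {
    y <- signal::filtfilt(bf, rec$data[ch, ])
    in_burst <- function(t0) {
      idx <- round((t0 + 0.2) * cfg$fs):round((t0 + 0.8) * cfg$fs)
      mean(y[idx]^2)
    }
    base_idx <- round(2.5 * cfg$fs):round(4.5 * cfg$fs)
    base <- mean(y[base_idx]^2)
    for (t0 in grasps) expect_gt(in_burst(t0), 2 * base)
  }
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(isi_bounds_s = c(2, 2)), "low < high")
  expect_error(sim_config(hg_duration_s = 0), "positive")
  expect_error(sim_config(n_channels = 4, active_channels = 9), "within")
  expect_error(sim_config(fs = 300), "twice the highest")
})
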