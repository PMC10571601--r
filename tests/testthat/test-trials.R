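test_that("epochs span -1 to 2.5 s in 36 frames and keep cue bookkeeping", {
  fx <- fx_small()
  ep <- epoch_trials(fx$feats, fx$cues)
  expect_equal(dim(ep$hg)[2], 36)   # round(3.5 / 0.1) + 1
  expect_equal(ep$cue_times, fx$cues)
  r <- ecogclick:::epoch_rel_times(ep)
  expect_true(all(r >= -1 - 1e-6 & r <= 2.5 + 0.1))
})

test_that("cues without full context are dropped with a warning", {
  fx <- fx_small()
  expect_warning(ep <- epoch_trials(fx$feats, c(0.5, fx$cues)), "dropped 1")
  expect_equal(length(ep$cue_times), length(fx$cues))
  expect_error(suppressWarnings(epoch_trials(fx$feats, 0.2)), "no usable trials")
})

test_that("alignment-channel selection recovers the active block", {
  fx <- fx_small()
  ep <- epoch_trials(fx$feats, fx$cues)
  expect_setequal(select_alignment_channels(ep, 2), c(3, 4))
  expect_setequal(select_alignment_channels(ep, 8), 1:8)
  expect_error(select_alignment_channels(ep, 9), "k must be")
  expect_identical(select_alignment_channels(ep, 2),
                   select_alignment_channels(ep, 2))
})

test_that("jitter-free trials need no realignment", {
  cfg <- sim_config(n_channels = 4, active_channels = 2, n_trials = 10,
                    isi_bounds_s = c(2.2, 3.0), hg_effect_z = 4,
                    reaction_jitter_sd_s = 0, calib_duration_s = 15, seed = 6)
  stats <- compute_calibration_stats(generate_calibration(cfg))
  blk <- generate_training_block(cfg)
  ft <- feature_stream(blk, stats)
  ep <- epoch_trials(ft, event_times(blk, "cue"))
  re <- realign_trials(ep, 2)
  expect_true(all(abs(re$offsets_s) <= 0.1 + 1e-9))
})

test_that("realignment recovers injected reaction jitter and raises inter-trial correlation", {
  cfg <- sim_config(n_channels = 4, active_channels = c(2, 3), n_trials = 30,
                    isi_bounds_s = c(2.6, 3.4), hg_effect_z = 3,
                    reaction_jitter_sd_s = 0.1, calib_duration_s = 20, seed = 14)
  stats <- compute_calibration_stats(generate_calibration(cfg))
  blk <- generate_training_block(cfg)
  ft <- feature_stream(blk, stats)
  cues <- event_times(blk, "cue")
  onsets <- event_times(blk, "movement_onset")
  jit <- onsets - cues - cfg$hg_onset_s
  ep <- epoch_trials(ft, cues)
  sel <- select_alignment_channels(ep, 2)
  re <- realign_trials(ep, sel, max_lag_s = 0.3)
  rel_off <- re$offsets_s - mean(re$offsets_s)
  rel_jit <- jit - mean(jit)
  expect_gte(mean(abs(rel_off - rel_jit) <= 0.1 + 1e-9), 0.9)
  # mean pairwise inter-trial correlation does not decrease
  pair_cor <- function(hg) {
    tr <- lapply(seq_len(dim(hg)[1]), function(i) as.vector(hg[i, , sel]))
    cm <- stats::cor(do.call(cbind, tr))
    mean(cm[upper.tri(cm)])
  }
  expect_gte(pair_cor(re$hg), pair_cor(ep$hg))
})

test_that("half-open label window gives exactly 8 grasp frames per trial", {
  fx <- fx_small()
  ep <- epoch_trials(fx$feats, fx$cues)
  lab <- assign_labels(ep)
  expect_true(all(rowSums(lab == "grasp") == 8))
  full <- assign_labels(ep, grasp_window_s = c(-1, 2.6))  # half-open cover
  expect_true(all(full == "grasp"))
  expect_error(assign_labels(ep, grasp_window_s = c(1, 1)), "empty")
  # two trials double the grasp-frame count
  ep2 <- epoch_trials(fx$feats, fx$cues[1:2])
  expect_equal(sum(assign_labels(ep2) == "grasp"), 16)
})

test_that("stream labels honor realignment offsets", {
  fx <- fx_small()
  lab0 <- assign_stream_labels(fx$feats, fx$cues)
  lab1 <- assign_stream_labels(fx$feats, fx$cues, offsets_s = 0.2)
  g0 <- which(lab0 == "grasp"); g1 <- which(lab1 == "grasp")
  expect_equal(length(g0), length(g1))
  expect_equal(g1, g0 + 2)   # 0.2 s = 2 frames later
})

test_that("dataset balancing downsamples rest to the grasp count", {
  # synthetic stream: 1000 frames, 100 grasp
  vals <- matrix(rnorm(1000 * 3), 1000, 3)
  ftream <- structure(list(values = vals, t = 0.256 + 0.1 * (0:999),
                           hop_s = 0.1, fs = 1000), class = "feature_stream")
  labels <- rep("rest", 1000)
  labels[seq(50, 950, by = 9)] <- "grasp"
  ds <- build_dataset(ftream, labels, n_folds = 5, balance_seed = 3)
  expect_equal(length(ds$labels), 2 * sum(labels[10:1000] == "grasp"))
  expect_equal(sum(ds$labels == "grasp"), sum(ds$labels == "rest"))
  ds2 <- build_dataset(ftream, labels, n_folds = 5, balance_seed = 3)
  expect_identical(ds$frame_idx, ds2$frame_idx)
  ds3 <- build_dataset(ftream, labels, n_folds = 5, balance_seed = 4)
  expect_false(identical(ds$frame_idx, ds3$frame_idx))
})

test_that("every sample's label matches its final frame and folds are contiguous and balanced", {
  fx <- fx_small()
  ds <- fx$dataset
  # label of final frame
  for (s in seq(1, length(ds$labels), by = 17)) {
    expect_equal(as.character(ds$labels[s]), fx$labels[ds$frame_idx[s]])
    expect_equal(ds$sequences[s, 10, ], fx$feats$values[ds$frame_idx[s], ])
  }
  # contiguity: fold ids non-decreasing in time; disjoint & exhaustive
  expect_true(all(diff(ds$fold_ids[order(ds$frame_idx)]) >= 0))
  expect_equal(sort(unique(ds$fold_ids)), 1:4)
  # class balance within fold
  for (f in 1:4) {
    lab <- ds$labels[ds$fold_ids == f]
    expect_equal(sum(lab == "grasp"), sum(lab == "rest"))
  }
  expect_error(build_dataset(fx$feats, rep("rest", nrow(fx$feats$values))),
               "no grasp")
})
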