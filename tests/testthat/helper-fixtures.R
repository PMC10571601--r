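# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- builder()
  }
  .fixture_cache[[name]]
}

# Compact high-SNR recording set: 8 channels, 2-channel active block,
# 24 grasp trials. Used across the trial/classifier/saliency tests.
fx_small <- function() {
  fixture("small", function() {
    cfg <- sim_config(n_channels = 8, active_channels = c(3, 4),
                      n_trials = 24, isi_bounds_s = c(2.2, 3.0),
                      hg_effect_z = 3, calib_duration_s = 20, seed = 11)
    stats <- compute_calibration_stats(generate_calibration(cfg))
    block <- generate_training_block(cfg)
    feats <- feature_stream(block, stats)
    cues <- event_times(block, "cue")
    labels <- assign_stream_labels(feats, cues)
    dataset <- build_dataset(feats, labels, n_folds = 4)
    list(cfg = cfg, stats = stats, block = block, feats = feats,
         cues = cues, labels = labels, dataset = dataset)
  })
}

# A quickly trained model on the small fixture (30 epochs suffices there).
fx_model <- function() {
  fixture("model", function() {
    fx <- fx_small()
    train_model(build_model(model_config(n_channels = 8, seed = 2)),
                fx$dataset, epochs = 30)
  })
}

# Scaled-down reference simulation for the cross-validation checks:
# 16 channels with a 3-channel active block (the active fraction of the
# 12-of-128 hand-knob grid), 100 trials, full realignment-based labeling.
fx_reference <- function() {
  fixture("reference", function() {
    cfg <- sim_config(n_channels = 16, active_channels = c(5, 6, 7),
                      n_trials = 100, isi_bounds_s = c(2.2, 3.0),
                      hg_effect_z = 3, calib_duration_s = 30, seed = 42)
    stats <- compute_calibration_stats(generate_calibration(cfg))
    block <- generate_training_block(cfg)
    feats <- feature_stream(block, stats)
    cues <- event_times(block, "cue")
    ep <- epoch_trials(feats, cues)
    ch <- select_alignment_channels(ep, 3)
    re <- realign_trials(ep, ch)
    labels <- assign_stream_labels(feats, cues, re$offsets_s)
    dataset <- build_dataset(feats, labels, n_folds = 10)
    list(cfg = cfg, stats = stats, feats = feats, cues = cues,
         dataset = dataset)
  })
}

# Brute-force O(N^2) DFT log-power oracle for one window.
dft_log_power_oracle <- function(segment, cfg, fs) {
  n <- ncol(segment)
  half <- 0:(n %/% 2)
  out <- matrix(0, nrow(segment), length(half))
  for (ch in seq_len(nrow(segment))) {
    x <- segment[ch, ]
    for (k in half) {
      re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
      im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
      out[ch, k + 1] <- log(max(re^2 + im^2, cfg$power_floor))
    }
  }
  out
}

# Maximum-cardinality onset/click matching by exhaustive subset search
# (small cases only): the oracle for the greedy TP assignment.
max_tp_matching_oracle <- function(onsets, clicks, window) {
  n_best <- 0
  k <- min(length(onsets), length(clicks))
  feasible <- function(os, cs) {
    all(cs >= os & cs <= os + window)
  }
  if (k == 0) return(0)
  for (m in k:1) {
    oc <- utils::combn(length(onsets), m, simplify = FALSE)
    cc <- utils::combn(length(clicks), m, simplify = FALSE)
    for (o in oc) for (cl in cc) {
      # onsets and clicks both time-sorted: within a feasible matching the
      # order-preserving pairing is also feasible, so pairing sorted
      # subsets in order suffices
      if (feasible(onsets[o], clicks[cl])) return(m)
    }
  }
  0
}

# Exhaustive permutation oracle for the two-sided rank-sum p-value:
# enumerates every group assignment by bitmask (independent of the
# combn-based path in the package).
ranksum_permutation_oracle <- function(a, b) {
  r <- rank(c(a, b))
  n <- length(r); n1 <- length(a)
  w_obs <- sum(r[seq_len(n1)])
  w_all <- numeric(0)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask)[1:n])
    if (sum(bits) == n1) w_all <- c(w_all, sum(r[bits == 1]))
  }
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}
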