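# ecogclick

Click decoding for electrocorticographic (ECoG) brain-computer interfaces.

People with severe motor impairment can control a computer through a
single decoded command: a binary rest-vs-grasp classifier watches cortical
activity and fires a discrete "brain click" when the user attempts a hand
movement. Paired with a switch-scanning interface — rows, then keys within
the selected row, highlighted cyclically, selected by timing a click —
that one command is enough to spell sentences. `ecogclick` implements this
entire decoding stack, together with a seeded synthetic ECoG generator so
the closed loop can be built, trained and evaluated with no participant
data. It is aimed at BCI researchers and engineers who want a tested,
fully reproducible reference pipeline.

## The method

* **Features.** Per channel, the log periodogram of 256 ms windows hopped
  every 100 ms is z-scored per frequency bin against a resting
  calibration baseline (per-channel, per-bin mean and SD of log power over
  a 60 s rest recording); the z-scores of bins with center frequency in
  the high-gamma band, 110–170 Hz, are summed:
  `HG_c = sum over f in [110, 170] of (log P_c(f) - mu_c(f)) / sigma_c(f)`.
* **Classifier.** Ten consecutive feature vectors (1 s of history) feed an
  LSTM with 25 hidden units; its full output sequence is flattened into a
  10-unit eLU layer and a 2-unit softmax — 17,932 trainable parameters at
  128 channels. Training: categorical cross-entropy, Adam, 45-sample
  batches, 75 epochs, 30% dropout, He-normal initialization, written as
  plain matrix code with hand-derived backpropagation through time.
* **Click logic.** One classification per 100 ms enters a voting window
  (W votes); a click fires when at least V are grasp and the 1 s lockout
  has expired, which bounds the minimum detection latency at exactly
  V × 100 ms and debounces sporadic misclassifications.
* **Evaluation.** A click is a true positive if it lands on screen within
  1.5 s of an unconsumed movement onset; sensitivity = 100·TP/attempts;
  TPF/FPF are clicks per minute; spelling is scored as correct characters
  and words per minute under exact positional matching. Group comparisons
  use the exact Wilcoxon rank-sum test with Holm–Bonferroni correction.
* **Saliency.** Integrated gradients of the grasp probability, L2-pooled
  over time and averaged over repeated cross-validated models, score each
  channel's contribution in [0, 1]; channel-subset ablations retrain the
  model on e.g. the 12-channel hand-knob block.

See the methods vignette (`vignettes/click-decoding.Rmd`) for assumptions,
parameter tables and design decisions.

## Worked example

```r
library(ecogclick)

cfg <- sim_config(n_channels = 16, active_channels = c(5, 6, 7),
                  n_trials = 100, isi_bounds_s = c(2.2, 3.0),
                  hg_effect_z = 3, calib_duration_s = 30, seed = 42)

stats <- compute_calibration_stats(generate_calibration(cfg))
block <- generate_training_block(cfg)
feats <- feature_stream(block, stats)
cues  <- event_times(block, "cue")

ep <- epoch_trials(feats, cues)                      # -1 .. +2.5 s epochs
re <- realign_trials(ep, select_alignment_channels(ep, 3))
lab <- assign_stream_labels(feats, cues, re$offsets_s)
ds  <- build_dataset(feats, lab, n_folds = 10)
ds
#> <labeled_dataset> 1600 samples (800 grasp / 800 rest) x 10 frames x 16 channels, 10 folds

model <- train_model(build_model(model_config(n_channels = 16, seed = 1)), ds)
stream <- generate_closed_loop_stream(cfg, seq(5, 150, by = 5))
log <- run_closed_loop(stream, model, stats, voting_config(7, 4))
session_metrics(log)
#> <session_metrics> sensitivity 100.0%, TPF 11.69/min, FPF 3.117/min (TP 30 / FP 8 / FN 0 in 154.0 s)
#>   median latency: detection 0.46 s, on-screen 0.66 s
```

All 30 simulated grasp attempts produced a click (sensitivity 100%) with
a median of 0.46 s from movement onset to algorithmic detection (0.66 s
to the on-screen click, which adds the 0.2 s display constant); the
remaining 8 clicks fired outside the 1.5 s true-positive windows, mostly
on the decaying tail of a burst, giving the printed false-positive
frequency. This is the operating regime the decoder class targets —
near-ceiling sensitivity with sub-second clicks — on a compact synthetic
reference problem.

Spelling with the simulated user and an ideal detector:

```r
res <- simulate_session(default_speller_layout(), "THE CAT",
                        user = user_model(0, 0), detector = "ideal", seed = 5)
res$transcripts
#> [1] "THE CAT"
round(res$scores[[1]]$ccpm, 1)
#> [1] 14.7
```

A command-line front end over the same functions is installed at
`system.file("cli/ecogclick", package = "ecogclick")` with subcommands
`simulate`, `calibrate`, `dataset`, `train`, `crossval`, `stream`,
`evaluate`, `saliency` and `spell`.

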