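---
title: "Click decoding for ECoG brain-computer interfaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Click decoding for ECoG brain-computer interfaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecogclick)
```

## The problem

A "click" decoder is the simplest useful brain-computer interface: a binary
classifier that watches cortical activity and fires a discrete selection
event when the user attempts a movement. Combined with a switch-scanning
interface — where rows and then columns of a key grid are highlighted in
turn and the user selects by timing a single click — it gives people with
severe motor impairment full keyboard access from one decoded command.

`ecogclick` implements that entire stack for electrocorticographic (ECoG)
recordings: a seeded synthetic ECoG generator with ground-truth event
schedules, high-gamma feature extraction against a resting baseline, a
small LSTM sequence classifier, a packetized real-time engine with a voting
window and lockout, communication-board and sentence-speller simulations
with a modelled user, the event-detection and spelling metrics, and
integrated-gradients channel saliency. Because every stage runs against the
simulator, the full closed loop is testable on any machine with no
participant data.

## The decoding model

**Features.** Each channel's voltage stream is cut into 256 ms windows
advanced in 100 ms hops (the first window starts at t = 0; a window at hop
k covers `[k*0.1, k*0.1 + 0.256)` seconds and is timestamped at its end).
Each window's raw periodogram is log-transformed and z-scored per frequency
bin against calibration statistics — the per-channel, per-bin mean and SD
of log power over a resting recording (60 s by default). The z-scores of
the bins whose center frequency falls in 110–170 Hz (inclusive; 15 bins at
the 3.906 Hz spacing of a 256-point FFT at 1 kHz) are summed, giving one
unitless high-gamma (HG) power value per channel per 100 ms. The band's
lower edge sits above 100 Hz because post-movement low-frequency activity
can reach that high; the generator can synthesize that artifact
(`low_freq_artifact`) to exercise the band exclusion.

**Classifier.** Ten consecutive feature vectors — one second of history —
form one classifier input. An LSTM with 25 hidden units consumes the
10 x 128 sequence and returns its full output sequence, which is flattened
(250 values) and passed through a 10-unit eLU layer and a 2-unit softmax
giving rest/grasp probabilities. With 128 input channels this architecture
has exactly 17,932 trainable parameters
(`4*(128*25 + 25^2 + 25) + (250*10 + 10) + (10*2 + 2)`); the
full-sequence-flatten reading is the only standard many-to-one variant
consistent with that count (pooling only the last LSTM step would give
15,682). Training uses categorical cross-entropy, Adam (learning rate
0.001, standard moment parameters — unstated upstream, so conventional
defaults), 45-sample batches, 75 epochs, 30% inverted dropout on the
flattened LSTM output and the eLU layer output, and He-normal
initialization for all weight matrices with zero biases except the LSTM
forget gate at one. Batch order is reshuffled each epoch from the run seed,
so training is bit-reproducible given the seed. The network is implemented
directly in matrix code (forward pass and backpropagation through time);
gradient correctness is pinned by finite-difference tests.

**Real-time path.** Packets of 100 ms update a running 256 ms sample
buffer; each newly complete window yields a feature vector into a 10-frame
history; once the history is full, one classification is emitted per tick
(the first at t = 1.156 s — no output is produced on partially filled
buffers). Classifications enter a voting window of W recent votes (10 for
the communication board, 7 for the speller); a click fires when at least V
are grasp *and* the 1 s lockout from the previous click has expired. On a
click the vote buffer is cleared: with the lockout alone, stale grasp votes
would re-fire immediately at expiry, which is not a plausible reading of a
debounce. Under sustained grasp classification the minimum detection
latency is therefore exactly V ticks, and consecutive clicks can never be
closer than the lockout. The batch and packetized feature paths are
identical by construction and tested as an equivalence pair.

## Trial structure, labels, and folds

Training blocks consist of brief (100 ms) Go cues followed by
interstimulus intervals drawn uniformly between configurable bounds
(default 8–12 s, which makes 260 trials span roughly 44 minutes). Features
are epoched from −1 to +2.5 s around each cue (36 frames). Because
reaction times vary, each trial is re-aligned before labeling: the k most
activated channels (largest trial-averaged post-cue peak) define a
template, each trial's best integer-frame lag within ±max_lag is found
exhaustively (lag 0 always included; ties go to the smaller |lag|, then
the earlier lag), trials are shifted, and the template is rebuilt until
convergence (≤ 10 iterations). At convergence no trial's correlation with
the template is below its unshifted value. The exact procedure of the
upstream alignment method is not published; this iterative template
matching is the simplest procedure with the reported outcome (increased
inter-trial correlation) and is validated by recovering injected jitter.

Frames whose re-aligned time lies in the half-open window `[0.3, 1.1)` s
post-cue are labeled grasp, all others rest; the half-open convention
yields exactly 8 grasp frames per trial at the 0.1 s hop regardless of
grid alignment. Each labeled frame with a complete 10-frame history
becomes one sample (labeled by its final frame; histories may span trial
boundaries, as they do in deployment). Folds for cross-validation are
contiguous blocks of time — never interleaved, to avoid leaking
autocorrelated neighbors between training and validation — and the
over-represented rest class is downsampled *within each fold*, so folds
are simultaneously contiguous, disjoint, exhaustive, and class-balanced.

## The synthetic generator

The generator produces what the decoder assumes and nothing more:

* **Background**: channel-independent 1/f^α Gaussian noise (α = 1.5 by
  default), synthesized by frequency-domain shaping with the gain floored
  below 0.5 Hz (a stand-in for the recording chain's high-pass). The
  amplitude scale is set analytically from the gain vector rather than
  normalized per realization — per-realization normalization would couple
  the large stochastic low-frequency power into the high-gamma band and
  shift band power between the calibration and task recordings, which is
  exactly what calibration assumes does not happen.
* **Grasp responses**: band-limited (110–170 Hz) noise bursts with a
  raised-cosine-tapered plateau envelope (0.15 s ramps), on the active
  channels only, from movement onset (cue + 0.2 s + truncated-Gaussian
  reaction jitter) for 1.0 s. The effect size `hg_effect_z` is calibrated
  in the units the feature pipeline measures: the added power satisfies
  `log(1 + a^2/sigma_band^2) = hg_effect_z * sd_logP`, where `sd_logP =
  sqrt(trigamma(1)) ≈ 1.28` is the SD of a log-periodogram bin, so a value
  of 3 shifts each in-band bin by three baseline SDs of log power at the
  plateau.
* **Schedules**: every recording carries its cue and ground-truth movement
  onset/offset events, so labeling and latency metrics need no external
  movement measurement.

What it does **not** emulate: inter-channel covariance, line noise,
electrode impedance drift, non-stationary baselines, or day-scale signal
changes. Passing tests on this generator demonstrate that the pipeline is
correct and self-consistent under its own assumptions — not that the
decoder would reach the same numbers on real cortical data.

## Metrics

A click is a true positive if it appears on screen within 1.5 s after a
not-yet-consumed movement onset (greedy earliest-onset-first, one click
per onset — multiplicity handling is unspecified upstream, and the greedy
rule both conserves counts, `TP + FN = onsets`, `TP + FP = clicks`, and
attains the maximum matching on interval constraints). Sensitivity is
`100 * TP / attempted grasps`; TPF and FPF are TP and FP counts per
minute; latencies are onset-to-detection and onset-to-onscreen (detection
plus a configured 0.2 s display constant; the real display overhead is
environment-specific). Spelling is scored as correct characters/words per
minute under exact positional matching against the prompt (single-space
tokenization; a word counts only if all its character positions match —
this reproduces the canonical 30-character/5-word/1-typo → 29/4 example,
which also implies comparison is per intended position, not
alignment-shifted). Group comparisons use the two-sided Wilcoxon rank-sum
test — exact enumeration of the rank-sum distribution for combined n ≤ 12
(midranks for ties), normal approximation with tie correction otherwise —
with Holm–Bonferroni correction at α = 0.05.

## Saliency

Channel contributions are measured by integrated gradients of the
grasp-class softmax probability with respect to the input history,
midpoint-rule approximated along the straight path from an all-zero
baseline (zero features are calibration-baseline activity, a natural
reference the upstream description leaves unstated; 64 steps by default).
Per-sample attributions are collapsed to channels by the L2 norm over the
10 time frames, averaged over all grasp samples of all validation folds
across repeated cross-validation runs, and min-max normalized to [0, 1]
(a constant map normalizes to zeros with a warning). The completeness
axiom — attributions summing to the output difference — is enforced by
test at 1% tolerance with 256 steps. Channel-subset ablations rebuild the
model on the subset (or `-drop` notation) with the same seeds and compare
per-fold accuracies to a reference run by rank-sum with a 3-way Holm
family, mirroring the all-channels / drop-one / hand-knob-only design.

## Numerical choices and degenerate inputs

* Rectangular FFT taper by default (Hann available): the minimal reading
  of "FFT filter"; the taper, scaling and sidedness of the upstream
  spectral estimate are unstated, and z-normalization absorbs constant
  scale factors (which also makes the log base irrelevant).
* Power is floored at 1e−12 before the log so degenerate all-zero windows
  cannot poison calibration; a zero-variance calibration bin raises an
  error naming the channel and bin.
* Softmax is computed with max subtraction; prediction ties break toward
  rest (the conservative class for a click detector).
* Scan-cycle highlights are computed from elapsed time with a 1e−9 guard
  so clicks landing exactly on a step boundary select that step; clicks
  during pre-selection steps are ignored (nothing is highlighted).
* A-DEL removes the entire last word regardless of how it was entered;
  wrong-row recovery re-cues within the selected row in board mode only,
  while speller mode requires deletion.

## Problem sizes

The test and acceptance runs use a scaled-down reference simulation chosen
once: 16 channels with a 3-channel active block (the same active fraction
as a 12-of-128 hand-knob grid), 100 trials at 2.2–3.0 s interstimulus
intervals, effect size 3, 10-fold cross-validation — about 1,600 balanced
samples. That size shows the same qualitative regime as the full
configuration (high sensitivity, low false-positive frequency,
sub-second latencies) while a complete run stays in minutes. Parameter
counts and voting mechanics are always checked at the full 128-channel
deployment configuration, which costs nothing.

## Known limitations

The user and detector models in the speller simulation are event-level
(reaction jitter, wrong-target probability, per-attempt miss probability);
spontaneous false-positive clicks are exercised in the real-time voting
engine rather than injected into scan sessions. The autocomplete is a
frequency-weighted prefix dictionary behind a pluggable interface, not a
language model, so simulated spelling rates describe interface mechanics,
not linguistic prediction quality. The LSTM runs on CPU in plain R; at
~18k parameters this trains a 10-fold CV in about a minute, but the code
is not meant for models orders of magnitude larger.
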