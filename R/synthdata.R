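#' Simulation configuration for synthetic ECoG
#'
#' Bundles every knob of the synthetic ECoG generator: grid geometry,
#' sampling, the channel subset carrying grasp-related modulation, the
#' event-related high-gamma (HG) response, trial timing, and the background
#' noise model. Defaults reflect a 128-channel, 1 kHz recording with a
#' 12-channel "hand-knob" active block and Go-cued grasp trials whose
#' interstimulus intervals are drawn uniformly between bounds.
#'
#' @param n_channels Number of recording channels.
#' @param fs Sampling rate in Hz.
#' @param active_channels 1-based indices of channels carrying event-related
#'   HG modulation. Default is a 12-channel block over cortical hand knob.
#' @param hg_effect_z Peak amplitude of the event-related HG burst, in units
#'   of the channel's baseline HG-band RMS (so 0 disables the response).
#' @param hg_onset_s Neural response onset relative to the cue, seconds.
#' @param hg_duration_s Duration of the HG burst, seconds.
#' @param reaction_jitter_sd_s SD of the per-trial Gaussian onset jitter
#'   (truncated at +/- 2 SD), seconds.
#' @param isi_bounds_s Two-element numeric, uniform interstimulus-interval
#'   bounds in seconds (low < high).
#' @param cue_duration_s Go-stimulus duration, seconds.
#' @param n_trials Trials per training block.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param low_freq_artifact Logical; add post-movement low-frequency power
#'   extending toward 100 Hz.
#' @param low_freq_amp Amplitude of that artifact in baseline-RMS units.
#' @param calib_duration_s Length of the resting calibration recording.
#' @param noise_sd Overall per-channel background SD in microvolts.
#' @param seed Integer seed; identical configs produce identical recordings.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 128,
                       fs = 1000,
                       active_channels = c(92, 93, 94, 100, 101, 102,
                                           108, 109, 110, 116, 117, 118),
                       hg_effect_z = 3,
                       hg_onset_s = 0.2,
                       hg_duration_s = 1.0,
                       reaction_jitter_sd_s = 0.05,
                       isi_bounds_s = c(8, 12),
                       cue_duration_s = 0.1,
                       n_trials = 260,
                       noise_exponent = 1.5,
                       low_freq_artifact = FALSE,
                       low_freq_amp = 2,
                       calib_duration_s = 60,
                       noise_sd = 10,
                       seed = 1) {
  cfg <- structure(list(
    n_channels = as.integer(n_channels), fs = fs,
    active_channels = as.integer(active_channels),
    hg_effect_z = hg_effect_z, hg_onset_s = hg_onset_s,
    hg_duration_s = hg_duration_s,
    reaction_jitter_sd_s = reaction_jitter_sd_s,
    isi_bounds_s = as.numeric(isi_bounds_s),
    cue_duration_s = cue_duration_s, n_trials = as.integer(n_trials),
    noise_exponent = noise_exponent,
    low_freq_artifact = isTRUE(low_freq_artifact),
    low_freq_amp = low_freq_amp,
    hg_band_hz = c(110, 170),
    low_freq_band_hz = c(2, 100),
    low_freq_duration_s = 0.5,
    calib_duration_s = calib_duration_s,
    noise_sd = noise_sd, seed = seed
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_channels < 1) stop_input("n_channels must be >= 1")
  if (cfg$fs <= 0) stop_input("fs must be positive")
  if (length(cfg$isi_bounds_s) != 2 || cfg$isi_bounds_s[1] >= cfg$isi_bounds_s[2]) {
    stop_input("isi_bounds_s must satisfy low < high")
  }
  if (cfg$hg_duration_s <= 0) stop_input("hg_duration_s must be positive")
  if (length(cfg$active_channels) &&
      (min(cfg$active_channels) < 1 || max(cfg$active_channels) > cfg$n_channels)) {
    stop_input("active_channels must lie within [1, n_channels]")
  }
  # everything synthesized must be below Nyquist
  f_max <- max(cfg$hg_band_hz[2],
               if (cfg$low_freq_artifact) cfg$low_freq_band_hz[2] else 0)
  if (cfg$fs <= 2 * f_max) {
    stop_input("fs must exceed twice the highest synthesized frequency (%g Hz)", f_max)
  }
  invisible(cfg)
}

#' Construct a raw multichannel recording
#'
#' Container for a channels x samples voltage matrix with its sampling rate,
#' channel labels and an event schedule (cue onsets and ground-truth
#' movement onsets/offsets).
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate, Hz.
#' @param channel_ids Character vector of channel labels (defaults to
#'   `ch001`, `ch002`, ...).
#' @param events Data frame with columns `type` (character) and `t` (seconds).
#'
#' @return An object of class `ecog_recording`.
#' @export
ecog_recording <- function(data, fs, channel_ids = NULL, events = NULL) {
  if (!is.matrix(data)) stop_input("data must be a channels x samples matrix")
  if (anyNA(data)) stop_input("recording contains NA/NaN voltages")
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%03d", seq_len(nrow(data)))
  if (length(channel_ids) != nrow(data)) {
    stop_input("channel_ids length (%d) does not match channel count (%d)",
               length(channel_ids), nrow(data))
  }
  if (is.null(events)) events <- data.frame(type = character(), t = numeric())
  dur <- ncol(data) / fs
  if (nrow(events) && (any(events$t < 0) || any(events$t > dur))) {
    stop_input("event times must lie within the recording duration")
  }
  structure(list(data = data, fs = fs, channel_ids = channel_ids,
                 events = events, duration_s = dur),
            class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %d samples (%.1f s at %g Hz), %d events\n",
              nrow(x$data), ncol(x$data), x$duration_s, x$fs, nrow(x$events)))
  invisible(x)
}

# 1/f^alpha background noise via spectral shaping: white Gaussian noise is
# filtered in the frequency domain with gain f^(-alpha/2), floored below
# 0.5 Hz (recording-chain high-pass stand-in) and zeroed at DC. The scale
# is set analytically (E[var] = sum(gain^2)/n) rather than per realization,
# so band power is statistically identical across independent recordings --
# normalizing each realization would couple the huge low-frequency power
# fluctuations into the high-gamma calibration.
pink_noise_gain <- function(n_samples, fs, alpha) {
  f <- pmax(fft_bin_freqs_full(n_samples, fs), 0.5)
  g <- f^(-alpha / 2)
  g[1] <- 0
  g
}

pink_noise_matrix <- function(n_channels, n_samples, fs, alpha, sd) {
  # synthesize at a 2-3-5-smooth length and truncate: arbitrary lengths
  # can hit O(n^2) mixed-radix FFT cases, and truncating stationary noise
  # changes nothing statistically
  np <- stats::nextn(n_samples, c(2, 3, 5))
  gain <- pink_noise_gain(np, fs, alpha)
  scale <- sd / sqrt(sum(gain^2) / np)
  out <- matrix(0, n_channels, n_samples)
  for (ch in seq_len(n_channels)) {
    w <- stats::rnorm(np)
    x <- Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / np
    out[ch, ] <- x[seq_len(n_samples)] * scale
  }
  out
}

# Symmetric frequency axis for a length-n FFT: min(k, n-k) * fs / n.
fft_bin_freqs_full <- function(n, fs) {
  k <- 0:(n - 1)
  pmin(k, n - k) * fs / n
}

# Fraction of total noise RMS falling inside [band[1], band[2]] for the
# 1/f^alpha spectrum, so burst amplitudes can be expressed in units of the
# baseline in-band RMS without an empirical pass over the signal.
band_rms_fraction <- function(n, fs, alpha, band) {
  f <- fft_bin_freqs_full(n, fs)
  p <- pink_noise_gain(n, fs, alpha)^2
  sqrt(sum(p[f >= band[1] & f <= band[2]]) / sum(p))
}

# Band-limited unit-RMS noise of `n` samples confined to `band` (Hz),
# generated by FFT masking of white noise.
band_limited_noise <- function(n, fs, band) {
  f <- fft_bin_freqs_full(n, fs)
  mask <- as.numeric(f >= band[1] & f <= band[2])
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * mask, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Raised-cosine-tapered (Tukey) amplitude envelope: cosine ramps of
# `ramp` samples around a flat plateau, so the burst sustains its
# amplitude across the response window instead of peaking only at its
# center.
raised_cosine_env <- function(n, ramp = NULL) {
  if (is.null(ramp)) ramp <- max(1L, min(n %/% 2, round(0.15 * n)))
  env <- rep(1, n)
  up <- seq_len(ramp)
  env[up] <- 0.5 * (1 - cos(pi * (up - 0.5) / ramp))
  env[n + 1 - up] <- env[up]
  env
}

# Add an amplitude-modulated band-limited burst to `data` (in place value
# semantics) on the given channels, starting at `onset_s` for `dur_s`.
add_burst <- function(data, fs, channels, onset_s, dur_s, band, amplitude) {
  n <- ncol(data)
  i0 <- floor(onset_s * fs) + 1
  len <- round(dur_s * fs)
  if (i0 < 1) { len <- len + (i0 - 1); i0 <- 1 }
  len <- min(len, n - i0 + 1)
  if (len <= 0) return(data)
  env <- raised_cosine_env(len) * amplitude
  for (ch in channels) {
    data[ch, i0:(i0 + len - 1)] <- data[ch, i0:(i0 + len - 1)] +
      band_limited_noise(len, fs, band) * env
  }
  data
}

# Truncated-normal reaction-time jitter (+/- 2 SD) via inverse-CDF sampling.
reaction_jitter <- function(n, sd) {
  if (sd <= 0) return(rep(0, n))
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

#' Generate a resting calibration recording
#'
#' Produces a rest segment (default 60 s) of 1/f^alpha background noise with
#' no event-related modulation, used to estimate per-channel, per-frequency
#' baseline statistics for feature normalization.
#'
#' @param config A [sim_config()].
#' @param duration_s Optional override of `config$calib_duration_s`.
#' @return An [ecog_recording()] with an empty event schedule.
#' @export
generate_calibration <- function(config, duration_s = NULL) {
  validate_sim_config(config)
  dur <- duration_s %||% config$calib_duration_s
  if (dur <= 0) stop_input("calibration duration must be positive")
  n <- round(dur * config$fs)
  with_seed(derive_seed(config$seed, 101), {
    data <- pink_noise_matrix(config$n_channels, n, config$fs,
                              config$noise_exponent, config$noise_sd)
    ecog_recording(data, config$fs)
  })
}

# Shared core: background noise plus HG bursts at given movement onsets.
synth_with_bursts <- function(config, n_samples, onsets, events, seed_stream) {
  with_seed(derive_seed(config$seed, seed_stream), {
    data <- pink_noise_matrix(config$n_channels, n_samples, config$fs,
                              config$noise_exponent, config$noise_sd)
    hg_rms <- config$noise_sd *
      band_rms_fraction(n_samples, config$fs, config$noise_exponent,
                        config$hg_band_hz)
    # hg_effect_z is the per-bin log-power shift in units of the baseline
    # log-power SD (sqrt(trigamma(1)) for a periodogram bin): the added
    # burst power a^2 satisfies log(1 + a^2/sigma^2) = z * sd_logP.
    amp <- hg_rms * sqrt(expm1(config$hg_effect_z * sqrt(trigamma(1))))
    if (amp > 0) {
      for (t0 in onsets) {
        data <- add_burst(data, config$fs, config$active_channels, t0,
                          config$hg_duration_s, config$hg_band_hz, amp)
      }
    }
    if (config$low_freq_artifact && config$low_freq_amp > 0) {
      lf_rms <- config$noise_sd *
        band_rms_fraction(n_samples, config$fs, config$noise_exponent,
                          config$low_freq_band_hz)
      for (t0 in onsets) {
        data <- add_burst(data, config$fs, config$active_channels,
                          t0 + config$hg_duration_s,
                          config$low_freq_duration_s,
                          config$low_freq_band_hz,
                          config$low_freq_amp * lf_rms)
      }
    }
    ecog_recording(data, config$fs, events = events)
  })
}

#' Generate a Go-cued grasp training block
#'
#' Simulates `n_trials` trials: a brief Go cue, a jittered ground-truth
#' movement onset (cue + `hg_onset_s` + truncated-Gaussian reaction jitter),
#' and an HG burst on the active channels only. Interstimulus intervals are
#' drawn uniformly from `isi_bounds_s`. Cue and movement events are recorded
#' in the schedule so downstream labeling and latency metrics need no
#' external ground truth.
#'
#' @param config A [sim_config()] with `n_trials >= 1`.
#' @param pad_s Silent padding before the first cue and after the last
#'   response, seconds.
#' @return An [ecog_recording()] with `cue`, `movement_onset` and
#'   `movement_offset` events.
#' @export
generate_training_block <- function(config, pad_s = 3) {
  validate_sim_config(config)
  if (config$n_trials < 1) stop_input("n_trials must be >= 1")
  sched <- with_seed(derive_seed(config$seed, 202), {
    isi <- stats::runif(config$n_trials - 1, config$isi_bounds_s[1],
                        config$isi_bounds_s[2])
    cues <- pad_s + cumsum(c(0, config$cue_duration_s + isi))
    jit <- reaction_jitter(config$n_trials, config$reaction_jitter_sd_s)
    list(cues = cues, onsets = cues + config$hg_onset_s + jit)
  })
  offsets <- sched$onsets + config$hg_duration_s
  n_samples <- round((max(offsets) + pad_s +
                        if (config$low_freq_artifact) config$low_freq_duration_s else 0) *
                       config$fs)
  events <- rbind(
    data.frame(type = "cue", t = sched$cues),
    data.frame(type = "movement_onset", t = sched$onsets),
    data.frame(type = "movement_offset", t = offsets)
  )
  events <- events[order(events$t), , drop = FALSE]
  rownames(events) <- NULL
  synth_with_bursts(config, n_samples, sched$onsets, events, 303)
}

#' Generate a continuous closed-loop test stream
#'
#' Produces a continuous recording with HG bursts at exactly the requested
#' grasp times (no cues), providing ground truth for closed-loop detection
#' metrics.
#'
#' @param config A [sim_config()].
#' @param grasp_times Strictly increasing movement-onset times in seconds,
#'   separated by more than `hg_duration_s`.
#' @param pad_s Padding before time zero's first possible event and after the
#'   last response, seconds.
#' @return An [ecog_recording()] with `movement_onset`/`movement_offset`
#'   events at the requested times.
#' @export
generate_closed_loop_stream <- function(config, grasp_times, pad_s = 3) {
  validate_sim_config(config)
  grasp_times <- as.numeric(grasp_times)
  if (length(grasp_times)) {
    if (any(diff(grasp_times) <= 0)) {
      stop_input("grasp_times must be strictly increasing")
    }
    if (any(diff(grasp_times) <= config$hg_duration_s)) {
      stop_input("grasp_times must be separated by more than hg_duration_s")
    }
    if (min(grasp_times) < 0) stop_input("grasp_times must be non-negative")
  }
  dur <- if (length(grasp_times)) max(grasp_times) + config$hg_duration_s + pad_s
         else pad_s + 10
  events <- if (length(grasp_times)) {
    ev <- rbind(
      data.frame(type = "movement_onset", t = grasp_times),
      data.frame(type = "movement_offset", t = grasp_times + config$hg_duration_s)
    )
    ev <- ev[order(ev$t), , drop = FALSE]
    rownames(ev) <- NULL
    ev
  } else {
    data.frame(type = character(), t = numeric())
  }
  synth_with_bursts(config, round(dur * config$fs), grasp_times, events, 404)
}

#' Event times of a given type
#'
#' @param rec An [ecog_recording()].
#' @param type Event type, e.g. `"cue"` or `"movement_onset"`.
#' @return Numeric vector of times in seconds.
#' @export
event_times <- function(rec, type) {
  rec$events$t[rec$events$type == type]
}
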