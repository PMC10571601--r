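#' Spectral feature configuration
#'
#' Parameters of the sliding-window spectral pipeline: 256 ms windows
#' advanced in 100 ms hops, raw-periodogram log power per FFT bin, and the
#' 110-170 Hz high-gamma band summed into one value per channel. The first
#' window starts at t = 0 and a window at hop k covers
#' `[k*hop, k*hop + window)`; timestamps are window-end times.
#'
#' @param window_s Window length in seconds (default 0.256).
#' @param hop_s Hop between consecutive windows in seconds (default 0.100).
#' @param hg_band_hz High-gamma band edges in Hz, inclusive by bin-center
#'   frequency (default `c(110, 170)`).
#' @param taper Window taper: `"rectangular"` (default) or `"hann"`.
#' @param power_floor Epsilon floor applied to power before the (natural)
#'   log, guarding degenerate all-zero inputs.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(window_s = 0.256, hop_s = 0.100,
                            hg_band_hz = c(110, 170),
                            taper = c("rectangular", "hann"),
                            power_floor = 1e-12) {
  taper <- match.arg(taper)
  if (!(window_s > hop_s && hop_s > 0)) {
    stop_input("require window_s > hop_s > 0")
  }
  if (hg_band_hz[1] >= hg_band_hz[2] || hg_band_hz[1] <= 0) {
    stop_input("hg_band_hz must be an increasing positive pair")
  }
  structure(list(window_s = window_s, hop_s = hop_s,
                 hg_band_hz = as.numeric(hg_band_hz), taper = taper,
                 power_floor = power_floor),
            class = "spectral_config")
}

window_samples <- function(cfg, fs) round(cfg$window_s * fs)
hop_samples <- function(cfg, fs) round(cfg$hop_s * fs)

#' One-sided FFT bin-center frequencies
#'
#' @param cfg A [spectral_config()].
#' @param fs Sampling rate, Hz.
#' @return Frequencies of bins 0..N/2 for the configured window length.
#' @export
bin_freqs <- function(cfg, fs) {
  n <- window_samples(cfg, fs)
  (0:(n %/% 2)) * fs / n
}

hg_band_bins <- function(cfg, fs) {
  f <- bin_freqs(cfg, fs)
  which(f >= cfg$hg_band_hz[1] & f <= cfg$hg_band_hz[2])
}

taper_vector <- function(cfg, n) {
  switch(cfg$taper,
         rectangular = rep(1, n),
         hann = 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))))
}

#' Log spectral power of one window
#'
#' Computes the log (natural) one-sided periodogram of a single analysis
#' window for every channel: `log(|FFT(x * taper)|^2)` over bins 0..N/2,
#' with an epsilon floor on power before the log.
#'
#' @param segment Numeric matrix, channels x samples, with exactly
#'   `round(window_s * fs)` columns.
#' @param cfg A [spectral_config()].
#' @param fs Sampling rate, Hz.
#' @return Matrix channels x bins of log power, with bin-center frequencies
#'   in attribute `"freqs"`.
#' @export
window_log_power <- function(segment, cfg, fs) {
  if (!is.matrix(segment)) segment <- matrix(segment, nrow = 1)
  n <- window_samples(cfg, fs)
  if (ncol(segment) != n) {
    stop_input("segment has %d samples; expected %d", ncol(segment), n)
  }
  w <- taper_vector(cfg, n)
  X <- stats::mvfft(t(segment * rep(w, each = nrow(segment))))
  half <- 1:(n %/% 2 + 1)
  p <- Mod(X[half, , drop = FALSE])^2
  lp <- t(log(pmax(p, cfg$power_floor)))
  attr(lp, "freqs") <- bin_freqs(cfg, fs)
  lp
}

# Number of complete windows in n_samples under the t=0-anchored placement.
n_windows <- function(n_samples, cfg, fs) {
  nw <- window_samples(cfg, fs); nh <- hop_samples(cfg, fs)
  if (n_samples < nw) return(0L)
  (n_samples - nw) %/% nh + 1L
}

#' Resting calibration statistics
#'
#' Slides the analysis window over a rest recording and accumulates, per
#' channel and frequency bin, the mean and standard deviation of log power.
#' These baseline statistics z-normalize all subsequent feature extraction.
#'
#' @param rest An [ecog_recording()] of resting activity (>= 5 s advised).
#' @param cfg A [spectral_config()].
#' @return Object of class `calibration_stats` with `mean`, `sd`
#'   (channels x bins), `bin_freqs_hz`, `n_windows`, `fs`.
#' @export
compute_calibration_stats <- function(rest, cfg = spectral_config()) {
  fs <- rest$fs
  nw <- window_samples(cfg, fs); nh <- hop_samples(cfg, fs)
  k <- n_windows(ncol(rest$data), cfg, fs)
  if (k < 2) stop_input("rest recording too short: %d windows", k)
  nch <- nrow(rest$data)
  nbin <- nw %/% 2 + 1
  s1 <- matrix(0, nch, nbin); s2 <- matrix(0, nch, nbin)
  for (i in seq_len(k)) {
    i0 <- (i - 1) * nh + 1
    lp <- window_log_power(rest$data[, i0:(i0 + nw - 1), drop = FALSE], cfg, fs)
    s1 <- s1 + lp
    s2 <- s2 + lp^2
  }
  mu <- s1 / k
  v <- (s2 - k * mu^2) / (k - 1)
  attr(mu, "freqs") <- NULL; attr(v, "freqs") <- NULL
  # cancellation guard: variances this far below the mean's scale are zero
  v[v < 1e-10 * (mu^2 + 1)] <- 0
  if (any(v == 0)) {
    idx <- which(v == 0, arr.ind = TRUE)[1, ]
    stop_input("zero-variance log power at channel %d, bin %d (%.1f Hz): degenerate rest input",
               idx[1], idx[2], bin_freqs(cfg, fs)[idx[2]])
  }
  structure(list(mean = mu, sd = sqrt(v), bin_freqs_hz = bin_freqs(cfg, fs),
                 n_windows = k, fs = fs, n_channels = nch),
            class = "calibration_stats")
}

#' @export
print.calibration_stats <- function(x, ...) {
  cat(sprintf("<calibration_stats> %d channels x %d bins (%.2f Hz spacing), %d windows\n",
              x$n_channels, length(x$bin_freqs_hz),
              diff(x$bin_freqs_hz[1:2]), x$n_windows))
  invisible(x)
}

#' High-gamma feature from one log-power window
#'
#' Z-scores each bin against the calibration statistics and sums the
#' z-scores over bins whose center frequency lies in the configured
#' high-gamma band (edges inclusive), yielding one unitless value per
#' channel.
#'
#' @param log_power Channels x bins log-power matrix from
#'   [window_log_power()].
#' @param stats A [compute_calibration_stats()] result.
#' @param cfg A [spectral_config()].
#' @return Numeric vector, one normalized HG power per channel.
#' @export
hg_feature <- function(log_power, stats, cfg = spectral_config()) {
  if (!all(dim(log_power) == dim(stats$mean))) {
    stop_input("log_power shape (%d x %d) does not match calibration stats (%d x %d)",
               nrow(log_power), ncol(log_power),
               nrow(stats$mean), ncol(stats$mean))
  }
  z <- (log_power - stats$mean) / stats$sd
  band <- hg_band_bins(cfg, stats$fs)
  rowSums(z[, band, drop = FALSE])
}

#' Sliding-window feature stream
#'
#' Applies [window_log_power()] + [hg_feature()] to every window placement
#' of a recording, producing the time-ordered sequence of per-channel HG
#' features. Identical by construction to the packetized real-time path.
#'
#' @param raw An [ecog_recording()].
#' @param stats Calibration statistics.
#' @param cfg A [spectral_config()].
#' @return Object of class `feature_stream`: `values` (frames x channels),
#'   `t` (window-end timestamps, seconds), `hop_s`, `fs`.
#' @export
feature_stream <- function(raw, stats, cfg = spectral_config()) {
  fs <- raw$fs
  nw <- window_samples(cfg, fs); nh <- hop_samples(cfg, fs)
  k <- n_windows(ncol(raw$data), cfg, fs)
  if (k < 1) stop_input("recording shorter than one analysis window")
  vals <- matrix(0, k, nrow(raw$data))
  for (i in seq_len(k)) {
    i0 <- (i - 1) * nh + 1
    lp <- window_log_power(raw$data[, i0:(i0 + nw - 1), drop = FALSE], cfg, fs)
    vals[i, ] <- hg_feature(lp, stats, cfg)
  }
  structure(list(values = vals,
                 t = ((seq_len(k) - 1) * nh + nw) / fs,
                 hop_s = cfg$hop_s, fs = fs),
            class = "feature_stream")
}

#' @export
print.feature_stream <- function(x, ...) {
  cat(sprintf("<feature_stream> %d frames x %d channels, t = %.3f..%.3f s\n",
              nrow(x$values), ncol(x$values), x$t[1], x$t[length(x$t)]))
  invisible(x)
}
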