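#' Voting-window configuration
#'
#' A click fires when at least `threshold_votes` of the last `window_votes`
#' classifications are grasp and the lockout from the previous click has
#' expired; on a click the vote buffer is cleared and a new lockout starts.
#'
#' @param window_votes Size W of the running classification buffer.
#' @param threshold_votes Grasp votes V required for a click (1 <= V <= W).
#' @param lockout_s Refractory period after each click, seconds.
#' @param tick_s Classification interval, seconds (one packet per tick).
#' @return Object of class `voting_config`.
#' @export
voting_config <- function(window_votes = 7, threshold_votes = 4,
                          lockout_s = 1.0, tick_s = 0.1) {
  if (threshold_votes < 1 || threshold_votes > window_votes) {
    stop_input("require 1 <= threshold_votes <= window_votes")
  }
  if (lockout_s < 0) stop_input("lockout_s must be >= 0")
  structure(list(window_votes = as.integer(window_votes),
                 threshold_votes = as.integer(threshold_votes),
                 lockout_s = lockout_s, tick_s = tick_s),
            class = "voting_config")
}

#' Run the voting/lockout logic over a classification sequence
#'
#' Pure debounce core shared by the streaming engine: given timestamped
#' rest/grasp classifications, returns the click times produced by the
#' voting window, threshold and lockout.
#'
#' @param labels Character vector of `"rest"`/`"grasp"` classifications.
#' @param times Their timestamps, seconds (strictly increasing).
#' @param vcfg A [voting_config()].
#' @return Numeric vector of click times.
#' @export
apply_voting <- function(labels, times, vcfg) {
  stopifnot(length(labels) == length(times))
  votes <- integer(0)
  lockout_until <- -Inf
  clicks <- numeric(0)
  for (i in seq_along(labels)) {
    votes <- c(votes, as.integer(labels[i] == "grasp"))
    if (length(votes) > vcfg$window_votes) {
      votes <- votes[-1]
    }
    if (sum(votes) >= vcfg$threshold_votes && times[i] >= lockout_until) {
      clicks <- c(clicks, times[i])
      lockout_until <- times[i] + vcfg$lockout_s
      votes <- integer(0)
    }
  }
  clicks
}

#' Wrap a trained model as a streaming classifier
#'
#' @param model A trained `click_model`.
#' @return Function `(history_matrix, t) -> "rest"|"grasp"` (ties toward
#'   rest).
#' @export
make_model_classifier <- function(model) {
  force(model)
  function(hist, t) as.character(predict(model, hist, type = "class"))
}

#' Initialize streaming state
#'
#' @param n_channels Channel count of the incoming stream.
#' @param fs Sampling rate, Hz.
#' @param scfg A [spectral_config()].
#' @param vcfg A [voting_config()].
#' @param history_len Feature-history frames required before the first
#'   classification (warm-up).
#' @return Object of class `stream_state`.
#' @export
new_stream_state <- function(n_channels, fs, scfg = spectral_config(),
                             vcfg = voting_config(), history_len = 10) {
  structure(list(
    n_channels = n_channels, fs = fs, scfg = scfg, vcfg = vcfg,
    history_len = history_len,
    buffer = matrix(0, n_channels, 0),   # most recent raw samples
    total_samples = 0L,
    next_window = 0L,                    # 0-based index of next window
    history = matrix(0, 0, n_channels),  # feature history (rows = frames)
    votes = integer(0),
    lockout_until = -Inf,
    class_times = numeric(0), class_labels = character(0),
    clicks = numeric(0)
  ), class = "stream_state")
}

#' Ingest one 100 ms packet
#'
#' Updates the running 256 ms sample buffer, computes any newly completed
#' feature windows, appends to the 10-frame feature history, and once warm
#' emits one classification per tick into the voting window. Clicks fire
#' per the voting rule; classifications and clicks are timestamped at the
#' end of the feature window that produced them.
#'
#' @param state A [new_stream_state()].
#' @param packet Channels x samples matrix with exactly `tick_s * fs`
#'   samples.
#' @param classifier Function `(history, t) -> "rest"|"grasp"`; see
#'   [make_model_classifier()].
#' @param stats Calibration statistics for feature normalization.
#' @return List with the updated `state` and `clicks` (times emitted by
#'   this packet, usually empty or length one).
#' @export
ingest_packet <- function(state, packet, classifier, stats) {
  fs <- state$fs; scfg <- state$scfg; vcfg <- state$vcfg
  tick_n <- round(vcfg$tick_s * fs)
  if (!is.matrix(packet) || nrow(packet) != state$n_channels ||
      ncol(packet) != tick_n) {
    stop_input("packet must be %d channels x %d samples",
               state$n_channels, tick_n)
  }
  nw <- window_samples(scfg, fs); nh <- hop_samples(scfg, fs)
  keep <- nw + nh  # raw history needed to serve any pending window
  state$buffer <- cbind(state$buffer, packet)
  state$total_samples <- state$total_samples + tick_n
  if (ncol(state$buffer) > keep) {
    state$buffer <- state$buffer[, (ncol(state$buffer) - keep + 1):ncol(state$buffer),
                                 drop = FALSE]
  }
  emitted <- numeric(0)
  repeat {
    w_start <- state$next_window * nh + 1L          # absolute sample index
    w_end <- w_start + nw - 1L
    if (w_end > state$total_samples) break
    first_abs <- state$total_samples - ncol(state$buffer) + 1L
    seg <- state$buffer[, (w_start - first_abs + 1L):(w_end - first_abs + 1L),
                        drop = FALSE]
    feat <- hg_feature(window_log_power(seg, scfg, fs), stats, scfg)
    state$history <- rbind(state$history, feat)
    if (nrow(state$history) > state$history_len) {
      state$history <- state$history[-1, , drop = FALSE]
    }
    t_now <- w_end / fs
    state$next_window <- state$next_window + 1L
    if (nrow(state$history) == state$history_len) {
      lab <- classifier(unname(state$history), t_now)
      state$class_times <- c(state$class_times, t_now)
      state$class_labels <- c(state$class_labels, lab)
      state$votes <- c(state$votes, as.integer(lab == "grasp"))
      if (length(state$votes) > vcfg$window_votes) {
        state$votes <- state$votes[-1]
      }
      if (sum(state$votes) >= vcfg$threshold_votes &&
          t_now >= state$lockout_until) {
        emitted <- c(emitted, t_now)
        state$clicks <- c(state$clicks, t_now)
        state$lockout_until <- t_now + vcfg$lockout_s
        state$votes <- integer(0)
      }
    }
  }
  list(state = state, clicks = emitted)
}

#' Click event log
#'
#' @param grasp_onsets Ground-truth movement-onset times, seconds.
#' @param detections Algorithm detection times, seconds.
#' @param onscreen_clicks On-screen click times (detection + display
#'   latency), seconds.
#' @param session_duration_s Total session time T, seconds.
#' @return Object of class `click_event_log` (assignments empty until
#'   [assign_events()]).
#' @export
click_event_log <- function(grasp_onsets, detections, onscreen_clicks,
                            session_duration_s) {
  if (length(detections) != length(onscreen_clicks)) {
    stop_input("detections and onscreen_clicks must pair up")
  }
  if (length(detections) && any(onscreen_clicks < detections)) {
    stop_input("on-screen click cannot precede its detection")
  }
  structure(list(grasp_onsets = sort(as.numeric(grasp_onsets)),
                 detections = as.numeric(detections),
                 onscreen_clicks = as.numeric(onscreen_clicks),
                 session_duration_s = session_duration_s,
                 assignments = NULL),
            class = "click_event_log")
}

#' @export
print.click_event_log <- function(x, ...) {
  cat(sprintf("<click_event_log> %d grasp onsets, %d clicks over %.1f s%s\n",
              length(x$grasp_onsets), length(x$detections),
              x$session_duration_s,
              if (is.null(x$assignments)) "" else
                sprintf(" (TP %d / FP %d / FN %d)",
                        x$assignments$n_tp, x$assignments$n_fp,
                        x$assignments$n_fn)))
  invisible(x)
}

#' Assign TP/FP/FN labels to clicks and grasp onsets
#'
#' Greedy earliest-first matching: each click (time-sorted) is a true
#' positive if it falls within `tp_window_s` after some not-yet-consumed
#' onset (consuming the earliest such onset); all other clicks are false
#' positives; onsets with no click in their window are false negatives.
#'
#' @param log A [click_event_log()].
#' @param tp_window_s True-positive window after movement onset, seconds.
#' @param use Which click timestamp to compare against the window:
#'   `"onscreen"` (the user-visible click, default) or `"detection"`.
#' @return The log with `assignments` filled: per-click and per-onset
#'   labels, TP pairs with both latencies, and the TP/FP/FN counts.
#' @export
assign_events <- function(log, tp_window_s = 1.5,
                          use = c("onscreen", "detection")) {
  use <- match.arg(use)
  ct <- if (use == "onscreen") log$onscreen_clicks else log$detections
  ord <- order(ct)
  onsets <- log$grasp_onsets
  consumed <- rep(FALSE, length(onsets))
  click_lab <- rep("FP", length(ct))
  click_onset <- rep(NA_integer_, length(ct))
  for (j in ord) {
    cand <- which(!consumed & onsets <= ct[j] & ct[j] <= onsets + tp_window_s)
    if (length(cand)) {
      k <- cand[1]
      consumed[k] <- TRUE
      click_lab[j] <- "TP"
      click_onset[j] <- k
    }
  }
  tp <- which(click_lab == "TP")
  log$assignments <- list(
    click = click_lab,
    onset = ifelse(consumed, "TP", "FN"),
    tp_pairs = data.frame(
      onset = onsets[click_onset[tp]],
      detection = log$detections[tp],
      onscreen = log$onscreen_clicks[tp]
    ),
    n_tp = length(tp),
    n_fp = sum(click_lab == "FP"),
    n_fn = sum(!consumed),
    tp_window_s = tp_window_s
  )
  log
}

#' Run the full closed-loop pipeline over a recording
#'
#' Streams a recording through the packetized engine (100 ms packets,
#' 256 ms buffer, 10-frame history, voting window, lockout), pairs the
#' resulting detections with the recording's ground-truth movement onsets,
#' and returns the assigned event log.
#'
#' @param raw An [ecog_recording()] whose events include
#'   `movement_onset`.
#' @param classifier Streaming classifier function, or a trained
#'   `click_model`.
#' @param stats Calibration statistics.
#' @param vcfg A [voting_config()].
#' @param scfg A [spectral_config()].
#' @param display_latency_s Constant added to detections for the on-screen
#'   click time (default 0.2 s).
#' @param tp_window_s True-positive window for [assign_events()].
#' @return An assigned [click_event_log()], with the raw classification
#'   sequence in attribute `"classifications"`.
#' @export
run_closed_loop <- function(raw, classifier, stats,
                            vcfg = voting_config(), scfg = spectral_config(),
                            display_latency_s = 0.2, tp_window_s = 1.5) {
  if (inherits(classifier, "click_model")) {
    classifier <- make_model_classifier(classifier)
  }
  state <- new_stream_state(nrow(raw$data), raw$fs, scfg, vcfg)
  tick_n <- round(vcfg$tick_s * raw$fs)
  n_packets <- ncol(raw$data) %/% tick_n
  for (p in seq_len(n_packets)) {
    pk <- raw$data[, ((p - 1) * tick_n + 1):(p * tick_n), drop = FALSE]
    state <- ingest_packet(state, pk, classifier, stats)$state
  }
  log <- click_event_log(event_times(raw, "movement_onset"),
                         state$clicks,
                         state$clicks + display_latency_s,
                         raw$duration_s)
  log <- assign_events(log, tp_window_s = tp_window_s)
  attr(log, "classifications") <- data.frame(t = state$class_times,
                                             label = state$class_labels)
  log
}
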