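#' Epoch a feature stream around cue events
#'
#' Cuts fixed-length trial epochs of the HG feature stream around each cue,
#' spanning `span_s` (default -1.0 to +2.5 s). An epoch consists of the
#' first frame whose window-end time reaches `cue + span_s[1]` and the
#' following frames up to the fixed epoch length; cues too close to the
#' recording edges are dropped with a warning.
#'
#' @param features A [feature_stream()].
#' @param cues Cue onset times in seconds.
#' @param span_s Epoch span relative to the cue, seconds.
#' @return Object of class `trial_epochs`: `hg` (trials x frames x
#'   channels), `cue_times`, `frame_t` (trials x frames absolute
#'   timestamps), `offsets_s` (zeros until realignment), `hop_s`, `span_s`.
#' @export
epoch_trials <- function(features, cues, span_s = c(-1.0, 2.5)) {
  hop <- features$hop_s
  n_frames_epoch <- round(diff(span_s) / hop) + 1L
  tt <- features$t
  keep <- logical(length(cues)); start <- integer(length(cues))
  for (i in seq_along(cues)) {
    j <- which(tt >= cues[i] + span_s[1] - 1e-9)[1]
    # the first frame must actually reach back to the requested pre-cue
    # context (within one hop), not merely be the earliest available frame
    if (!is.na(j) && j + n_frames_epoch - 1L <= length(tt) &&
        tt[j] <= cues[i] + span_s[1] + hop + 1e-9) {
      keep[i] <- TRUE; start[i] <- j
    }
  }
  if (any(!keep)) {
    warning(sprintf("dropped %d trial(s) without full epoch context", sum(!keep)))
  }
  cues <- cues[keep]; start <- start[keep]
  if (!length(cues)) stop_input("no usable trials: every cue lacks full epoch context")
  nch <- ncol(features$values)
  hg <- array(0, c(length(cues), n_frames_epoch, nch))
  frame_t <- matrix(0, length(cues), n_frames_epoch)
  for (i in seq_along(cues)) {
    idx <- start[i]:(start[i] + n_frames_epoch - 1L)
    hg[i, , ] <- features$values[idx, ]
    frame_t[i, ] <- tt[idx]
  }
  structure(list(hg = hg, cue_times = cues, frame_t = frame_t,
                 offsets_s = rep(0, length(cues)),
                 hop_s = hop, span_s = span_s),
            class = "trial_epochs")
}

#' @export
print.trial_epochs <- function(x, ...) {
  cat(sprintf("<trial_epochs> %d trials x %d frames x %d channels, span [%g, %g] s\n",
              dim(x$hg)[1], dim(x$hg)[2], dim(x$hg)[3],
              x$span_s[1], x$span_s[2]))
  invisible(x)
}

# Relative frame times (trials x frames), seconds post-cue.
epoch_rel_times <- function(epochs) {
  sweep(epochs$frame_t, 1, epochs$cue_times)
}

#' Select highly activated channels for trial re-alignment
#'
#' Returns the `k` channels with the largest trial-averaged peak HG value in
#' the post-cue part of the epoch. Ties break toward the lowest channel
#' index.
#'
#' @param epochs A [epoch_trials()] result.
#' @param k Number of channels to select.
#' @return Integer vector of channel indices, sorted by decreasing peak.
#' @export
select_alignment_channels <- function(epochs, k) {
  nch <- dim(epochs$hg)[3]
  if (k < 1 || k > nch) stop_input("k must be in [1, %d]", nch)
  avg <- apply(epochs$hg, c(2, 3), mean)           # frames x channels
  post <- colMeans(epoch_rel_times(epochs)) >= 0
  peak <- apply(avg[post, , drop = FALSE], 2, max)
  ord <- order(-peak, seq_len(nch))
  sort_by_peak <- ord[seq_len(k)]
  sort_by_peak
}

# Pearson correlation that treats degenerate (zero-variance) traces as
# incomparable (-Inf) so they never win the lag search.
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
  stats::cor(a, b)
}

#' Re-align trials by template matching on selected channels
#'
#' Accounts for per-trial reaction-time variability: builds a template as
#' the trial mean of the selected-channel traces, exhaustively searches
#' integer-frame lags within `max_lag_s` for each trial (ties break toward
#' the smallest |lag|, then the earlier lag), shifts, rebuilds the template,
#' and iterates to convergence. Lag 0 is always in the search grid, so at
#' convergence no trial's correlation with the template is below its
#' unshifted value.
#'
#' @param epochs A [epoch_trials()] result.
#' @param channels Channel indices used for matching (see
#'   [select_alignment_channels()]).
#' @param max_lag_s Maximum |shift| in seconds (<= 0.5).
#' @param max_iter Maximum template-refinement iterations.
#' @return A `trial_epochs` object whose `hg` has been shifted per trial
#'   (edge frames replicated) and whose `offsets_s` holds the recovered
#'   shifts in seconds (positive = response later than template).
#' @export
realign_trials <- function(epochs, channels, max_lag_s = 0.3, max_iter = 10) {
  if (max_lag_s > 0.5) stop_input("max_lag_s must be <= 0.5")
  hop <- epochs$hop_s
  L <- round(max_lag_s / hop)
  nt <- dim(epochs$hg)[1]; nf <- dim(epochs$hg)[2]
  if (2 * L >= nf - 1) stop_input("max_lag_s too large for the epoch length")
  A <- epochs$hg[, , channels, drop = FALSE]       # trials x frames x k
  core <- (L + 1):(nf - L)
  trace <- function(i, off) as.vector(A[i, core + off, ])
  off <- rep(0L, nt)
  for (iter in seq_len(max_iter)) {
    tmpl <- Reduce(`+`, lapply(seq_len(nt), function(i) trace(i, off[i]))) / nt
    new_off <- off
    for (i in seq_len(nt)) {
      lags <- -L:L
      cors <- vapply(lags, function(l) safe_cor(trace(i, l), tmpl), 0)
      best <- max(cors)
      cand <- lags[cors >= best - 1e-12]
      new_off[i] <- cand[order(abs(cand), cand)][1]
    }
    if (all(new_off == off) && iter > 1) break
    off <- new_off
  }
  shifted <- epochs$hg
  for (i in seq_len(nt)) {
    if (off[i] != 0) {
      src <- pmin(pmax(seq_len(nf) + off[i], 1L), nf)
      shifted[i, , ] <- epochs$hg[i, src, ]
    }
  }
  out <- epochs
  out$hg <- shifted
  out$offsets_s <- off * hop
  out
}

#' Assign rest/grasp labels to epoch frames
#'
#' Frames whose (re-aligned) time relative to the cue lies in the half-open
#' window `[grasp_window_s[1], grasp_window_s[2])` are labeled `grasp`; all
#' other frames are `rest`.
#'
#' @param epochs A `trial_epochs` object (realigned or not).
#' @param grasp_window_s Label window in seconds post-cue, default
#'   `c(0.3, 1.1)`.
#' @return Character matrix trials x frames of `"rest"`/`"grasp"`.
#' @export
assign_labels <- function(epochs, grasp_window_s = c(0.3, 1.1)) {
  if (grasp_window_s[1] >= grasp_window_s[2]) {
    stop_input("empty grasp window")
  }
  if (grasp_window_s[1] < epochs$span_s[1] ||
      grasp_window_s[2] > epochs$span_s[2] + epochs$hop_s + 1e-9) {
    stop_input("grasp window must lie within the epoch span")
  }
  r <- epoch_rel_times(epochs)
  lab <- ifelse(r >= grasp_window_s[1] - 1e-9 & r < grasp_window_s[2] - 1e-9,
                "grasp", "rest")
  matrix(lab, nrow(r), ncol(r))
}

#' Label every frame of a continuous feature stream
#'
#' Stream-level counterpart of [assign_labels()]: a frame is `grasp` iff its
#' time falls in the half-open grasp window after any (offset-corrected)
#' cue.
#'
#' @param features A [feature_stream()].
#' @param cues Cue times, seconds.
#' @param offsets_s Per-trial re-alignment shifts added to the cue times
#'   (recycled; default 0).
#' @param grasp_window_s Label window, seconds post-cue.
#' @return Character vector of `"rest"`/`"grasp"`, one per frame.
#' @export
assign_stream_labels <- function(features, cues, offsets_s = 0,
                                 grasp_window_s = c(0.3, 1.1)) {
  if (grasp_window_s[1] >= grasp_window_s[2]) stop_input("empty grasp window")
  offsets_s <- rep_len(offsets_s, length(cues))
  lab <- rep("rest", length(features$t))
  for (i in seq_along(cues)) {
    r <- features$t - (cues[i] + offsets_s[i])
    lab[r >= grasp_window_s[1] - 1e-9 & r < grasp_window_s[2] - 1e-9] <- "grasp"
  }
  lab
}

#' Assemble a balanced, contiguously folded training dataset
#'
#' Builds one sample per labeled frame with a complete `history_len`-frame
#' feature history ending at that frame (the sample's label is the label of
#' its final frame). The over-represented rest class is randomly
#' downsampled, *within each fold*, to match that fold's grasp count, so
#' folds are contiguous in time, disjoint, jointly exhaustive, and
#' class-balanced.
#'
#' @param features A [feature_stream()].
#' @param labels Per-frame labels from [assign_stream_labels()].
#' @param history_len Frames of history per sample (default 10 = 1 s).
#' @param balance_seed Seed for the rest-class downsampling.
#' @param n_folds Number of contiguous folds (default 10).
#' @return Object of class `labeled_dataset`: `sequences` (samples x
#'   history x channels), `labels` (factor rest/grasp), `fold_ids`,
#'   `frame_idx`, `t`, `history_len`.
#' @export
build_dataset <- function(features, labels, history_len = 10,
                          balance_seed = 1, n_folds = 10) {
  n <- nrow(features$values)
  stopifnot(length(labels) == n)
  usable <- seq_len(n) >= history_len
  g_idx <- which(labels == "grasp" & usable)
  r_idx <- which(labels == "rest" & usable)
  if (!length(g_idx)) stop_input("no grasp-labeled frames with full history")
  n_folds <- min(n_folds, length(g_idx))
  # contiguous fold boundaries placed between grasp-frame blocks
  quota <- diff(round(seq(0, length(g_idx), length.out = n_folds + 1)))
  if (any(quota == 0)) stop_input("too few grasp frames for %d folds", n_folds)
  g_fold <- rep(seq_len(n_folds), quota)
  # frame-range boundary between fold f and f+1: midpoint between the
  # adjacent grasp frames
  cuts <- vapply(seq_len(n_folds - 1), function(f) {
    a <- max(g_idx[g_fold == f]); b <- min(g_idx[g_fold == f + 1])
    (a + b) / 2
  }, 0)
  frame_fold <- findInterval(seq_len(n), c(-Inf, cuts)) # 1..n_folds per frame
  sel <- integer(0); sel_fold <- integer(0)
  with_seed(balance_seed, {
    for (f in seq_len(n_folds)) {
      gf <- g_idx[frame_fold[g_idx] == f]
      rf <- r_idx[frame_fold[r_idx] == f]
      if (length(rf) < length(gf)) {
        stop_input("fold %d has %d rest frames for %d grasp frames; cannot balance",
                   f, length(rf), length(gf))
      }
      rs <- sort(sample(rf, length(gf)))
      idx <- sort(c(gf, rs))
      sel <- c(sel, idx)
      sel_fold <- c(sel_fold, rep(f, length(idx)))
    }
  })
  nch <- ncol(features$values)
  seqs <- array(0, c(length(sel), history_len, nch))
  for (s in seq_along(sel)) {
    seqs[s, , ] <- features$values[(sel[s] - history_len + 1):sel[s], ]
  }
  structure(list(sequences = seqs,
                 labels = factor(labels[sel], levels = c("rest", "grasp")),
                 fold_ids = sel_fold,
                 frame_idx = sel,
                 t = features$t[sel],
                 history_len = history_len),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples (%d grasp / %d rest) x %d frames x %d channels, %d folds\n",
              dim(x$sequences)[1], sum(x$labels == "grasp"),
              sum(x$labels == "rest"), dim(x$sequences)[2],
              dim(x$sequences)[3], length(unique(x$fold_ids))))
  invisible(x)
}
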