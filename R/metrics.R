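#' Click-detection sensitivity
#'
#' `100 * N_trueclicks / N_attemptedgrasps`, the percentage of attempted
#' grasps that produced a correctly detected click.
#'
#' @param log An assigned [click_event_log()].
#' @return Sensitivity in percent.
#' @export
compute_sensitivity <- function(log) {
  a <- need_assignments(log)
  n_grasps <- length(log$grasp_onsets)
  if (n_grasps == 0) stop_input("sensitivity undefined: no attempted grasps")
  100 * a$n_tp / n_grasps
}

#' True- and false-positive click frequencies
#'
#' TP and FP counts divided by the session duration, per minute.
#'
#' @param log An assigned [click_event_log()].
#' @return List with `tpf_per_min` and `fpf_per_min`.
#' @export
compute_rates <- function(log) {
  a <- need_assignments(log)
  if (is.null(log$session_duration_s) || log$session_duration_s <= 0) {
    stop_input("session duration must be positive")
  }
  t_min <- log$session_duration_s / 60
  list(tpf_per_min = a$n_tp / t_min, fpf_per_min = a$n_fp / t_min)
}

#' Click latency summaries
#'
#' For each true positive, the interval from movement onset to algorithm
#' detection and to the on-screen click, with medians, means and SDs.
#'
#' @param log An assigned [click_event_log()].
#' @return List with `detection` and `onscreen` components (`values`,
#'   `median`, `mean`, `sd`) and `n_tp`. Empty with a warning when there
#'   are no true positives.
#' @export
compute_latencies <- function(log) {
  a <- need_assignments(log)
  if (a$n_tp == 0) {
    warning("no true positives: empty latency summary")
    return(list(n_tp = 0L, detection = NULL, onscreen = NULL))
  }
  det <- a$tp_pairs$detection - a$tp_pairs$onset
  scr <- a$tp_pairs$onscreen - a$tp_pairs$onset
  summ <- function(x) list(values = x, median = stats::median(x),
                           mean = mean(x), sd = stats::sd(x))
  list(n_tp = a$n_tp, detection = summ(det), onscreen = summ(scr))
}

need_assignments <- function(log) {
  if (is.null(log$assignments)) {
    stop_input("event log has no TP/FP/FN assignments; run assign_events() first")
  }
  log$assignments
}

#' Spelling rate: correct characters and words per minute
#'
#' Characters are credited only where they exactly match their position in
#' the prompted sentence; a word (single-space tokenization) is credited
#' only if every one of its character positions matches. Trailing
#' whitespace is ignored and comparison is case-insensitive by default.
#'
#' @param typed The spelled text.
#' @param prompt The prompted sentence.
#' @param duration_s Spelling time, seconds.
#' @param case_sensitive Compare case-sensitively (default FALSE).
#' @return List with `n_correct_chars`, `n_correct_words`, `ccpm`, `cwpm`.
#' @export
score_spelling <- function(typed, prompt, duration_s,
                           case_sensitive = FALSE) {
  if (!nzchar(trimws(prompt))) stop_input("empty prompt")
  if (duration_s <= 0) stop_input("duration must be positive")
  norm <- function(s) {
    s <- sub("[ \t\r\n]+$", "", s)
    if (case_sensitive) s else toupper(s)
  }
  typed <- norm(typed); prompt <- norm(prompt)
  pc <- strsplit(prompt, "")[[1]]
  tc <- strsplit(typed, "")[[1]]
  n <- length(pc)
  ok <- rep(FALSE, n)
  m <- min(n, length(tc))
  if (m > 0) ok[seq_len(m)] <- pc[seq_len(m)] == tc[seq_len(m)]
  n_chars <- sum(ok)
  # word spans in the prompt (split on single spaces)
  starts <- c(1, which(pc == " ") + 1)
  ends <- c(which(pc == " ") - 1, n)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  n_words <- sum(vapply(seq_along(starts),
                        function(i) all(ok[starts[i]:ends[i]]), TRUE))
  list(n_correct_chars = n_chars, n_correct_words = n_words,
       ccpm = n_chars / (duration_s / 60),
       cwpm = n_words / (duration_s / 60))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum null distribution (midranks for ties)
#' when the combined sample size is at most `exact_max`; otherwise the
#' normal approximation with tie correction via [stats::wilcox.test()].
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest combined n for the exact path (default 12).
#' @return Two-sided p-value.
#' @export
ranksum_test <- function(a, b, exact_max = 12) {
  if (!length(a) || !length(b)) stop_input("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1) {
    warning("all values tied across both samples; p = 1")
    return(1)
  }
  n <- length(a) + length(b)
  if (n <= exact_max) {
    r <- rank(c(a, b))
    w_obs <- sum(r[seq_along(a)])
    combos <- utils::combn(n, length(a))
    w_all <- colSums(matrix(r[combos], nrow = length(a)))
    # two-sided doubled one-tail probability, capped at 1
    p_lo <- mean(w_all <= w_obs + 1e-9)
    p_hi <- mean(w_all >= w_obs - 1e-9)
    min(1, 2 * min(p_lo, p_hi))
  } else {
    stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  }
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param pvals P-values in `[0, 1]`.
#' @param alpha Familywise significance level for the reject flags.
#' @return List with `adjusted` (same order as input) and `reject`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1)) stop_input("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "holm")
  list(adjusted = adj, reject = adj < alpha)
}

#' Summarize a closed-loop session
#'
#' Convenience wrapper collecting sensitivity, click rates and latencies
#' from one assigned event log.
#'
#' @param log An assigned [click_event_log()].
#' @return Object of class `session_metrics`.
#' @export
session_metrics <- function(log) {
  rates <- compute_rates(log)
  lat <- suppressWarnings(compute_latencies(log))
  structure(list(sensitivity_pct = compute_sensitivity(log),
                 tpf_per_min = rates$tpf_per_min,
                 fpf_per_min = rates$fpf_per_min,
                 latency = lat,
                 n_tp = log$assignments$n_tp,
                 n_fp = log$assignments$n_fp,
                 n_fn = log$assignments$n_fn,
                 session_duration_s = log$session_duration_s),
            class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf("<session_metrics> sensitivity %.1f%%, TPF %.2f/min, FPF %.3f/min (TP %d / FP %d / FN %d in %.1f s)\n",
              x$sensitivity_pct, x$tpf_per_min, x$fpf_per_min,
              x$n_tp, x$n_fp, x$n_fn, x$session_duration_s))
  if (x$latency$n_tp > 0) {
    cat(sprintf("  median latency: detection %.2f s, on-screen %.2f s\n",
                x$latency$detection$median, x$latency$onscreen$median))
  }
  invisible(x)
}
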