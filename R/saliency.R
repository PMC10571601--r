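#' Integrated-gradients attribution for one sample
#'
#' Midpoint Riemann approximation of the path integral of the grasp-class
#' probability gradient along the straight line from `baseline` to
#' `sample`, scaled elementwise by `(sample - baseline)`. Satisfies the
#' completeness axiom (attributions sum to `f(sample) - f(baseline)`) to
#' within the quadrature error, which shrinks as `steps` grows.
#'
#' @param model A trained `click_model`.
#' @param sample `history_len x n_channels` input matrix.
#' @param baseline Reference input of the same shape (default all zeros,
#'   i.e. calibration-baseline activity).
#' @param steps Riemann steps (>= 8).
#' @param class Output probability attributed, `"grasp"` (default) or
#'   `"rest"`.
#' @return Attribution matrix of the sample's shape.
#' @export
integrated_gradients <- function(model, sample, baseline = NULL, steps = 64,
                                 class = "grasp") {
  cfg <- model$config
  if (is.null(baseline)) baseline <- matrix(0, cfg$history_len, cfg$n_channels)
  if (!all(dim(sample) == c(cfg$history_len, cfg$n_channels)) ||
      !all(dim(baseline) == dim(sample))) {
    stop_input("sample/baseline must be %d x %d", cfg$history_len, cfg$n_channels)
  }
  if (steps < 8) stop_input("steps must be >= 8")
  grad_fn <- function(X) input_gradient(model, X, class = class)
  midpoint_path_attribution(grad_fn, sample, baseline, steps)
}

# Midpoint-rule path attribution: (x - x') elementwise-scaled mean gradient
# along the straight line from baseline to sample. grad_fn takes a stacked
# n x nrow x ncol array and returns gradients of the same shape.
midpoint_path_attribution <- function(grad_fn, sample, baseline, steps) {
  diff <- sample - baseline
  alphas <- (seq_len(steps) - 0.5) / steps
  X <- array(0, c(steps, nrow(sample), ncol(sample)))
  for (s in seq_len(steps)) X[s, , ] <- baseline + alphas[s] * diff
  G <- grad_fn(X)
  avg <- apply(G, c(2, 3), mean)
  avg * diff
}

#' Per-channel saliency from an attribution map
#'
#' Collapses a `history_len x n_channels` attribution to one score per
#' channel: the L2 norm over the time steps.
#'
#' @param attribution Matrix from [integrated_gradients()].
#' @return Numeric vector, one non-negative score per channel.
#' @export
saliency_vector <- function(attribution) {
  sqrt(colSums(attribution^2))
}

#' Channel saliency map from repeated cross-validated models
#'
#' For each repetition and fold, computes integrated-gradients
#' attributions of the grasp-labeled samples in the validation fold using
#' that fold's model, collapses them to per-channel scores, averages over
#' all samples, folds and repetitions, and min-max normalizes to `[0, 1]`.
#'
#' @param data A [build_dataset()] result.
#' @param cfg Model configuration.
#' @param repetitions Repeated CV runs (paper setting: 20).
#' @param epochs Optional training-epoch override.
#' @param steps Integrated-gradients steps.
#' @param seed Base seed.
#' @param cv Optional precomputed [cross_validate()] result with
#'   `keep_models = TRUE` (avoids retraining).
#' @return Object of class `saliency_map`: `values` in `[0, 1]`,
#'   `raw_mean`, `n_samples`, `n_repetitions`.
#' @export
saliency_map <- function(data, cfg = model_config(), repetitions = 1,
                         epochs = NULL, steps = 64, seed = 1, cv = NULL) {
  if (!any(data$labels == "grasp")) stop_input("dataset has no grasp samples")
  if (is.null(cv)) {
    cv <- cross_validate(data, cfg, repetitions = repetitions,
                         epochs = epochs, seed = seed, keep_models = TRUE)
  }
  if (is.null(cv$models)) stop_input("cv result lacks models; use keep_models = TRUE")
  nch <- dim(data$sequences)[3]
  acc <- rep(0, nch); n_used <- 0L
  for (r in seq_along(cv$models)) {
    for (fi in seq_along(cv$folds)) {
      model <- cv$models[[r]][[fi]]
      va <- which(data$fold_ids == cv$folds[fi] & data$labels == "grasp")
      for (s in va) {
        att <- integrated_gradients(model,
                                    matrix(data$sequences[s, , ],
                                           data$history_len, nch),
                                    steps = steps)
        acc <- acc + saliency_vector(att)
        n_used <- n_used + 1L
      }
    }
  }
  raw <- acc / n_used
  rng <- range(raw)
  values <- if (rng[2] - rng[1] < .Machine$double.eps) {
    warning("constant saliency map; normalized to all zeros")
    rep(0, nch)
  } else {
    (raw - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(values = values, raw_mean = raw,
                 n_samples = n_used, n_repetitions = length(cv$models)),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  top <- order(-x$values)[1:min(5, length(x$values))]
  cat(sprintf("<saliency_map> %d channels from %d attributions (%d reps); top: %s\n",
              length(x$values), x$n_samples, x$n_repetitions,
              paste(top, collapse = ", ")))
  invisible(x)
}

#' Channel-subset ablation experiment
#'
#' Rebuilds the classifier on a channel subset, runs repeated contiguous
#' cross-validation, and (optionally) compares the per-fold accuracies to
#' a reference run with a rank-sum test, Holm-adjusted over the supplied
#' number of comparisons.
#'
#' @param data Full-channel [build_dataset()] result.
#' @param channel_subset Channel indices to keep (e.g. the hand-knob
#'   block), or negative indices to drop channels.
#' @param cfg Model configuration (its `n_channels` is replaced).
#' @param repetitions,epochs,seed Passed to [cross_validate()].
#' @param reference Optional per-fold accuracies of a reference run.
#' @param n_comparisons Holm correction family size (paper setting: 3).
#' @return Object of class `ablation_result`: `channel_subset`,
#'   `fold_accuracies`, `mean_accuracy`, `confusion_pct`, and
#'   `comparison_p` (adjusted) when a reference is given.
#' @export
ablation_experiment <- function(data, channel_subset, cfg = model_config(),
                                repetitions = 1, epochs = NULL, seed = 1,
                                reference = NULL, n_comparisons = 3) {
  nch <- dim(data$sequences)[3]
  if (!length(channel_subset)) stop_input("channel subset must be non-empty")
  if (all(channel_subset < 0)) {
    channel_subset <- setdiff(seq_len(nch), -channel_subset)
  }
  if (min(channel_subset) < 1 || max(channel_subset) > nch) {
    stop_input("channel subset out of range [1, %d]", nch)
  }
  sub <- data
  sub$sequences <- data$sequences[, , channel_subset, drop = FALSE]
  scfg <- cfg
  scfg$n_channels <- length(channel_subset)
  cv <- cross_validate(sub, scfg, repetitions = repetitions,
                       epochs = epochs, seed = seed)
  p_adj <- NULL
  if (!is.null(reference)) {
    p <- ranksum_test(cv$fold_mean, reference)
    p_adj <- min(1, p * n_comparisons)   # Holm step for one of m tests
  }
  structure(list(channel_subset = channel_subset,
                 fold_accuracies = cv$fold_mean,
                 mean_accuracy = cv$mean_accuracy,
                 confusion_pct = cv$confusion_pct,
                 comparison_p = p_adj),
            class = "ablation_result")
}
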