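adam_init <- function(model) {
  par <- c("W", "U", "b", "W1", "b1", "W2", "b2")
  list(m = lapply(model[par], function(p) p * 0),
       v = lapply(model[par], function(p) p * 0),
       t = 0)
}

adam_step <- function(model, grads, state) {
  cfg <- model$config
  state$t <- state$t + 1
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (p in names(state$m)) {
    state$m[[p]] <- cfg$beta1 * state$m[[p]] + (1 - cfg$beta1) * grads[[p]]
    state$v[[p]] <- cfg$beta2 * state$v[[p]] + (1 - cfg$beta2) * grads[[p]]^2
    model[[p]] <- model[[p]] - cfg$lr * (state$m[[p]] / bc1) /
      (sqrt(state$v[[p]] / bc2) + cfg$epsilon)
  }
  list(model = model, state = state)
}

dataset_targets <- function(labels) {
  Y <- matrix(0, length(labels), 2)
  Y[cbind(seq_along(labels), ifelse(labels == "grasp", 2, 1))] <- 1
  Y
}

#' Train the click classifier
#'
#' Minimizes categorical cross-entropy with Adam over seeded shuffled
#' mini-batches, applying inverted dropout to the LSTM output sequence and
#' the FC1 output. Deterministic given the training seed.
#'
#' @param model An (untrained) `click_model` from [build_model()].
#' @param data A [build_dataset()] result (or any list with `sequences`
#'   and `labels`).
#' @param epochs,batch_size Optional overrides of the model config.
#' @param seed Training seed (defaults to the model config seed).
#' @param sample_idx Optional subset of sample indices to train on.
#' @return The trained `click_model`, with a per-epoch `training_log`
#'   data frame (`epoch`, `loss`, `accuracy`).
#' @export
train_model <- function(model, data, epochs = NULL, batch_size = NULL,
                        seed = NULL, sample_idx = NULL) {
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  seed <- seed %||% cfg$seed
  idx_all <- sample_idx %||% seq_along(data$labels)
  if (!length(idx_all)) stop_input("empty training dataset")
  X <- data$sequences[idx_all, , , drop = FALSE]
  Y <- dataset_targets(data$labels[idx_all])
  n <- nrow(Y)
  p_drop <- cfg$dropout
  opt <- adam_init(model)
  log_loss <- numeric(epochs); log_acc <- numeric(epochs)
  with_seed(derive_seed(seed, 11), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq(1, n, by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1, n)]
        Xb <- X[bi, , , drop = FALSE]
        Yb <- Y[bi, , drop = FALSE]
        nb <- length(bi)
        masks <- if (p_drop > 0) {
          keep <- 1 - p_drop
          list(h = matrix((stats::runif(nb * cfg$history_len * cfg$lstm_units) < keep) / keep,
                          nb, cfg$history_len * cfg$lstm_units),
               e = matrix((stats::runif(nb * cfg$fc1_units) < keep) / keep,
                          nb, cfg$fc1_units))
        } else NULL
        fw <- model_forward(model, Xb, masks = masks, want_cache = TRUE)
        pt <- rowSums(fw$P * Yb)
        ep_loss <- ep_loss - sum(log(pmax(pt, 1e-12)))
        ep_correct <- ep_correct +
          sum((fw$P[, 2] > fw$P[, 1]) == (Yb[, 2] == 1))
        dlogits <- (fw$P - Yb) / nb
        bk <- model_backward(model, fw$cache, dlogits)
        upd <- adam_step(model, bk$grads, opt)
        model <- upd$model; opt <- upd$state
      }
      log_loss[ep] <- ep_loss / n
      log_acc[ep] <- ep_correct / n
    }
  })
  model$trained <- TRUE
  model$training_log <- data.frame(epoch = seq_len(epochs),
                                   loss = log_loss, accuracy = log_acc)
  model
}

#' Classification accuracy on a sample subset
#'
#' @param model A trained `click_model`.
#' @param data A `labeled_dataset`.
#' @param idx Sample indices to evaluate (default all).
#' @return Fraction of correct hard classifications.
#' @export
evaluate_accuracy <- function(model, data, idx = NULL) {
  idx <- idx %||% seq_along(data$labels)
  pred <- predict(model, data$sequences[idx, , , drop = FALSE], type = "class")
  mean(pred == data$labels[idx])
}

#' Contiguous-fold cross-validation
#'
#' Trains one model per fold (validation = that fold, training = the rest),
#' optionally repeated with different initialization/training seeds, and
#' pools a 2x2 confusion matrix over all folds and repetitions.
#'
#' @param data A [build_dataset()] result carrying contiguous balanced
#'   `fold_ids`.
#' @param cfg Model configuration for every fold model.
#' @param repetitions Number of repeated CV runs (re-initialized models).
#' @param epochs Optional override of `cfg$epochs`.
#' @param seed Base seed; each (repetition, fold) derives its own.
#' @param keep_models Keep the trained fold models (needed for saliency).
#' @return List with `fold_accuracy` (repetitions x folds matrix),
#'   `fold_mean` (per-fold mean over repetitions), `mean_accuracy`,
#'   `confusion_pct` (2x2, percent of all pooled validation samples) and,
#'   if requested, `models[[rep]][[fold]]`.
#' @export
cross_validate <- function(data, cfg = model_config(), repetitions = 1,
                           epochs = NULL, seed = 1, keep_models = FALSE) {
  folds <- sort(unique(data$fold_ids))
  k <- length(folds)
  for (f in folds) {
    lab <- data$labels[data$fold_ids == f]
    if (length(unique(lab)) < 2) {
      stop_input("fold %d contains a single class; cannot validate", f)
    }
  }
  acc <- matrix(0, repetitions, k)
  conf <- matrix(0, 2, 2, dimnames = list(true = c("rest", "grasp"),
                                          pred = c("rest", "grasp")))
  models <- if (keep_models) vector("list", repetitions) else NULL
  for (r in seq_len(repetitions)) {
    if (keep_models) models[[r]] <- vector("list", k)
    for (fi in seq_len(k)) {
      f <- folds[fi]
      tr <- which(data$fold_ids != f)
      va <- which(data$fold_ids == f)
      mcfg <- cfg
      mcfg$seed <- derive_seed(seed, r * 1000 + fi)
      model <- build_model(mcfg)
      model <- train_model(model, data, epochs = epochs, sample_idx = tr)
      pred <- predict(model, data$sequences[va, , , drop = FALSE],
                      type = "class")
      truth <- data$labels[va]
      acc[r, fi] <- mean(pred == truth)
      conf <- conf + table(factor(truth, c("rest", "grasp")),
                           factor(pred, c("rest", "grasp")))
      if (keep_models) models[[r]][[fi]] <- model
    }
  }
  out <- list(fold_accuracy = acc,
              fold_mean = colMeans(acc),
              mean_accuracy = mean(acc),
              confusion_pct = conf / sum(conf) * 100,
              folds = folds)
  if (keep_models) out$models <- models
  out
}
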