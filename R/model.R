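#' Classifier configuration
#'
#' Architecture and training recipe of the rest-vs-grasp sequence
#' classifier: an LSTM over a `history_len` x `n_channels` feature history
#' returning its full output sequence, flattened, then a fully-connected
#' eLU layer and a 2-unit softmax layer. With the defaults (128 channels,
#' 10 frames, 25 LSTM units, FC 10 and 2) the network has 17,932 trainable
#' parameters.
#'
#' @param n_channels Input channels per frame.
#' @param history_len Frames of feature history per sample.
#' @param lstm_units LSTM hidden units.
#' @param fc1_units First fully-connected layer width (eLU activation).
#' @param fc2_units Output layer width (softmax; 2 = rest/grasp).
#' @param dropout Dropout fraction applied to the LSTM output sequence and
#'   the FC1 output during training.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr,beta1,beta2,epsilon Adam optimizer settings.
#' @param seed Seed for weight initialization and training stochasticity.
#' @return Object of class `model_config`.
#' @export
model_config <- function(n_channels = 128, history_len = 10, lstm_units = 25,
                         fc1_units = 10, fc2_units = 2, dropout = 0.30,
                         epochs = 75, batch_size = 45,
                         lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, seed = 1) {
  if (dropout < 0 || dropout >= 1) stop_input("dropout must be in [0, 1)")
  if (min(n_channels, history_len, lstm_units, fc1_units, fc2_units,
          epochs, batch_size) < 1) {
    stop_input("all architecture counts must be positive")
  }
  structure(list(n_channels = as.integer(n_channels),
                 history_len = as.integer(history_len),
                 lstm_units = as.integer(lstm_units),
                 fc1_units = as.integer(fc1_units),
                 fc2_units = as.integer(fc2_units),
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = seed),
            class = "model_config")
}

#' Closed-form trainable parameter count
#'
#' `4 (nc nu + nu^2 + nu) + (T nu f1 + f1) + (f1 f2 + f2)` for `nc` input
#' channels, `nu` LSTM units, history length `T` and FC widths `f1`, `f2`.
#'
#' @param cfg A [model_config()] or `click_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(cfg) {
  if (inherits(cfg, "click_model")) cfg <- cfg$config
  as.integer(with(cfg,
    4 * (n_channels * lstm_units + lstm_units^2 + lstm_units) +
      (history_len * lstm_units * fc1_units + fc1_units) +
      (fc1_units * fc2_units + fc2_units)))
}

he_normal <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

#' Build an untrained classifier
#'
#' Initializes all weight matrices from a He-normal distribution (seeded),
#' biases at zero except the LSTM forget-gate bias at one. Gate order in
#' the stacked LSTM matrices is input, forget, cell, output.
#'
#' @param cfg A [model_config()].
#' @return Object of class `click_model`.
#' @export
build_model <- function(cfg = model_config()) {
  nu <- cfg$lstm_units; nc <- cfg$n_channels
  with_seed(derive_seed(cfg$seed, 7), {
    b <- rep(0, 4 * nu); b[(nu + 1):(2 * nu)] <- 1
    m <- list(
      config = cfg,
      W = he_normal(nc, 4 * nu, nc),
      U = he_normal(nu, 4 * nu, nu),
      b = b,
      W1 = he_normal(cfg$history_len * nu, cfg$fc1_units,
                     cfg$history_len * nu),
      b1 = rep(0, cfg$fc1_units),
      W2 = he_normal(cfg$fc1_units, cfg$fc2_units, cfg$fc1_units),
      b2 = rep(0, cfg$fc2_units),
      trained = FALSE, training_log = NULL
    )
    class(m) <- "click_model"
    m
  })
}

#' @export
print.click_model <- function(x, ...) {
  cat(sprintf("<click_model> %d ch x %d frames -> LSTM(%d) -> FC(%d, eLU) -> FC(%d, softmax); %d parameters%s\n",
              x$config$n_channels, x$config$history_len,
              x$config$lstm_units, x$config$fc1_units, x$config$fc2_units,
              n_parameters(x), if (x$trained) " (trained)" else ""))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Ensure input is an n x T x C array.
as_seq_array <- function(x, cfg) {
  if (is.matrix(x)) x <- array(x, c(1, nrow(x), ncol(x)))
  if (length(dim(x)) != 3 || dim(x)[2] != cfg$history_len ||
      dim(x)[3] != cfg$n_channels) {
    stop_input("input must be (n x) %d x %d [history x channels]",
               cfg$history_len, cfg$n_channels)
  }
  x
}

# Batched forward pass. masks: NULL (inference) or list(h, e) of inverted
# dropout masks. Returns probabilities plus the cache needed for backprop.
model_forward <- function(model, X, masks = NULL, want_cache = FALSE) {
  cfg <- model$config
  nu <- cfg$lstm_units; Tn <- cfg$history_len
  n <- dim(X)[1]
  H <- matrix(0, n, nu); C <- matrix(0, n, nu)
  Hflat <- matrix(0, n, Tn * nu)
  steps <- if (want_cache) vector("list", Tn) else NULL
  bmat <- rep(model$b, each = n)
  ii <- 1:nu; ff <- (nu + 1):(2 * nu); gg <- (2 * nu + 1):(3 * nu)
  oo <- (3 * nu + 1):(4 * nu)
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[, t, ], n, cfg$n_channels)
    Z <- Xt %*% model$W + H %*% model$U + bmat
    i <- sigmoid(Z[, ii, drop = FALSE]); f <- sigmoid(Z[, ff, drop = FALSE])
    g <- tanh(Z[, gg, drop = FALSE]);    o <- sigmoid(Z[, oo, drop = FALSE])
    C_prev <- C; H_prev <- H
    C <- f * C + i * g
    tc <- tanh(C)
    H <- o * tc
    Hflat[, ((t - 1) * nu + 1):(t * nu)] <- H
    if (want_cache) {
      steps[[t]] <- list(i = i, f = f, g = g, o = o, C = C, C_prev = C_prev,
                         H_prev = H_prev, tc = tc)
    }
  }
  Hd <- if (is.null(masks)) Hflat else Hflat * masks$h
  A1 <- Hd %*% model$W1 + rep(model$b1, each = n)
  E <- elu(A1)
  Ed <- if (is.null(masks)) E else E * masks$e
  logits <- Ed %*% model$W2 + rep(model$b2, each = n)
  P <- softmax_rows(logits)
  out <- list(P = P)
  if (want_cache) {
    out$cache <- list(X = X, steps = steps, Hflat = Hflat, Hd = Hd,
                      A1 = A1, Ed = Ed, masks = masks, n = n)
  }
  out
}

# Backprop from a gradient on the logits. Returns parameter gradients and,
# if want_dX, the gradient with respect to the input sequence.
model_backward <- function(model, cache, dlogits, want_dX = FALSE) {
  cfg <- model$config
  nu <- cfg$lstm_units; Tn <- cfg$history_len; n <- cache$n
  masks <- cache$masks
  dW2 <- crossprod(cache$Ed, dlogits)
  db2 <- colSums(dlogits)
  dEd <- dlogits %*% t(model$W2)
  dE <- if (is.null(masks)) dEd else dEd * masks$e
  dA1 <- dE * elu_grad(cache$A1)
  dW1 <- crossprod(cache$Hd, dA1)
  db1 <- colSums(dA1)
  dHd <- dA1 %*% t(model$W1)
  dHflat <- if (is.null(masks)) dHd else dHd * masks$h
  dW <- matrix(0, nrow(model$W), ncol(model$W))
  dU <- matrix(0, nrow(model$U), ncol(model$U))
  db <- rep(0, length(model$b))
  dX <- if (want_dX) array(0, dim(cache$X)) else NULL
  dH_carry <- matrix(0, n, nu); dC <- matrix(0, n, nu)
  ii <- 1:nu; ff <- (nu + 1):(2 * nu); gg <- (2 * nu + 1):(3 * nu)
  oo <- (3 * nu + 1):(4 * nu)
  for (t in rev(seq_len(Tn))) {
    st <- cache$steps[[t]]
    dH <- dHflat[, ((t - 1) * nu + 1):(t * nu), drop = FALSE] + dH_carry
    dC <- dC + dH * st$o * (1 - st$tc^2)
    do <- dH * st$tc
    di <- dC * st$g
    df <- dC * st$C_prev
    dg <- dC * st$i
    dZ <- matrix(0, n, 4 * nu)
    dZ[, ii] <- di * st$i * (1 - st$i)
    dZ[, ff] <- df * st$f * (1 - st$f)
    dZ[, gg] <- dg * (1 - st$g^2)
    dZ[, oo] <- do * st$o * (1 - st$o)
    Xt <- matrix(cache$X[, t, ], n, cfg$n_channels)
    dW <- dW + crossprod(Xt, dZ)
    dU <- dU + crossprod(st$H_prev, dZ)
    db <- db + colSums(dZ)
    if (want_dX) dX[, t, ] <- dZ %*% t(model$W)
    dH_carry <- dZ %*% t(model$U)
    dC <- dC * st$f
  }
  list(grads = list(W = dW, U = dU, b = db, W1 = dW1, b1 = db1,
                    W2 = dW2, b2 = db2),
       dX = dX)
}

#' Predict class probabilities for feature histories
#'
#' @param object A `click_model`.
#' @param newdata A single `history_len x n_channels` matrix or an
#'   `n x history_len x n_channels` array.
#' @param type `"prob"` for a probability matrix (columns rest, grasp) or
#'   `"class"` for hard labels (ties break toward rest).
#' @param ... Unused.
#' @return Probability matrix or factor of labels.
#' @export
predict.click_model <- function(object, newdata,
                                type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as_seq_array(newdata, object$config)
  P <- model_forward(object, X)$P
  colnames(P) <- c("rest", "grasp")
  if (type == "prob") return(P)
  factor(ifelse(P[, "grasp"] > P[, "rest"], "grasp", "rest"),
         levels = c("rest", "grasp"))
}

#' Gradient of the grasp probability with respect to the input
#'
#' Backpropagates the softmax grasp-class probability through the network
#' to the input feature history; used by the integrated-gradients
#' attribution.
#'
#' @param model A `click_model`.
#' @param x Input sample(s): `history_len x n_channels` matrix or
#'   `n x history_len x n_channels` array.
#' @param class Output whose probability is differentiated, `"grasp"`
#'   (default) or `"rest"`.
#' @return Array with the shape of `x`.
#' @export
input_gradient <- function(model, x, class = c("grasp", "rest")) {
  class <- match.arg(class)
  was_matrix <- is.matrix(x)
  X <- as_seq_array(x, model$config)
  fw <- model_forward(model, X, want_cache = TRUE)
  k <- if (class == "grasp") 2 else 1
  # d p_k / d z_j = p_k (delta_kj - p_j)
  onehot <- matrix(0, nrow(fw$P), ncol(fw$P)); onehot[, k] <- 1
  dlogits <- fw$P[, k] * (onehot - fw$P)
  dX <- model_backward(model, fw$cache, dlogits, want_dX = TRUE)$dX
  if (was_matrix) matrix(dX[1, , ], dim(X)[2], dim(X)[3]) else dX
}
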