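#' Attention-based feature reconstruction
#'
#' Reconstructs a sequence of feature vectors by scaled dot-product
#' attention: `Q = F W_Q`, `K = F W_K`, `V = F W_V`,
#' `A = rowsoftmax(Q K' / sqrt(d))`, output `A V`. Every row of `A` is a
#' probability distribution over the input positions, so each output vector
#' is a convex re-weighting of the value vectors, emphasising positions
#' whose keys align with the query.
#'
#' @param F numeric matrix `[T x d_in]`, one feature vector per row.
#' @param W_Q,W_K,W_V projection matrices `[d_in x d]`.
#' @return `[T x d]` matrix of reconstructed features, with the `[T x T]`
#'   attention weight matrix attached as attribute `"weights"`.
#' @export
attention_reconstruct <- function(F, W_Q, W_K, W_V) {
  F <- as.matrix(F)
  stopifnot(nrow(F) >= 1L,
            all(dim(W_Q) == dim(W_K)), all(dim(W_Q) == dim(W_V)),
            ncol(F) == nrow(W_Q))
  d <- ncol(W_Q)
  Q <- F %*% W_Q; K <- F %*% W_K; V <- F %*% W_V
  S <- Q %*% t(K) / sqrt(d)
  S <- S - apply(S, 1, max)            # stabilise row-wise
  E <- exp(S)
  A <- E / rowSums(E)
  structure(A %*% V, weights = A)
}

#' One gated-recurrent-unit step
#'
#' Evaluates the two-gate GRU recurrence for a single time step:
#' \deqn{z_t = \sigma(W_z [h_{t-1}; x_t] + b_z)}
#' \deqn{r_t = \sigma(W_r [h_{t-1}; x_t] + b_r)}
#' \deqn{\tilde h_t = \tanh(W_h [r_t \odot h_{t-1}; x_t] + b_h)}
#' \deqn{h_t = (1-z_t) \odot h_{t-1} + z_t \odot \tilde h_t}
#' The update gate decides how much of the previous state survives; the
#' reset gate controls how much of it feeds the candidate state. With
#' `reverse_gate = TRUE` the roles of `z` and `1 - z` in the final blend are
#' mirrored (both conventions appear in the literature).
#'
#' @param x_t input vector.
#' @param h_prev previous hidden state.
#' @param cell list with matrices `Wz`, `Wr`, `Wh` (`[H x (H + length(x_t))]`,
#'   acting on the concatenation `[h_prev; x_t]`) and bias vectors `bz`,
#'   `br`, `bh`; optional logical `reverse_gate`.
#' @return The next hidden state `h_t`; each element is a convex blend of
#'   bounded terms, so `h_t` stays in `[-1, 1]` whenever `h_prev` does.
#' @export
gru_step <- function(x_t, h_prev, cell) {
  H <- length(h_prev)
  u <- c(h_prev, x_t)
  stopifnot(ncol(cell$Wz) == length(u), nrow(cell$Wz) == H,
            all(dim(cell$Wr) == dim(cell$Wz)),
            all(dim(cell$Wh) == dim(cell$Wz)))
  sigm <- function(x) 1 / (1 + exp(-x))
  z <- sigm(as.numeric(cell$Wz %*% u + cell$bz))
  r <- sigm(as.numeric(cell$Wr %*% u + cell$br))
  htil <- tanh(as.numeric(cell$Wh %*% c(r * h_prev, x_t) + cell$bh))
  if (isTRUE(cell$reverse_gate)) z * h_prev + (1 - z) * htil
  else (1 - z) * h_prev + z * htil
}

#' Linear logistic model (reference classifier)
#'
#' A single-layer logistic classifier `p = sigmoid(w'x + b)` exposing the
#' same loss/gradient contract as the full network. Used as a closed-form
#' oracle for adversarial perturbation: for binary cross-entropy the input
#' gradient is `(p - y) w`, so a fast-gradient-sign step changes the logit
#' by exactly `eps * ||w||_1` in the loss-increasing direction.
#'
#' @param w weight vector (matched to flattened windows).
#' @param b scalar bias.
#' @return An object of class `linear_logit`.
#' @export
linear_logit <- function(w, b = 0) {
  structure(list(w = as.numeric(w), b = b), class = "linear_logit")
}

#' @export
predict.linear_logit <- function(object, x, ...) {
  x <- flatten_inputs(x, length(object$w))
  as.numeric(1 / (1 + exp(-(x %*% object$w + object$b))))
}

#' Mean binary cross-entropy of a model on inputs
#' @param model a classifier with a `predict` method returning probabilities.
#' @param x inputs (window array, matrix of flattened rows, or vector).
#' @param y labels in `[0, 1]`.
#' @param ... passed on to methods.
#' @return Mean binary cross-entropy (natural log).
#' @export
bce_loss <- function(model, x, y, ...) UseMethod("bce_loss")

#' @export
bce_loss.default <- function(model, x, y, ...) {
  p <- pmin(pmax(predict(model, x, ...), 1e-12), 1 - 1e-12)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Gradient of the loss with respect to the input
#'
#' Required by adversarial augmentation: `\eqn{\nabla_x J(\theta, x, y)}`
#' for the model's binary cross-entropy loss `J`, holding parameters fixed.
#'
#' @param model a classifier.
#' @param x inputs in the model's native shape.
#' @param y labels in `[0, 1]`.
#' @param ... passed on to methods.
#' @return Gradient with the same shape as `x`.
#' @export
input_gradient <- function(model, x, y, ...) UseMethod("input_gradient")

#' @export
input_gradient.linear_logit <- function(model, x, y, ...) {
  xm <- flatten_inputs(x, length(model$w))
  p <- as.numeric(1 / (1 + exp(-(xm %*% model$w + model$b))))
  g <- outer(p - y, model$w)          # d/dx of per-sample BCE
  if (is.null(dim(x)) || length(dim(x)) < 2L) as.numeric(g) else
    array(g, dim(as.array(x)))
}

flatten_inputs <- function(x, d) {
  if (is.null(dim(x))) {
    if (length(x) == d) matrix(x, 1L) else stop_validation("bad input length")
  } else if (length(dim(x)) == 3L) {
    matrix(x, dim(x)[1], d)
  } else as.matrix(x)
}
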