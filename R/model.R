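#' Model configuration
#'
#' Hyperparameters of the attention-augmented 1D CNN-GRU window classifier.
#' The defaults follow the reference configuration for this architecture:
#' convolution kernel 3 with length-preserving ("same") padding, max
#' pooling, 128 GRU units, dropout 0.5 before the dense head, Adam at
#' learning rate 0.001, 50 epochs, batch size 256. Layer widths that the
#' reference leaves open (two conv blocks of 32 and 64 filters, pool 2/2,
#' attention width 32) are package defaults and freely overridable.
#'
#' @param conv_channels filter counts, one per conv+pool block.
#' @param conv_kernel convolution kernel length in samples (odd).
#' @param pool max-pool width and stride per block.
#' @param attention_dim width `d` of the Q/K/V projections.
#' @param gru_units hidden-state size of the GRU.
#' @param dropout dropout rate applied to the final GRU state in training.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size mini-batch size (capped at the data size).
#' @param use_attention `FALSE` bypasses the attention layer (identity),
#'   degrading the model to a plain 1D CNN-GRU; the ablation hook.
#' @param reverse_gate mirrored GRU blend convention (see [gru_step()]).
#' @param seed integer seed for initialization and training.
#' @return A `model_config`.
#' @export
model_config <- function(conv_channels = c(32L, 64L), conv_kernel = 3L,
                         pool = 2L, attention_dim = 32L, gru_units = 128L,
                         dropout = 0.5, lr = 0.001, epochs = 50L,
                         batch_size = 256L, use_attention = TRUE,
                         reverse_gate = FALSE, seed = 1L) {
  if (conv_kernel %% 2L != 1L)
    stop_validation("conv_kernel must be odd (length-preserving padding)")
  if (dropout < 0 || dropout >= 1) stop_validation("dropout must be in [0, 1)")
  structure(list(conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel), pool = as.integer(pool),
                 attention_dim = as.integer(attention_dim),
                 gru_units = as.integer(gru_units), dropout = dropout,
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 use_attention = isTRUE(use_attention),
                 reverse_gate = isTRUE(reverse_gate), seed = as.integer(seed)),
            class = "model_config")
}

model_dims <- function(cfg, n_channels, window_samples) {
  L <- length(cfg$conv_channels)
  if (window_samples %% cfg$pool^L != 0L)
    stop(errorCondition(sprintf(
      "window_samples (%d) not divisible by cumulative pooling factor (%d)",
      window_samples, cfg$pool^L),
      class = c("ictalnet_config_error", "error")))
  list(C = as.integer(n_channels), S = as.integer(window_samples),
       K = cfg$conv_kernel, P = cfg$pool, A = cfg$attention_dim,
       H = cfg$gru_units, use_att = cfg$use_attention,
       rev_gate = cfg$reverse_gate, filters = cfg$conv_channels)
}

init_params <- function(cfg, dims) {
  L <- length(dims$filters)
  fan <- c(dims$C, dims$filters)
  with_seed(cfg$seed, {
    parts <- list()
    for (l in seq_len(L)) {
      fin <- fan[l] * dims$K
      parts[[length(parts) + 1L]] <-
        rnorm(fan[l + 1L] * fin, sd = sqrt(2 / fin))        # He (ReLU)
      parts[[length(parts) + 1L]] <- numeric(fan[l + 1L])   # conv bias
    }
    D <- fan[L + 1L]
    if (dims$use_att) {
      # W_Q starts at zero: attention is exactly uniform at initialization
      # (each reconstructed vector = mean of the value vectors), which gives
      # smooth global-average features from the first step; W_K nonzero
      # keeps the gradient into W_Q alive so attention can sharpen.
      parts[[length(parts) + 1L]] <- numeric(D * dims$A)    # W_Q
      for (i in 1:2)
        parts[[length(parts) + 1L]] <-
          rnorm(D * dims$A, sd = sqrt(1 / D))               # W_K, W_V
    }
    G <- if (dims$use_att) dims$A else D
    gin <- dims$H + G
    for (i in 1:3) {
      parts[[length(parts) + 1L]] <-
        rnorm(dims$H * gin, sd = sqrt(1 / gin))             # Wz, Wr, Wh
      parts[[length(parts) + 1L]] <- numeric(dims$H)
    }
    c(unlist(parts), numeric(dims$H), 0)                    # zero dense head
  })
}

#' Build the seizure classifier
#'
#' Assembles the five-part network for a given input geometry: conv+pool
#' feature extractor, attention reconstruction over the pooled feature
#' sequence, GRU fusion, dropout, and a single-unit sigmoid head trained
#' with binary cross-entropy. Initialization is deterministic under
#' `cfg$seed`; the dense head starts at zero, so an untrained model outputs
#' probability 0.5 everywhere.
#'
#' @param cfg a [model_config()].
#' @param n_channels channels per window.
#' @param window_samples samples per window; must be divisible by
#'   `pool^(number of conv blocks)`.
#' @return A `seizure_model`.
#' @export
build_model <- function(cfg, n_channels, window_samples) {
  stopifnot(inherits(cfg, "model_config"))
  dims <- model_dims(cfg, n_channels, window_samples)
  params <- init_params(cfg, dims)
  expected <- nn_n_params(dims)
  if (length(params) != expected)
    stop(sprintf("internal: parameter layout mismatch (%d vs %d)",
                 length(params), expected))
  structure(list(cfg = cfg, dims = dims, params = params,
                 trained = FALSE, log = NULL),
            class = "seizure_model")
}

#' @export
print.seizure_model <- function(x, ...) {
  cat(sprintf(
    "<seizure_model> %d ch x %d samples -> conv[%s] -> %s -> GRU(%d) -> sigmoid; %d parameters%s\n",
    x$dims$C, x$dims$S, paste(x$dims$filters, collapse = ","),
    if (x$dims$use_att) sprintf("attention(d=%d)", x$dims$A) else "no attention",
    x$dims$H, n_parameters(x), if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Number of learned parameters
#' @param model a `seizure_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) length(model$params)

windows_to_cube <- function(x) {
  if (inherits(x, "window_set")) x <- x$windows
  if (length(dim(x)) == 2L) x <- array(x, c(1L, dim(x)))
  aperm(x, c(2L, 3L, 1L))        # [n x C x S] -> [C x S x n]
}

check_geometry <- function(model, x) {
  d <- dim(x)
  if (d[1] != model$dims$C || d[2] != model$dims$S)
    stop_validation("window geometry [%d x %d] does not match model [%d x %d]",
                    d[1], d[2], model$dims$C, model$dims$S)
}

#' Train the classifier
#'
#' Minimizes mean binary cross-entropy over shuffled mini-batches with Adam.
#' Soft labels from mixup are consumed as-is. Training is reproducible: the
#' shuffle order and dropout masks derive from `seed` alone.
#'
#' @param model a `seizure_model` from [build_model()].
#' @param data a `window_set` (labels may be fractional).
#' @param epochs override `model$cfg$epochs`.
#' @param seed override the training seed (default `cfg$seed`).
#' @param verbose print per-epoch loss.
#' @return The trained model; the per-epoch log (`epoch`, `loss`,
#'   `train_acc`) is stored in `$log`.
#' @export
train_model <- function(model, data, epochs = NULL, seed = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "seizure_model"), inherits(data, "window_set"))
  n <- n_windows(data)
  if (n == 0L) stop_validation("empty training set")
  X <- windows_to_cube(data)
  check_geometry(model, X)
  y <- data$labels
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  seed <- seed %||% cfg$seed
  bsz <- min(cfg$batch_size, n)
  H <- model$dims$H
  theta <- model$params
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; tstep <- 0L
  log_rows <- vector("list", epochs)

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / bsz))
      ep_loss <- 0; ep_correct <- 0
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        B <- length(idx)
        mask <- if (cfg$dropout > 0) {
          matrix(rbinom(H * B, 1L, 1 - cfg$dropout), H, B)
        } else matrix(0, 0, 0)
        res <- nn_grad(theta, model$dims, X[, , idx, drop = FALSE],
                       y[idx], mask, cfg$dropout, FALSE)
        if (!is.finite(res$loss))
          stop(errorCondition(sprintf(
            "non-finite loss at epoch %d batch %d (labels: %s)",
            ep, bi, paste(round(y[idx], 3), collapse = ",")),
            class = c("ictalnet_numeric_error", "error")))
        tstep <- tstep + 1L
        g <- res$grad
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mhat <- m / (1 - b1^tstep)
        vhat <- v / (1 - b2^tstep)
        theta <- theta - cfg$lr * mhat / (sqrt(vhat) + epsA)
        ep_loss <- ep_loss + res$loss * B
        ep_correct <- ep_correct + sum((res$probs >= 0.5) == (y[idx] >= 0.5))
      }
      log_rows[[ep]] <- data.frame(epoch = ep, loss = ep_loss / n,
                                   train_acc = ep_correct / n)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f",
                        ep, ep_loss / n, ep_correct / n))
    }
  })
  model$params <- theta
  model$trained <- TRUE
  model$log <- do.call(rbind, log_rows)
  model
}

#' Predict seizure probabilities
#'
#' Inference-mode forward pass (no dropout), deterministic and independent
#' of window order.
#'
#' @param object a `seizure_model`.
#' @param windows a `window_set`, a `[n x C x S]` array, or one `[C x S]`
#'   window.
#' @param type `"prob"` for probabilities, `"class"` for hard 0/1 labels.
#' @param threshold decision threshold for `type = "class"`.
#' @param batch internal chunk size bounding memory.
#' @param ... unused.
#' @return Numeric vector of probabilities in `[0, 1]` or hard labels.
#' @export
predict.seizure_model <- function(object, windows, type = c("prob", "class"),
                                  threshold = 0.5, batch = 128L, ...) {
  type <- match.arg(type)
  X <- windows_to_cube(windows)
  check_geometry(object, X)
  n <- dim(X)[3]
  p <- numeric(n)
  at <- 1L
  while (at <= n) {
    hi <- min(at + batch - 1L, n)
    p[at:hi] <- nn_forward(object$params, object$dims,
                           X[, , at:hi, drop = FALSE], matrix(0, 0, 0), 0)
    at <- hi + 1L
  }
  if (type == "class") as.integer(p >= threshold) else p
}

#' @rdname input_gradient
#' @export
input_gradient.seizure_model <- function(model, x, y, ...) {
  X <- windows_to_cube(x)
  check_geometry(model, X)
  res <- nn_grad(model$params, model$dims, X, as.numeric(y),
                 matrix(0, 0, 0), 0, TRUE)
  if (!all(is.finite(res$xgrad)))
    stop(errorCondition("non-finite input gradient",
                        class = c("ictalnet_numeric_error", "error")))
  g <- aperm(res$xgrad, c(3L, 1L, 2L))          # back to [n x C x S]
  if (inherits(x, "window_set") || length(dim(x)) == 3L) g else g[1L, , ]
}

#' @export
bce_loss.seizure_model <- function(model, x, y, ...) {
  X <- windows_to_cube(x)
  check_geometry(model, X)
  res <- nn_grad(model$params, model$dims, X, as.numeric(y),
                 matrix(0, 0, 0), 0, FALSE)
  res$loss
}
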