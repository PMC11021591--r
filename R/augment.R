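#' Augmentation configuration
#'
#' Parameters of the combined adversarial + mixup training-set
#' amplification. `epsilon` is the L-infinity budget of the adversarial
#' perturbation, expressed in the units of the (normalized) windows — i.e.
#' per-channel training-set standard deviations when the standard z-score
#' preprocessing is used. `multiplier` is how many extra copies of the
#' training set are generated (`0` disables augmentation); `mix_ratio` is
#' the fraction of generated windows produced by mixup rather than
#' adversarial perturbation; mixup coefficients are drawn from
#' `Beta(mixup_alpha, mixup_alpha)`.
#'
#' @param epsilon L-infinity perturbation budget, `>= 0`.
#' @param multiplier integer amplification factor `n` (0, 1, 2, 3, ...).
#' @param mixup_alpha Beta shape for the mixing coefficient, `> 0`.
#' @param mix_ratio fraction of generated samples from mixup, in `[0, 1]`.
#' @param seed integer seed.
#' @return An `augmentation_config`.
#' @export
augmentation_config <- function(epsilon = 0.1, multiplier = 1L,
                                mixup_alpha = 0.2, mix_ratio = 0.5,
                                seed = 1L) {
  if (epsilon < 0) stop_validation("epsilon must be >= 0")
  if (multiplier < 0) stop_validation("multiplier must be >= 0")
  if (mixup_alpha <= 0) stop_validation("mixup_alpha must be > 0")
  if (mix_ratio < 0 || mix_ratio > 1)
    stop_validation("mix_ratio must lie in [0, 1]")
  structure(list(epsilon = epsilon, multiplier = as.integer(multiplier),
                 mixup_alpha = mixup_alpha, mix_ratio = mix_ratio,
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Adversarial perturbation under an L-infinity budget
#'
#' Fast gradient sign step: solves the linearized form of
#' `argmax J(theta, xbar, y)` subject to `||xbar - x||_inf <= eps` by
#' `xbar = x + eps * sign(grad_x J)`. The constraint holds exactly, with
#' equality wherever the gradient is nonzero, and the model parameters are
#' untouched. With `steps > 1` a projected multi-step ascent is run instead
#' (step size `eps/steps`, clipped back into the eps-ball each step).
#'
#' @param model classifier exposing [input_gradient()].
#' @param x windows in the model's native shape.
#' @param y true labels of `x` (kept by the augmented samples).
#' @param eps perturbation budget in the units of `x`.
#' @param steps number of ascent steps (1 = classic single-step).
#' @return Perturbed windows, same shape as `x`.
#' @export
adversarial_perturb <- function(model, x, y, eps, steps = 1L) {
  if (eps < 0) stop_validation("eps must be >= 0")
  if (eps == 0) return(x)
  if (steps == 1L) {
    g <- input_gradient(model, x, y)
    return(x + eps * sign(g))
  }
  xb <- x
  alpha <- eps / steps
  for (i in seq_len(steps)) {
    g <- input_gradient(model, xb, y)
    xb <- xb + alpha * sign(g)
    xb <- pmin(pmax(xb, x - eps), x + eps)
  }
  xb
}

#' Mixup of two windows
#'
#' Convex combination of a pair of windows and of their labels:
#' `(lam * x_i + (1-lam) * x_j, lam * y_i + (1-lam) * y_j)`. The soft label
#' is consumed directly by the binary cross-entropy loss.
#'
#' @param x_i,x_j windows of identical shape.
#' @param y_i,y_j their labels in `[0, 1]`.
#' @param lam mixing coefficient in `[0, 1]`.
#' @return List with elements `x` and `y`.
#' @export
mixup <- function(x_i, y_i, x_j, y_j, lam) {
  if (lam < 0 || lam > 1) stop_validation("lam must lie in [0, 1]")
  if (!identical(dim(x_i), dim(x_j)) || length(x_i) != length(x_j))
    stop_validation("mixup windows must share a shape")
  list(x = lam * x_i + (1 - lam) * x_j,
       y = lam * y_i + (1 - lam) * y_j)
}

#' Amplify a training set with adversarial and mixup samples
#'
#' Emits the original windows plus `multiplier * n` generated windows
#' (`n = |train|`): a `mix_ratio` share by mixup (partners sampled
#' uniformly, `lambda ~ Beta(alpha, alpha)`) and the rest by fast gradient
#' sign perturbation against `model` (sources cycled through the training
#' set; each keeps its source's true label). The model must already be
#' trained on the raw training set, and `train` must be normalized with the
#' training statistics, since `epsilon` is expressed in those units.
#'
#' The result is a `window_set` that additionally carries `origin`
#' (`"original"`, `"adversarial"` or `"mixup"`), provenance indices
#' `prov_i`, `prov_j` and the mixup coefficient `lambda` per window.
#'
#' @param train normalized training `window_set`.
#' @param model classifier trained on `train` (required when
#'   `multiplier > 0`).
#' @param cfg an [augmentation_config()].
#' @return An augmented `window_set` of size `(1 + multiplier) * n`.
#' @export
amplify <- function(train, model, cfg) {
  stopifnot(inherits(train, "window_set"),
            inherits(cfg, "augmentation_config"))
  n <- n_windows(train)
  out <- train
  out$origin <- rep("original", n)
  out$prov_i <- seq_len(n)
  out$prov_j <- rep(NA_integer_, n)
  out$lambda <- rep(NA_real_, n)
  if (cfg$multiplier == 0L) return(out)
  if (is.null(model) || !isTRUE(model$trained))
    stop_validation("amplify with multiplier > 0 needs a trained model")

  n_gen <- cfg$multiplier * n
  n_mix <- round(cfg$mix_ratio * n_gen)
  n_adv <- n_gen - n_mix

  gen <- with_seed(cfg$seed, {
    w <- array(0, c(n_gen, dim(train$windows)[2], dim(train$windows)[3]))
    y <- numeric(n_gen)
    origin <- character(n_gen)
    pi_ <- integer(n_gen); pj <- rep(NA_integer_, n_gen)
    lam <- rep(NA_real_, n_gen)
    if (n_adv > 0L) {
      src <- rep(seq_len(n), length.out = n_adv)   # cycle through the set
      xadv <- adversarial_perturb(
        model, train$windows[src, , , drop = FALSE], train$labels[src],
        cfg$epsilon)
      w[seq_len(n_adv), , ] <- xadv
      y[seq_len(n_adv)] <- train$labels[src]
      origin[seq_len(n_adv)] <- "adversarial"
      pi_[seq_len(n_adv)] <- src
    }
    if (n_mix > 0L) {
      ii <- rep(seq_len(n), length.out = n_mix)
      jj <- sample.int(n, n_mix, replace = TRUE)
      ll <- rbeta(n_mix, cfg$mixup_alpha, cfg$mixup_alpha)
      for (k in seq_len(n_mix)) {
        mx <- mixup(train$windows[ii[k], , ], train$labels[ii[k]],
                    train$windows[jj[k], , ], train$labels[jj[k]], ll[k])
        w[n_adv + k, , ] <- mx$x
        y[n_adv + k] <- mx$y
      }
      origin[n_adv + seq_len(n_mix)] <- "mixup"
      pi_[n_adv + seq_len(n_mix)] <- ii
      pj[n_adv + seq_len(n_mix)] <- jj
      lam[n_adv + seq_len(n_mix)] <- ll
    }
    list(w = w, y = y, origin = origin, pi_ = pi_, pj = pj, lam = lam)
  })

  out$windows <- abind3(train$windows, gen$w)
  out$labels <- c(train$labels, gen$y)
  out$sources <- rbind(train$sources,
                       train$sources[gen$pi_, , drop = FALSE])
  rownames(out$sources) <- NULL
  out$origin <- c(out$origin, gen$origin)
  out$prov_i <- c(out$prov_i, gen$pi_)
  out$prov_j <- c(out$prov_j, gen$pj)
  out$lambda <- c(out$lambda, gen$lam)
  out
}

#' Serialize an augmented set's provenance table
#'
#' One row per window: origin tag, source indices and mixup coefficient.
#'
#' @param aug an augmented `window_set` from [amplify()].
#' @return Data frame suitable for writing as CSV alongside the arrays.
#' @export
provenance_table <- function(aug) {
  stopifnot(!is.null(aug$origin))
  data.frame(index = seq_len(n_windows(aug)), origin = aug$origin,
             source_i = aug$prov_i, source_j = aug$prov_j,
             lambda = aug$lambda, label = aug$labels)
}
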