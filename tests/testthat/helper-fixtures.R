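# shared fixtures; everything is generated in code, no stored data

# small, fast synthetic world for unit tests (not the acceptance fixture)
tiny_synth_cfg <- function(...) {
  args <- list(n_channels = 2, fs = 64, duration_s = 60,
               seizure_len_s = 10, amplitude_gain = 3, seed = 42L)
  over <- list(...)
  args[names(over)] <- over
  if (is.null(args$seizure_intervals))
    args$seizure_intervals <-
      if (args$duration_s >= 30) list(c(20, 30)) else list()
  do.call(synth_config, args)
}

# model geometry small enough for oracle comparisons and gradient checks
tiny_model_cfg <- function(epochs = 5L, batch_size = 8L, dropout = 0,
                           seed = 3L, ...) {
  model_config(conv_channels = c(4L, 6L), attention_dim = 5L,
               gru_units = 7L, dropout = dropout, epochs = epochs,
               batch_size = batch_size, seed = seed, ...)
}

random_window_set <- function(n = 12, nch = 2, samples = 32, fs = 16,
                              labels = NULL, seed = 1) {
  set.seed(seed)
  window_set(array(rnorm(n * nch * samples), c(n, nch, samples)),
             labels %||% rep(c(0, 1), length.out = n),
             data.frame(patient_id = rep("T", n),
                        start_s = seq_len(n) * samples / fs),
             window_s = samples / fs, fs = fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pure-R re-implementation of the network forward pass, built from the
# exported attention_reconstruct()/gru_step() primitives plus hand-rolled
# conv/pool. Independent route used to cross-check the compiled forward.
r_unpack_params <- function(model) {
  d <- model$dims
  p <- model$params
  at <- 0L
  take <- function(n) { v <- p[(at + 1L):(at + n)]; at <<- at + n; v }
  L <- length(d$filters)
  fan <- c(d$C, d$filters)
  conv <- list()
  for (l in seq_len(L)) {
    conv[[l]] <- list(W = matrix(take(fan[l + 1] * fan[l] * d$K),
                                 fan[l + 1], fan[l] * d$K),
                      b = take(fan[l + 1]))
  }
  D <- fan[L + 1]
  att <- NULL
  if (d$use_att) {
    att <- list(Wq = matrix(take(D * d$A), D, d$A),
                Wk = matrix(take(D * d$A), D, d$A),
                Wv = matrix(take(D * d$A), D, d$A))
  }
  G <- if (d$use_att) d$A else D
  gru <- list()
  for (nm in c("Wz", "Wr", "Wh")) {
    gru[[nm]] <- matrix(take(d$H * (d$H + G)), d$H, d$H + G)
    gru[[sub("W", "b", nm)]] <- take(d$H)
  }
  gru$reverse_gate <- d$rev_gate
  head <- list(w = take(d$H), b = take(1))
  stopifnot(at == length(p))
  list(conv = conv, att = att, gru = gru, head = head)
}

r_forward_one <- function(model, x) {
  d <- model$dims
  pr <- r_unpack_params(model)
  pad <- (d$K - 1) / 2
  cur <- x
  for (l in seq_along(pr$conv)) {
    Cin <- nrow(cur); S <- ncol(cur)
    M <- matrix(0, Cin * d$K, S)
    for (k in seq_len(d$K)) {
      shift <- k - 1 - pad
      src <- seq_len(S) + shift
      ok <- src >= 1 & src <= S
      M[(k - 1) * Cin + seq_len(Cin), which(ok)] <- cur[, src[ok], drop = FALSE]
    }
    A <- pmax(pr$conv[[l]]$W %*% M + pr$conv[[l]]$b, 0)
    So <- S / d$P
    P <- matrix(0, nrow(A), So)
    for (j in seq_len(So))
      P[, j] <- apply(A[, ((j - 1) * d$P + 1):(j * d$P), drop = FALSE], 1, max)
    cur <- P
  }
  Fseq <- t(cur)
  G <- if (d$use_att) {
    unclass(attention_reconstruct(Fseq, pr$att$Wq, pr$att$Wk, pr$att$Wv))
  } else Fseq
  h <- numeric(d$H)
  for (t in seq_len(nrow(G))) h <- gru_step(G[t, ], h, pr$gru)
  1 / (1 + exp(-(sum(pr$head$w * h) + pr$head$b)))
}
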