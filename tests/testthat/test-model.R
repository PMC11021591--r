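# classifier: build contract, attention/GRU oracles, compiled-vs-R forward,
# gradient exactness, training behaviour

test_that("build respects the reference hyperparameter defaults", {
  cfg <- model_config()
  expect_identical(cfg$conv_kernel, 3L)
  expect_identical(cfg$gru_units, 128L)
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$lr, 0.001)
  expect_identical(cfg$epochs, 50L)
  expect_identical(cfg$batch_size, 256L)
  expect_error(model_config(conv_kernel = 4L),
               class = "ictalnet_validation_error")
})

test_that("build contract: shapes, probability range, determinism", {
  cfg <- tiny_model_cfg()
  m <- build_model(cfg, n_channels = 3, window_samples = 32)
  expect_gt(n_parameters(m), 0)
  X <- array(rnorm(5 * 3 * 32), c(5, 3, 32))
  p <- predict(m, X)
  expect_length(p, 5)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, rep(0.5, 5))   # zero-initialized head
  m2 <- build_model(cfg, 3, 32)
  expect_identical(m$params, m2$params)
  expect_error(build_model(cfg, 3, 30),   # 30 not divisible by pool^2
               class = "ictalnet_config_error")
})

test_that("dropout distinguishes training from inference mode", {
  cfg <- tiny_model_cfg(dropout = 0.5)
  m <- build_model(cfg, 2, 16)
  set.seed(1)
  m$params <- m$params + rnorm(n_parameters(m), sd = 0.3)
  X <- ictalnet:::windows_to_cube(array(rnorm(4 * 2 * 16), c(4, 2, 16)))
  mask <- matrix(rbinom(7 * 4, 1, 0.5), 7, 4)
  p_train <- ictalnet:::nn_forward(m$params, m$dims, X, mask, 0.5)
  p_inf1 <- ictalnet:::nn_forward(m$params, m$dims, X, matrix(0, 0, 0), 0)
  p_inf2 <- ictalnet:::nn_forward(m$params, m$dims, X, matrix(0, 0, 0), 0)
  expect_false(identical(p_train, p_inf1))
  expect_identical(p_inf1, p_inf2)   # inference is idempotent
})

test_that("attention reconstruction matches its degenerate closed forms", {
  # T = 1: softmax of a singleton is 1, output = value vector
  F1 <- matrix(c(0.3, -1.2), 1, 2)
  W <- diag(2)
  out <- attention_reconstruct(F1, W, W, W)
  expect_equal(attr(out, "weights"), matrix(1, 1, 1))
  expect_equal(unclass(out), F1 %*% W, ignore_attr = TRUE)

  # zero query: uniform weights, every output row = mean of value rows
  set.seed(2)
  F3 <- matrix(rnorm(12), 4, 3)
  Wk <- matrix(rnorm(6), 3, 2); Wv <- matrix(rnorm(6), 3, 2)
  out0 <- attention_reconstruct(F3, matrix(0, 3, 2), Wk, Wv)
  expect_equal(attr(out0, "weights"), matrix(0.25, 4, 4))
  V <- F3 %*% Wv
  for (r in 1:4) expect_equal(out0[r, ], colMeans(V), ignore_attr = TRUE)
})

test_that("attention matches an independent brute-force softmax", {
  # T = 3 hand-set projections; oracle computed elementwise from scratch
  F <- matrix(c(1, 0, -1, 2, 0.5, 1), 3, 2)
  Wq <- matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2)
  Wk <- matrix(c(-0.1, 0.4, 0.9, -0.6), 2, 2)
  Wv <- matrix(c(1, 0, 0.5, -1), 2, 2)
  Q <- F %*% Wq; K <- F %*% Wk; V <- F %*% Wv
  A_brute <- matrix(0, 3, 3)
  for (i in 1:3) {
    s <- numeric(3)
    for (j in 1:3) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(2)
    A_brute[i, ] <- exp(s) / sum(exp(s))
  }
  out <- attention_reconstruct(F, Wq, Wk, Wv)
  expect_equal(attr(out, "weights"), A_brute, tolerance = 1e-12)
  expect_equal(unclass(out), A_brute %*% V, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowSums(attr(out, "weights")), rep(1, 3), tolerance = 1e-9)
})

test_that("gru_step matches closed forms and stays bounded", {
  # all-zero cell: z = r = 0.5, candidate = 0, h' = 0.5 * h_prev
  cell0 <- list(Wz = matrix(0, 1, 2), bz = 0, Wr = matrix(0, 1, 2), br = 0,
                Wh = matrix(0, 1, 2), bh = 0)
  expect_equal(gru_step(x_t = 0, h_prev = 1, cell0), 0.5)
  expect_equal(gru_step(x_t = 3, h_prev = -0.4, cell0), -0.2)

  # random 2-unit cell against an elementwise hand oracle
  set.seed(4)
  for (case in 1:20) {
    cell <- list(Wz = matrix(rnorm(2 * 5), 2), bz = rnorm(2),
                 Wr = matrix(rnorm(2 * 5), 2), br = rnorm(2),
                 Wh = matrix(rnorm(2 * 5), 2), bh = rnorm(2))
    x <- rnorm(3); h <- runif(2, -1, 1)
    u <- c(h, x)
    z <- r <- ht <- numeric(2)
    for (i in 1:2) {
      z[i] <- 1 / (1 + exp(-(sum(cell$Wz[i, ] * u) + cell$bz[i])))
      r[i] <- 1 / (1 + exp(-(sum(cell$Wr[i, ] * u) + cell$br[i])))
    }
    u2 <- c(r * h, x)
    for (i in 1:2) ht[i] <- tanh(sum(cell$Wh[i, ] * u2) + cell$bh[i])
    want <- (1 - z) * h + z * ht
    got <- gru_step(x, h, cell)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(abs(got) <= 1))   # convex blend of bounded terms

    cell$reverse_gate <- TRUE
    expect_equal(gru_step(x, h, cell), z * h + (1 - z) * ht,
                 tolerance = 1e-12)
  }
})

test_that("compiled forward equals the pure-R composition of primitives", {
  X <- array(rnorm(3 * 2 * 16), c(3, 2, 16))
  for (variant in list(list(att = TRUE, rev = FALSE),
                       list(att = FALSE, rev = FALSE),
                       list(att = TRUE, rev = TRUE))) {
    cfg <- tiny_model_cfg(use_attention = variant$att,
                          reverse_gate = variant$rev)
    m <- build_model(cfg, 2, 16)
    set.seed(10)
    m$params <- m$params + rnorm(n_parameters(m), sd = 0.4)
    p_cpp <- predict(m, X)
    p_r <- vapply(1:3, function(i) r_forward_one(m, X[i, , ]), 0)
    expect_equal(p_cpp, p_r, tolerance = 1e-10,
                 label = sprintf("att=%s rev=%s", variant$att, variant$rev))
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_model_cfg()
  m <- build_model(cfg, 2, 16)
  set.seed(20)
  m$params <- m$params + rnorm(n_parameters(m), sd = 0.3)
  X <- ictalnet:::windows_to_cube(array(rnorm(3 * 2 * 16), c(3, 2, 16)))
  y <- c(1, 0, 0.5)
  res <- ictalnet:::nn_grad(m$params, m$dims, X, y, matrix(0, 0, 0), 0, TRUE)
  f <- function(th)
    ictalnet:::nn_grad(th, m$dims, X, y, matrix(0, 0, 0), 0, FALSE)$loss
  h <- 1e-5
  for (i in sample(n_parameters(m), 40)) {
    tp <- m$params
    tp[i] <- tp[i] + h; up <- f(tp)
    tp[i] <- tp[i] - 2 * h; dn <- f(tp)
    expect_equal(res$grad[i], (up - dn) / (2 * h), tolerance = 1e-5)
  }
  fx <- function(Xp)
    ictalnet:::nn_grad(m$params, m$dims, Xp, y, matrix(0, 0, 0), 0, FALSE)$loss
  for (i in sample(length(X), 20)) {
    Xp <- X
    Xp[i] <- Xp[i] + h; up <- fx(Xp)
    Xp[i] <- Xp[i] - 2 * h; dn <- fx(Xp)
    expect_equal(res$xgrad[i], (up - dn) / (2 * h), tolerance = 1e-5)
  }
})

test_that("input gradients are finite on random batches", {
  m <- build_model(tiny_model_cfg(), 2, 32)
  set.seed(30)
  m$params <- m$params + rnorm(n_parameters(m), sd = 0.3)
  X <- array(rnorm(6 * 2 * 32), c(6, 2, 32))
  g <- input_gradient(m, X, rep(c(0, 1), 3))
  expect_identical(dim(g), dim(X))
  expect_true(all(is.finite(g)))
})

test_that("training learns a separable fixture and is reproducible", {
  set.seed(50)
  n <- 60
  # class 1 = high-amplitude windows: the caricature of ictal activity
  amp <- rep(c(1, 4), each = n / 2)
  X <- array(rnorm(n * 2 * 32), c(n, 2, 32)) * amp
  ws <- window_set(X, rep(c(0, 1), each = n / 2),
                   data.frame(patient_id = "T", start_s = seq_len(n)),
                   window_s = 2, fs = 16)
  cfg <- tiny_model_cfg(epochs = 40L, dropout = 0.2, batch_size = 16L)
  m <- build_model(cfg, 2, 32)
  fit <- train_model(m, ws)
  expect_true(all(is.finite(fit$log$loss)))
  expect_equal(nrow(fit$log), 40)
  expect_gte(tail(fit$log$train_acc, 1), 0.95)
  expect_lt(tail(fit$log$loss, 1), head(fit$log$loss, 1))

  fit2 <- train_model(m, ws)
  expect_identical(fit$params, fit2$params)   # bit-reproducible
  expect_identical(fit$log, fit2$log)
  fit3 <- train_model(m, ws, seed = 99L)
  expect_false(identical(fit$params, fit3$params))
})

test_that("prediction is order-invariant and validates geometry", {
  m <- build_model(tiny_model_cfg(), 2, 32)
  set.seed(60)
  m$params <- m$params + rnorm(n_parameters(m), sd = 0.3)
  X <- array(rnorm(7 * 2 * 32), c(7, 2, 32))
  p <- predict(m, X)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  expect_equal(predict(m, X[perm, , ]), p[perm], tolerance = 1e-12)
  expect_error(predict(m, array(0, c(2, 3, 32))),
               class = "ictalnet_validation_error")
  # hard labels at a threshold
  expect_identical(predict(m, X, type = "class"), as.integer(p >= 0.5))
})

test_that("ablated (no-attention) model builds and trains", {
  set.seed(70)
  X <- array(rnorm(30 * 2 * 32), c(30, 2, 32)) * rep(c(1, 4), each = 15)
  ws <- window_set(X, rep(c(0, 1), each = 15),
                   data.frame(patient_id = "T", start_s = 1:30),
                   window_s = 2, fs = 16)
  m <- build_model(tiny_model_cfg(use_attention = FALSE, epochs = 10L,
                                  batch_size = 8L), 2, 32)
  fit <- train_model(m, ws)
  expect_true(all(is.finite(fit$log$loss)))
  expect_false(fit$dims$use_att)
})
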