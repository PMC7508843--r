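enc_seq <- function(n, D = 4L, seed = 1L) {
  set.seed(seed)
  list(x = matrix(rnorm(n * D), n, D), y = sample(0:1, n, TRUE))
}

test_that("augmentation contract: n outputs, zero pads labelled 2, fuzzed", {
  l <- 8L
  s <- enc_seq(3)
  out <- augment_sequence(s$x, s$y, l)
  expect_length(out, 3L)
  expect_equal(vapply(out, `[[`, 0L, "n_real"), 1:3)
  expect_equal(rowSums(abs(out[[1]]$x[2:l, ])), rep(0, l - 1))
  expect_equal(out[[1]]$y, c(s$y[1], rep(2L, l - 1)))
  expect_equal(out[[3]]$y[1:3], s$y)

  set.seed(33)
  for (i in 1:20) {
    l <- sample(2:12, 1)
    n <- sample(seq_len(l), 1)
    s <- enc_seq(n, D = sample(2:6, 1), seed = i)
    out <- augment_sequence(s$x, s$y, l)
    expect_length(out, n)
    for (j in seq_len(n)) {
      a <- out[[j]]
      expect_equal(a$x[seq_len(j), , drop = FALSE],
                   s$x[seq_len(j), , drop = FALSE])   # labels/values unchanged
      expect_equal(a$y[seq_len(j)], s$y[seq_len(j)])
      if (j < l) {
        expect_true(all(a$x[(j + 1):l, ] == 0))       # post-padding only
        expect_true(all(a$y[(j + 1):l] == 2L))
      }
    }
  }

  # n > l keeps the most recent l visits
  s <- enc_seq(10)
  out <- augment_sequence(s$x, s$y, 6L)
  expect_length(out, 6L)
  expect_equal(out[[6]]$x, s$x[5:10, ])
})

test_that("model parameter count matches the closed-form LSTM formula", {
  cfg <- model_config(hidden1 = 50L, hidden2 = 20L)
  m <- build_model(cfg, input_dim = 30L)
  want <- 4 * (50 * (50 + 30) + 50) + 4 * (20 * (20 + 50) + 20) + (20 + 1)
  expect_equal(n_params(m), want)

  cfg2 <- model_config(hidden1 = 7L, hidden2 = 3L)
  m2 <- build_model(cfg2, input_dim = 5L)
  expect_equal(n_params(m2),
               4 * (7 * (7 + 5) + 7) + 4 * (3 * (3 + 7) + 3) + 4)
})

test_that("forward pass emits (batch, l) risks in (0, 1)", {
  params <- drusenseq:::init_params(4, 6, 3, 1)
  X <- array(rnorm(5 * 7 * 4), c(5, 7, 4))
  fwd <- drusenseq:::forward_model(params, X)
  expect_equal(dim(fwd$yhat), c(5, 7))
  expect_true(all(fwd$yhat > 0 & fwd$yhat < 1))
})

test_that("loss: closed forms and loop oracle to 1e-6", {
  l <- 10L
  # perfect prediction on real steps, pads masked: loss ~ 0
  Y <- matrix(c(1, 0, 1, rep(2, l - 3)), 1, l)
  Yhat <- matrix(c(1, 0, 1, runif(l - 3)), 1, l)
  expect_lt(seq_loss(Y, Yhat, c(1, 1, 0)), 1e-5)

  # yhat = 0.5 on j real steps -> (j/l) ln 2, exactly
  for (j in c(1, 4, 7)) {
    Y <- matrix(c(rep(1, j), rep(2, l - j)), 1, l)
    Yhat <- matrix(0.5, 1, l)
    expect_equal(seq_loss(Y, Yhat, c(1, 1, 0)), (j / l) * log(2),
                 tolerance = 1e-12)
  }

  # all padding with lambda[3] = 0 contributes nothing
  expect_equal(seq_loss(matrix(2, 2, l), matrix(0.3, 2, l), c(1, 1, 0)), 0)

  # random batches equal the independent per-timestep loop oracle
  set.seed(4)
  for (i in 1:10) {
    N <- sample(1:5, 1); l <- sample(3:12, 1)
    Y <- matrix(sample(0:2, N * l, TRUE), N, l)
    Yhat <- matrix(runif(N * l), N, l)
    lam <- c(1, runif(1, 0.5, 30), sample(c(0, 0.3), 1))
    expect_equal(seq_loss(Y, Yhat, lam), oracle_loss(Y, Yhat, lam),
                 tolerance = 1e-6)
  }
  expect_error(seq_loss(matrix(0, 2, 3), matrix(0.5, 3, 2)), "shapes")
})

test_that("analytic BPTT gradients match finite differences", {
  set.seed(42)
  D <- 4L; l <- 5L; N <- 3L
  params <- drusenseq:::init_params(D, 3, 2, 9)
  X <- array(rnorm(N * l * D), c(N, l, D))
  Y <- matrix(sample(0:2, N * l, TRUE), N, l)
  wt <- matrix(runif(N * l), N, l); wt[Y == 2L] <- 0
  bl <- drusenseq:::batch_loss_grad(params, X, Y, wt, N)
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in idx) {
      eps <- 1e-6
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      up <- drusenseq:::batch_loss_grad(p2, X, Y, wt, N)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      dn <- drusenseq:::batch_loss_grad(p2, X, Y, wt, N)$loss
      expect_equal(bl$grads[[nm]][i], (up - dn) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("causality: perturbing future inputs never changes prediction at t", {
  params <- drusenseq:::init_params(5, 8, 4, 2)
  set.seed(10)
  l <- 9L
  X <- array(rnorm(1 * l * 5), c(1, l, 5))
  base <- drusenseq:::forward_model(params, X)$yhat
  for (t in 1:(l - 1)) {
    Xp <- X
    Xp[1, (t + 1):l, ] <- Xp[1, (t + 1):l, ] + 50 * rnorm(length(Xp[1, (t + 1):l, ]))
    pert <- drusenseq:::forward_model(params, Xp)$yhat
    expect_equal(pert[1, 1:t], base[1, 1:t], tolerance = 1e-6)
  }
})

test_that("weighted training path reproduces the explicit augmentation loss", {
  co <- tiny_cohort(n_eyes = 15L, seed = 17L)
  sq <- build_labeled_sequences(co, 3L)
  schema <- fit_encoder(do.call(rbind, lapply(sq, `[[`, "visits")))
  l <- 24L
  wgt <- drusenseq:::sequences_to_arrays(sq, schema, "h3", l, "weighted")
  exp_ <- drusenseq:::sequences_to_arrays(sq, schema, "h3", l, "explicit")
  params <- drusenseq:::init_params(dim(wgt$X)[3], 6, 3, 5)
  lambda <- c(1, 3, 0)
  lw <- drusenseq:::batch_loss_grad(
    params, wgt$X, wgt$Y,
    wgt$M * matrix(lambda[wgt$Y + 1L], nrow(wgt$Y), ncol(wgt$Y)), wgt$norm
  )
  le <- drusenseq:::batch_loss_grad(
    params, exp_$X, exp_$Y,
    exp_$M * matrix(lambda[exp_$Y + 1L], nrow(exp_$Y), ncol(exp_$Y)),
    exp_$norm
  )
  expect_equal(wgt$norm, dim(exp_$X)[1])      # one virtual copy per prefix
  expect_equal(lw$loss, le$loss, tolerance = 1e-9)
  for (nm in names(params)) {
    expect_equal(lw$grads[[nm]], le$grads[[nm]], tolerance = 1e-8)
  }
})

test_that("training: smoke behaviour, determinism, degenerate labels", {
  co <- tiny_cohort(n_eyes = 40L, seed = 19L)
  sq <- build_labeled_sequences(co, 3L)
  cfg <- model_config(hidden1 = 10L, hidden2 = 5L, epochs = 8L,
                      patience = 8L, n_ensemble = 1L, horizon_k = 3L,
                      seed = 4L)
  m1 <- train_deep_sequence(sq, cfg)
  m2 <- train_deep_sequence(sq, cfg)
  expect_identical(m1$params, m2$params)          # bit-reproducible on CPU
  # training loss decreases over the first epochs
  expect_lt(m1$history$train_loss[nrow(m1$history)], m1$history$train_loss[1])

  # same input twice -> identical scores; last-step score equals predict_risk
  s <- sq[[1]]
  r1 <- predict_sequence(m1, s$visits)
  r2 <- predict_sequence(m1, s$visits)
  expect_identical(r1, r2)
  expect_equal(predict_risk(m1, s$visits), r1[length(r1)])
  expect_true(all(r1 > 0 & r1 < 1))

  # all-negative labels refuse to train
  sq0 <- lapply(sq, function(s) { s$labels[, 1] <- 0L; s })
  expect_error(train_deep_sequence(sq0, cfg), "degenerate labels",
               class = "drusenseq_degenerate")

  # weighted path demands a masking pad weight
  cfgbad <- model_config(lambda_weights = c(1, 1, 0.5), epochs = 2L,
                         n_ensemble = 1L, horizon_k = 3L)
  expect_error(train_deep_sequence(sq, cfgbad), "lambda\\[3\\]")
  expect_no_error(
    train_deep_sequence(sq, cfgbad, augment = "explicit")
  )
})

test_that("eyes with faster drusen growth score higher on average", {
  co <- tiny_cohort(n_eyes = 80L, seed = 23L)
  sq <- build_labeled_sequences(co, 3L)
  cfg <- model_config(epochs = 30L, patience = 10L, n_ensemble = 1L,
                      horizon_k = 3L, seed = 8L)
  m <- train_deep_sequence(sq, cfg)
  risk <- vapply(sq, function(s) predict_risk(m, s$visits), 0)
  vol_end <- vapply(sq, function(s) {
    v <- s$visits$total_volume
    v[length(v)]
  }, 0)
  hi <- vol_end > stats::median(vol_end)
  expect_gt(mean(risk[hi]), mean(risk[!hi]))
})
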