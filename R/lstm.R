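#' Configuration of the stacked-LSTM risk model
#'
#' Two stacked one-directional LSTM layers (defaults 50 and 20 hidden units)
#' followed by a per-timestep affine + sigmoid scalar head: a many-to-many
#' network emitting, at every visit, the risk of exudation within the
#' horizon. One independent model is trained per horizon.
#'
#' @param l padded sequence length (default 24, one slot per monthly visit of
#'   a 24-month study); sequences longer than `l` keep their most recent `l`
#'   visits.
#' @param hidden1,hidden2 LSTM units in layers 1 and 2.
#' @param lambda_weights length-3 weights for targets (0, 1, 2 = pad); `NULL`
#'   means `(1, n_neg/n_pos, 0)` with the class ratio computed on the
#'   training split.
#' @param learning_rate,epochs,batch_size Adam settings.
#' @param patience early-stopping patience (epochs without validation
#'   improvement) on the 20% validation split of the training set.
#' @param val_fraction fraction of training eyes held out for early stopping.
#' @param weight_decay L2 penalty on the weight matrices (not biases); at
#'   desk-scale cohorts the unregularised network memorises the training
#'   eyes within a few epochs, so the default is comparatively strong.
#' @param val_metric model-selection metric on the validation split:
#'   `"auc"` (default; ranking is what the evaluation measures and the
#'   weighted loss is a poor surrogate under a large class weight) or
#'   `"loss"`.
#' @param n_ensemble number of independently initialised members trained per
#'   model; predictions average the members' risks. Small recurrent nets on
#'   a few hundred eyes have high seed variance, and a 3-member average is a
#'   cheap stabiliser. Set 1 for a single network.
#' @param horizon_k prediction horizon in months.
#' @param seed integer; fans out to init, shuffling and the val split.
#' @return a `model_config` list.
#' @export
model_config <- function(l = 24L, hidden1 = 50L, hidden2 = 20L,
                         lambda_weights = NULL, learning_rate = 1e-3,
                         epochs = 100L, batch_size = 64L, patience = 10L,
                         val_fraction = 0.2, weight_decay = 3e-2,
                         val_metric = c("auc", "loss"), n_ensemble = 3L,
                         horizon_k = 3L, seed = 1L) {
  val_metric <- match.arg(val_metric)
  assert_that(is_count(l) && is_count(hidden1) && is_count(hidden2),
              "l, hidden1, hidden2 must be positive integers")
  if (!is.null(lambda_weights)) {
    assert_that(length(lambda_weights) == 3L && all(lambda_weights >= 0),
                "lambda_weights must be 3 non-negative reals")
  }
  structure(
    list(l = as.integer(l), hidden1 = as.integer(hidden1),
         hidden2 = as.integer(hidden2), lambda_weights = lambda_weights,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         val_fraction = val_fraction, weight_decay = weight_decay,
         val_metric = val_metric, n_ensemble = as.integer(n_ensemble),
         horizon_k = as.integer(horizon_k), seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Augment one visit sequence by incremental padding
#'
#' A length-`n` sequence yields exactly `n` fixed-length training sequences:
#' the j-th contains the first `j` real visits followed by `l - j`
#' post-padding slots, each a zero feature vector with target 2. Applied to
#' the training set only. If `n > l` the most recent `l` visits are kept
#' first (truncation), then augmented.
#'
#' @param x numeric matrix `n x D` of encoded visits (time-ordered).
#' @param y integer vector of length `n`, per-visit targets in `{0, 1, 2}`.
#' @param l padded length.
#' @return list of `n` elements, each `list(x = l x D matrix, y = length-l
#'   targets, n_real = j)`.
#' @export
augment_sequence <- function(x, y, l) {
  x <- as.matrix(x)
  assert_that(nrow(x) == length(y), "x and y lengths differ")
  assert_that(nrow(x) >= 1L, "need at least one visit")
  if (nrow(x) > l) {     # keep the most recent l visits
    keep <- (nrow(x) - l + 1L):nrow(x)
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- nrow(x)
  lapply(seq_len(n), function(j) {
    xp <- matrix(0, l, ncol(x))
    xp[seq_len(j), ] <- x[seq_len(j), , drop = FALSE]
    yp <- rep(2L, l)
    yp[seq_len(j)] <- y[seq_len(j)]
    list(x = xp, y = yp, n_real = j)
  })
}

pad_sequence <- function(x, y, l) {
  # single full-length padded copy (no augmentation)
  x <- as.matrix(x)
  if (nrow(x) > l) {
    keep <- (nrow(x) - l + 1L):nrow(x)
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- nrow(x)
  xp <- matrix(0, l, ncol(x))
  xp[seq_len(n), ] <- x
  yp <- rep(2L, l)
  yp[seq_len(n)] <- y
  list(x = xp, y = yp, n_real = n)
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

init_params <- function(D, h1, h2, seed) {
  set.seed(seed)
  b1 <- numeric(4 * h1); b1[(h1 + 1):(2 * h1)] <- 1   # forget-gate bias 1
  b2 <- numeric(4 * h2); b2[(h2 + 1):(2 * h2)] <- 1
  list(
    W1 = glorot(D, 4 * h1), U1 = glorot(h1, 4 * h1), b1 = b1,
    W2 = glorot(h1, 4 * h2), U2 = glorot(h2, 4 * h2), b2 = b2,
    w_out = glorot(h2, 1), b_out = 0
  )
}

#' Build an untrained stacked-LSTM model
#'
#' @param config a [model_config()].
#' @param input_dim feature dimension D.
#' @param schema optional `encoder_schema` to bundle with the model.
#' @return a `deep_sequence_model` with freshly initialised parameters.
#' @export
build_model <- function(config, input_dim, schema = NULL) {
  stopifnot(inherits(config, "model_config"))
  structure(
    list(
      params = init_params(input_dim, config$hidden1, config$hidden2,
                           derive_seed(config$seed, 1L)),
      config = config, schema = schema, input_dim = as.integer(input_dim),
      lambda = config$lambda_weights %||% c(1, 1, 0),
      horizon_k = config$horizon_k, history = NULL
    ),
    class = "deep_sequence_model"
  )
}

#' Parameter count of the model
#'
#' Each LSTM layer has `4 * (h * (h + d) + h)` parameters; the per-timestep
#' output head adds `h2 + 1`.
#' @param model a `deep_sequence_model`.
#' @return integer.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_layer_forward <- function(X_list, W, U, b, N) {
  # X_list: list over t of N x d inputs; returns hidden states + cache
  l <- length(X_list)
  h <- length(b) / 4L
  idx_i <- 1:h; idx_f <- (h + 1):(2 * h)
  idx_o <- (2 * h + 1):(3 * h); idx_g <- (3 * h + 1):(4 * h)
  hp <- matrix(0, N, h); cp <- matrix(0, N, h)
  H <- vector("list", l)
  cache <- vector("list", l)
  bmat <- matrix(b, N, 4 * h, byrow = TRUE)
  for (t in seq_len(l)) {
    a <- X_list[[t]] %*% W + hp %*% U + bmat
    i <- sigmoid(a[, idx_i, drop = FALSE])
    f <- sigmoid(a[, idx_f, drop = FALSE])
    o <- sigmoid(a[, idx_o, drop = FALSE])
    g <- tanh(a[, idx_g, drop = FALSE])
    c_t <- f * cp + i * g
    tc <- tanh(c_t)
    h_t <- o * tc
    cache[[t]] <- list(i = i, f = f, o = o, g = g, c_prev = cp, tc = tc,
                       h_prev = hp, x = X_list[[t]])
    hp <- h_t; cp <- c_t
    H[[t]] <- h_t
  }
  list(H = H, cache = cache)
}

lstm_layer_backward <- function(dH_list, W, U, cache, N) {
  # dH_list: gradient w.r.t. each hidden state (external contributions)
  l <- length(dH_list)
  h <- ncol(cache[[1]]$i)
  d <- ncol(cache[[1]]$x)
  dW <- matrix(0, d, 4 * h); dU <- matrix(0, h, 4 * h); db <- numeric(4 * h)
  dX <- vector("list", l)
  dh_next <- matrix(0, N, h)
  dc_next <- matrix(0, N, h)
  for (t in rev(seq_len(l))) {
    cc <- cache[[t]]
    dh <- dH_list[[t]] + dh_next
    do <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    df <- dc * cc$c_prev
    di <- dc * cc$g
    dg <- dc * cc$i
    dc_next <- dc * cc$f
    da <- cbind(
      di * cc$i * (1 - cc$i),
      df * cc$f * (1 - cc$f),
      do * cc$o * (1 - cc$o),
      dg * (1 - cc$g^2)
    )
    dW <- dW + crossprod(cc$x, da)
    dU <- dU + crossprod(cc$h_prev, da)
    db <- db + colSums(da)
    dh_next <- da %*% t(U)
    dX[[t]] <- da %*% t(W)
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

forward_model <- function(params, X) {
  # X: array N x l x D; returns yhat (N x l) and caches
  N <- dim(X)[1]; l <- dim(X)[2]; D <- dim(X)[3]
  X_list <- lapply(seq_len(l), function(t) matrix(X[, t, ], N, D))
  l1 <- lstm_layer_forward(X_list, params$W1, params$U1, params$b1, N)
  l2 <- lstm_layer_forward(l1$H, params$W2, params$U2, params$b2, N)
  yhat <- matrix(0, N, l)
  for (t in seq_len(l)) {
    yhat[, t] <- sigmoid(l2$H[[t]] %*% params$w_out + params$b_out)
  }
  list(yhat = yhat, l1 = l1, l2 = l2)
}

backward_model <- function(params, fwd, dlogit) {
  # dlogit: N x l gradient of the loss w.r.t. the output pre-sigmoid logit
  N <- nrow(dlogit); l <- ncol(dlogit)
  dH2 <- vector("list", l)
  dw_out <- matrix(0, nrow(params$w_out), 1)
  db_out <- 0
  for (t in seq_len(l)) {
    dl <- dlogit[, t, drop = FALSE]
    dw_out <- dw_out + crossprod(fwd$l2$H[[t]], dl)
    db_out <- db_out + sum(dl)
    dH2[[t]] <- dl %*% t(params$w_out)
  }
  g2 <- lstm_layer_backward(dH2, params$W2, params$U2, fwd$l2$cache, N)
  g1 <- lstm_layer_backward(g2$dX, params$W1, params$U1, fwd$l1$cache, N)
  list(W1 = g1$dW, U1 = g1$dU, b1 = g1$db,
       W2 = g2$dW, U2 = g2$dU, b2 = g2$db,
       w_out = dw_out, b_out = db_out)
}

#' Time-distributed weighted cross-entropy loss
#'
#' For each sequence, `-(1/l) * sum_t (y ln yhat + (1 - y) ln(1 - yhat)) *
#' lambda[y_t]`: per-timestep binary cross-entropy scaled by the weight of
#' the timestep's target label (0, 1, or 2 = padding; `lambda[3] = 0` masks
#' padding). Targets equal to 2 use 0 as the binary reference inside the
#' cross-entropy term (only relevant when `lambda[3] > 0`). Predictions are
#' clipped to `[1e-7, 1 - 1e-7]`. Returns the mean over sequences.
#'
#' @param Y integer matrix `N x l` of targets in `{0, 1, 2}`.
#' @param Yhat numeric matrix `N x l` of predicted risks in `(0, 1)`.
#' @param lambda length-3 non-negative weights, indexed by target + 1.
#' @return scalar loss.
#' @export
seq_loss <- function(Y, Yhat, lambda = c(1, 1, 0)) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  assert_that(all(dim(Y) == dim(Yhat)), "Y and Yhat shapes differ")
  assert_that(length(lambda) == 3L, "lambda must have length 3")
  eps <- 1e-7
  p <- pmin(pmax(Yhat, eps), 1 - eps)
  yb <- ifelse(Y == 1L, 1, 0)
  wt <- matrix(lambda[Y + 1L], nrow(Y), ncol(Y))
  ce <- -(yb * log(p) + (1 - yb) * log(1 - p)) * wt
  mean(rowSums(ce) / ncol(Y))
}

batch_loss_grad <- function(params, X, Y, wt, norm) {
  # wt: N x l combined weights (lambda x multiplicity); norm: scalar divisor
  fwd <- forward_model(params, X)
  eps <- 1e-7
  p <- pmin(pmax(fwd$yhat, eps), 1 - eps)
  yb <- ifelse(Y == 1L, 1, 0)
  l <- ncol(Y)
  loss <- sum(-(yb * log(p) + (1 - yb) * log(1 - p)) * wt) / (l * norm)
  dlogit <- wt * (fwd$yhat - yb) / (l * norm)
  grads <- backward_model(params, fwd, dlogit)
  list(loss = loss, grads = grads, yhat = fwd$yhat)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---------------------------------------------------------------------------

sequences_to_arrays <- function(sequences, schema, horizon_col, l,
                                augment = c("weighted", "explicit", "none")) {
  # Builds the padded tensors for a set of labeled_sequence objects.
  # "weighted": one padded copy per eye plus the augmentation multiplicity
  #   (n - t + 1) as a per-timestep weight -- exactly equivalent in loss and
  #   gradient to materialising the n prefix sequences when lambda[3] = 0
  #   (prefix predictions coincide with the full sequence's by causality).
  # "explicit": materialise every augmented prefix sequence.
  # "none": one padded copy per eye, unit multiplicity (evaluation).
  augment <- match.arg(augment)
  xs <- list(); ys <- list(); mult <- list(); eye <- character(0)
  for (s in sequences) {
    x <- encode_visits(schema, s$visits)
    y <- s$labels[, horizon_col]
    if (augment == "explicit") {
      for (a in augment_sequence(x, y, l)) {
        xs[[length(xs) + 1L]] <- a$x
        ys[[length(ys) + 1L]] <- a$y
        m <- rep(0, l); m[seq_len(a$n_real)] <- 1
        mult[[length(mult) + 1L]] <- m
        eye <- c(eye, s$eye_id)
      }
    } else {
      p <- pad_sequence(x, y, l)
      xs[[length(xs) + 1L]] <- p$x
      ys[[length(ys) + 1L]] <- p$y
      m <- rep(0, l)
      m[seq_len(p$n_real)] <- if (augment == "weighted") {
        p$n_real - seq_len(p$n_real) + 1
      } else 1
      mult[[length(mult) + 1L]] <- m
      eye <- c(eye, s$eye_id)
    }
  }
  N <- length(xs); D <- ncol(xs[[1]])
  X <- array(0, c(N, l, D))
  for (n in seq_len(N)) X[n, , ] <- xs[[n]]
  Y <- do.call(rbind, ys)
  M <- do.call(rbind, mult)
  # norm = number of (virtual) augmented sequences, so the weighted path
  # reproduces the mean-over-augmented-sequences loss
  norm <- if (augment == "weighted") sum(vapply(mult, max, 0)) else N
  list(X = X, Y = Y, M = M, eye = eye, norm = norm)
}

#' Train a Deep-Sequence risk model for one horizon
#'
#' Fits the encoder schema on the training eyes, builds the padded training
#' tensors (augmentation on the training set only), and optimises the
#' time-distributed weighted cross-entropy with Adam. 20% of the training
#' eyes (patient-level) are held out for early stopping; the best-validation
#' parameters are restored. Deterministic given `config$seed`.
#'
#' @param sequences list of `labeled_sequence` (the training split).
#' @param config a [model_config()].
#' @param schema optional pre-fitted `encoder_schema`; default fits on
#'   `sequences`' visit rows.
#' @param augment `"weighted"` (default; exact loss-equivalent reduction of
#'   the explicit augmentation, requires `lambda[3] == 0`) or `"explicit"`.
#' @param verbose print a line per epoch.
#' @return a trained `deep_sequence_model`; `$history` holds per-epoch
#'   training/validation loss.
#' @export
train_deep_sequence <- function(sequences, config, schema = NULL,
                                augment = c("weighted", "explicit"),
                                verbose = FALSE) {
  stopifnot(inherits(config, "model_config"))
  augment <- match.arg(augment)
  hcol <- paste0("h", config$horizon_k)
  assert_that(hcol %in% colnames(sequences[[1]]$labels),
              "sequences were not labeled for this horizon")

  # patient-level validation split for early stopping
  pats <- vapply(sequences, function(s) s$patient_id, "")
  upat <- unique(pats)
  set.seed(derive_seed(config$seed, 2L))
  n_val <- max(1L, round(config$val_fraction * length(upat)))
  val_pat <- sample(upat, n_val)
  is_val <- pats %in% val_pat
  train_seq <- sequences[!is_val]
  val_seq <- sequences[is_val]
  assert_that(length(train_seq) > 0 && length(val_seq) > 0,
              "too few eyes to split for early stopping")

  if (is.null(schema)) {
    schema <- fit_encoder(do.call(rbind, lapply(train_seq, `[[`, "visits")))
  }

  tr <- sequences_to_arrays(train_seq, schema, hcol, config$l, augment)
  va <- sequences_to_arrays(val_seq, schema, hcol, config$l, "none")

  n_pos <- sum(tr$Y == 1L & tr$M > 0)
  n_neg <- sum(tr$Y == 0L & tr$M > 0)
  if (n_pos == 0L) {
    stop_drusenseq("degenerate labels: no progressor in training data",
                   "drusenseq_degenerate")
  }
  lambda <- config$lambda_weights %||% c(1, n_neg / max(n_pos, 1), 0)
  if (augment == "weighted" && lambda[3] != 0) {
    stop_drusenseq(
      "weighted augmentation path requires lambda[3] == 0; use explicit",
      "drusenseq_invalid"
    )
  }
  wt_tr <- tr$M * matrix(lambda[tr$Y + 1L], nrow(tr$Y), ncol(tr$Y))
  wt_va <- va$M * matrix(lambda[va$Y + 1L], nrow(va$Y), ncol(va$Y))

  D <- dim(tr$X)[3]
  N <- dim(tr$X)[1]
  decay_on <- c("W1", "U1", "W2", "U2", "w_out")
  val_real <- va$Y != 2L & va$M > 0

  train_member <- function(member) {
    params <- init_params(D, config$hidden1, config$hidden2,
                          derive_seed(config$seed, 1L + 10L * member))
    state <- adam_init(params)
    set.seed(derive_seed(config$seed, 3L + 10L * member))
    best <- list(crit = Inf, params = params, epoch = 0L)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0), val_auc = numeric(0))
    wait <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0; ep_norm <- 0
      for (start in seq(1, N, by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1L, N)]
        Xb <- tr$X[bi, , , drop = FALSE]
        bnorm <- if (augment == "weighted") {
          sum(apply(tr$M[bi, , drop = FALSE], 1, max))
        } else length(bi)
        bl <- batch_loss_grad(params, Xb, tr$Y[bi, , drop = FALSE],
                              wt_tr[bi, , drop = FALSE], bnorm)
        if (config$weight_decay > 0) {
          for (nm in decay_on) {
            bl$grads[[nm]] <- bl$grads[[nm]] +
              config$weight_decay * params[[nm]]
          }
        }
        up <- adam_step(params, bl$grads, state, config$learning_rate)
        params <- up$params; state <- up$state
        ep_loss <- ep_loss + bl$loss * bnorm
        ep_norm <- ep_norm + bnorm
      }
      fwd <- forward_model(params, va$X)
      eps <- 1e-7
      p <- pmin(pmax(fwd$yhat, eps), 1 - eps)
      yb <- ifelse(va$Y == 1L, 1, 0)
      vl <- sum(-(yb * log(p) + (1 - yb) * log(1 - p)) * wt_va) /
        (ncol(va$Y) * va$norm)
      vauc <- roc_auc(fwd$yhat[val_real], va$Y[val_real])
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / ep_norm,
                                     val_loss = vl, val_auc = vauc))
      if (verbose) {
        message(sprintf("member %d epoch %3d  train %.5f  val %.5f  val AUC %.3f",
                        member, ep, ep_loss / ep_norm, vl, vauc))
      }
      crit <- if (config$val_metric == "auc" && !is.na(vauc)) -vauc else vl
      if (crit < best$crit - 1e-9) {
        best <- list(crit = crit, params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    list(params = best$params, hist = hist, best_epoch = best$epoch)
  }

  members <- lapply(seq_len(max(1L, config$n_ensemble %||% 1L)), train_member)
  structure(
    list(params = members[[1]]$params,
         members = lapply(members, `[[`, "params"),
         config = config, schema = schema,
         input_dim = D, lambda = lambda, horizon_k = config$horizon_k,
         history = members[[1]]$hist,
         best_epoch = members[[1]]$best_epoch,
         train_patients = unique(pats)),
    class = "deep_sequence_model"
  )
}

#' Per-visit risk scores for one eye
#'
#' Encodes the eye's dry visits with the model's schema, pads to the model
#' length and runs the network. `predict_risk()` returns the risk at the last
#' real visit (the prediction "now"); `predict_sequence()` returns the risk
#' emitted at every visit, which is what the overall evaluation scores (each
#' observation is one prediction). By causality, the score at visit `t` uses
#' visits `1..t` only.
#'
#' @param model a trained `deep_sequence_model`.
#' @param visits data.frame of the eye's dry visits, time-ordered.
#' @return `predict_risk`: scalar in (0, 1); `predict_sequence`: numeric
#'   vector, one score per (kept) visit. If the eye has more visits than the
#'   model length `l`, only the most recent `l` are scored.
#' @export
predict_sequence <- function(model, visits) {
  stopifnot(inherits(model, "deep_sequence_model"))
  assert_that(nrow(visits) >= 1L, "need at least one visit")
  x <- encode_visits(model$schema, visits)
  p <- pad_sequence(x, rep(0L, nrow(x)), model$config$l)
  X <- array(0, c(1, model$config$l, ncol(x)))
  X[1, , ] <- p$x
  members <- model$members %||% list(model$params)
  r <- rowMeans(matrix(vapply(members, function(pp) {
    forward_model(pp, X)$yhat[1, seq_len(p$n_real)]
  }, numeric(p$n_real)), nrow = p$n_real))
  unname(r)
}

#' @rdname predict_sequence
#' @export
predict_risk <- function(model, visits) {
  r <- predict_sequence(model, visits)
  r[length(r)]
}

#' @export
print.deep_sequence_model <- function(x, ...) {
  cat(sprintf(
    "<deep_sequence_model> horizon %d months | D=%d -> LSTM(%d) -> LSTM(%d) -> sigmoid | %d params | lambda (%.3g, %.3g, %.3g)\n",
    x$horizon_k, x$input_dim, x$config$hidden1, x$config$hidden2,
    n_params(x), x$lambda[1], x$lambda[2], x$lambda[3]
  ))
  if (!is.null(x$history) && nrow(x$history)) {
    cat(sprintf("  trained %d epochs (best val loss %.5f at epoch %d)\n",
                max(x$history$epoch), min(x$history$val_loss), x$best_epoch))
  }
  invisible(x)
}
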