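# Minimal feed-forward / convolutional / recurrent networks with Adam,
# sized for desk-scale EEG window classification. Binary cross-entropy
# throughout; all weight initialization and batching is seed-driven.

sigmoid <- function(z) 1 / (1 + exp(-z))

adam_state <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_update <- function(params, grads, st, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  for (k in names(params)) {
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * grads[[k]]
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * grads[[k]]^2
    mhat <- st$m[[k]] / (1 - b1^st$t)
    vhat <- st$v[[k]] / (1 - b2^st$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

glorot <- function(nin, nout)
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

minibatches <- function(n, batch) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch))
}

# ---- MLP -------------------------------------------------------------------

mlp_init <- function(n_in, hidden) {
  dims <- c(n_in, hidden, 1L)
  params <- list()
  for (l in seq_len(length(dims) - 1L)) {
    params[[paste0("W", l)]] <- glorot(dims[l], dims[l + 1])
    params[[paste0("b", l)]] <- matrix(0, 1, dims[l + 1])
  }
  params
}

mlp_forward <- function(params, X) {
  L <- length(params) / 2L
  acts <- list(X)
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% params[[paste0("W", l)]], 2,
               params[[paste0("b", l)]], "+")
    acts[[l + 1]] <- if (l < L) pmax(z, 0) else sigmoid(z)
  }
  acts
}

mlp_backward <- function(params, acts, y) {
  L <- length(params) / 2L
  n <- nrow(acts[[1]])
  grads <- list()
  delta <- (acts[[L + 1]] - y) / n          # d(BCE)/dz for sigmoid output
  for (l in rev(seq_len(L))) {
    grads[[paste0("W", l)]] <- t(acts[[l]]) %*% delta
    grads[[paste0("b", l)]] <- matrix(colSums(delta), 1)
    if (l > 1) delta <- (delta %*% t(params[[paste0("W", l)]])) *
        (acts[[l]] > 0)
  }
  grads
}

#' Train a multilayer perceptron binary classifier
#'
#' Fully-connected network with ReLU hidden layers (default 16-8-4 neurons)
#' and a sigmoid output, trained with Adam (learning rate 0.001, batch 32)
#' on binary cross-entropy. Optional validation set enables early stopping
#' on validation accuracy.
#'
#' @param X n x p feature matrix.
#' @param y 0/1 numeric labels.
#' @param hidden hidden-layer sizes.
#' @param lr,batch,epochs optimizer settings.
#' @param X_val,y_val optional validation data for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param seed RNG seed for init and batching.
#' @return An `eeg_mlp` model usable with [nn_predict()].
#' @export
mlp_train <- function(X, y, hidden = c(16, 8, 4), lr = 1e-3, batch = 32,
                      epochs = 30, X_val = NULL, y_val = NULL, patience = 3,
                      seed = 1) {
  with_seed(seed, {
    params <- mlp_init(ncol(X), hidden)
    st <- adam_state(params)
    best <- list(params = params, score = -Inf, wait = 0L)
    for (ep in seq_len(epochs)) {
      for (ib in minibatches(nrow(X), batch)) {
        acts <- mlp_forward(params, X[ib, , drop = FALSE])
        grads <- mlp_backward(params, acts, y[ib])
        upd <- adam_update(params, grads, st, lr)
        params <- upd$params; st <- upd$state
      }
      if (!is.null(X_val)) {
        p <- mlp_forward(params, X_val)[[length(params) / 2 + 1]]
        acc <- mean((p > 0.5) == y_val)
        if (acc > best$score) best <- list(params = params, score = acc,
                                           wait = 0L)
        else {
          best$wait <- best$wait + 1L
          if (best$wait >= patience) break
        }
      }
    }
    if (!is.null(X_val) && best$score > -Inf) params <- best$params
    structure(list(params = params, kind = "mlp"), class = "eeg_mlp")
  })
}

#' Predict with a trained network
#'
#' @param model an `eeg_mlp`, `eeg_cnn1d` or `eeg_lstm` model.
#' @param X features in the same shape the model was trained on (matrix for
#'   the MLP, n x time x channels array for CNN/LSTM).
#' @return Numeric vector of class-1 probabilities.
#' @export
nn_predict <- function(model, X) {
  switch(model$kind,
         mlp = as.numeric(mlp_forward(model$params, X)[[
           length(model$params) / 2 + 1]]),
         cnn1d = as.numeric(cnn_forward(model, X, train = FALSE)$p),
         lstm = as.numeric(lstm_forward(model$params, X,
                                        dropout = 0)$p),
         stop("unknown model kind"))
}

# ---- 1D CNN ----------------------------------------------------------------

# im2col for a batch: X (B x T x C), kernel K over time -> (B*P) x (K*C)
im2col <- function(X, K) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; C <- dim(X)[3]
  P <- Tn - K + 1L
  out <- matrix(0, B * P, K * C)
  for (k in seq_len(K)) {
    sl <- matrix(X[, k:(k + P - 1L), , drop = FALSE], B, P * C)
    # reorder to (B*P) x C block for kernel offset k
    m <- matrix(aperm(array(sl, c(B, P, C)), c(1, 2, 3)), B * P, C)
    out[, ((k - 1L) * C + 1L):(k * C)] <- m
  }
  out
}

cnn_init <- function(C, K, filters, P) {
  list(Wc = glorot(K * C, filters), bc = matrix(0, 1, filters),
       gamma = matrix(1, 1, filters), beta = matrix(0, 1, filters),
       Wf = glorot(P * filters, 1), bf = matrix(0, 1, 1))
}

cnn_forward <- function(model, X, train = TRUE, drop_mask = NULL) {
  pr <- model$params
  K <- model$K; F_ <- ncol(pr$Wc)
  B <- dim(X)[1]; P <- dim(X)[2] - K + 1L
  cols <- im2col(X, K)                          # (B*P) x (K*C)
  z <- sweep(cols %*% pr$Wc, 2, pr$bc, "+")     # (B*P) x F
  if (train) {
    mu <- colMeans(z)
    v <- colMeans(sweep(z, 2, mu)^2)
  } else {
    mu <- model$bn_mu; v <- model$bn_var
  }
  zhat <- sweep(sweep(z, 2, mu), 2, sqrt(v + 1e-5), "/")
  zb <- sweep(sweep(zhat, 2, as.numeric(pr$gamma), "*"), 2,
              as.numeric(pr$beta), "+")
  a <- pmax(zb, 0)
  if (train && !is.null(drop_mask)) a <- a * drop_mask
  flat <- matrix(a, B, P * F_)                  # (B*P) x F -> B x (P*F)
  p <- sigmoid(sweep(flat %*% pr$Wf, 2, pr$bf, "+"))
  list(p = p, cols = cols, z = z, zhat = zhat, zb = zb, a = a, flat = flat,
       mu = mu, v = v, B = B, P = P)
}

cnn_backward <- function(model, fw, y, drop_mask) {
  pr <- model$params
  B <- fw$B; P <- fw$P; F_ <- ncol(pr$Wc)
  dlogit <- (fw$p - y) / B                      # B x 1
  gWf <- t(fw$flat) %*% dlogit
  gbf <- matrix(sum(dlogit), 1, 1)
  dflat <- dlogit %*% t(pr$Wf)                  # B x (P*F)
  da <- matrix(dflat, B * P, F_)
  if (!is.null(drop_mask)) da <- da * drop_mask
  dzb <- da * (fw$zb > 0)
  ggamma <- matrix(colSums(dzb * fw$zhat), 1)
  gbeta <- matrix(colSums(dzb), 1)
  dzhat <- sweep(dzb, 2, as.numeric(pr$gamma), "*")
  # batchnorm backward (per feature, over the B*P axis)
  n <- B * P
  sd_ <- sqrt(fw$v + 1e-5)
  dz <- sweep(dzhat, 2, sd_, "/") -
    sweep(matrix(1, n, 1) %*% matrix(colSums(dzhat), 1), 2, n * sd_, "/") -
    sweep(fw$zhat * (matrix(1, n, 1) %*%
                       matrix(colSums(dzhat * fw$zhat), 1)), 2, n * sd_, "/")
  gWc <- t(fw$cols) %*% dz
  gbc <- matrix(colSums(dz), 1)
  list(Wc = gWc, bc = gbc, gamma = ggamma, beta = gbeta, Wf = gWf, bf = gbf)
}

#' Train a 1-D convolutional binary classifier
#'
#' One temporal convolution layer (kernel 5 over the time axis, acting on
#' all channels), batch normalization, ReLU, dropout, and a fully-connected
#' sigmoid output; Adam optimizer. The reference architecture uses 512
#' filters; the default here is a desk-scaled 32 (configurable), which the
#' evaluation properties do not depend on.
#'
#' @param X n x time x channels array.
#' @param y 0/1 labels.
#' @param filters number of convolution filters.
#' @param kernel temporal kernel size.
#' @param dropout dropout probability after the conv block.
#' @param lr,batch,epochs optimizer settings.
#' @param X_val,y_val optional validation set for early stopping.
#' @param patience early-stopping patience (epochs).
#' @param seed RNG seed.
#' @return An `eeg_cnn1d` model usable with [nn_predict()].
#' @export
cnn1d_train <- function(X, y, filters = 32, kernel = 5, dropout = 0.4,
                        lr = 1e-3, batch = 32, epochs = 40, X_val = NULL,
                        y_val = NULL, patience = 8, seed = 1) {
  with_seed(seed, {
    Tn <- dim(X)[2]; C <- dim(X)[3]
    P <- Tn - kernel + 1L
    params <- cnn_init(C, kernel, filters, P)
    st <- adam_state(params)
    model <- list(params = params, kind = "cnn1d", K = kernel,
                  bn_mu = rep(0, filters), bn_var = rep(1, filters))
    best <- list(model = model, score = -Inf, wait = 0L)
    for (ep in seq_len(epochs)) {
      for (ib in minibatches(dim(X)[1], batch)) {
        Xb <- X[ib, , , drop = FALSE]
        mask <- matrix(stats::rbinom(length(ib) * P * filters, 1,
                                     1 - dropout) / (1 - dropout),
                       length(ib) * P, filters)
        fw <- cnn_forward(model, Xb, train = TRUE, drop_mask = mask)
        grads <- cnn_backward(model, fw, y[ib], mask)
        upd <- adam_update(model$params, grads, st, lr)
        model$params <- upd$params; st <- upd$state
        model$bn_mu <- 0.9 * model$bn_mu + 0.1 * fw$mu
        model$bn_var <- 0.9 * model$bn_var + 0.1 * fw$v
      }
      if (!is.null(X_val)) {
        acc <- mean((nn_predict(model, X_val) > 0.5) == y_val)
        if (acc > best$score) best <- list(model = model, score = acc,
                                           wait = 0L)
        else {
          best$wait <- best$wait + 1L
          if (best$wait >= patience) break
        }
      }
    }
    if (!is.null(X_val) && best$score > -Inf) model <- best$model
    class(model) <- "eeg_cnn1d"
    model
  })
}

# ---- LSTM ------------------------------------------------------------------

lstm_init <- function(C, H) {
  list(Wx = glorot(C, 4 * H), Wh = glorot(H, 4 * H),
       b = matrix(rep(c(0, 1, 0, 0), each = H), 1, 4 * H), # forget bias 1
       Wo = glorot(H, 1), bo = matrix(0, 1, 1))
}

lstm_forward <- function(params, X, dropout = 0, drop_mask = NULL) {
  B <- dim(X)[1]; Tn <- dim(X)[2]
  H <- nrow(params$Wh)
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  cache <- vector("list", Tn)
  gi <- 1:H; gf <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H)
  go <- (3 * H + 1):(4 * H)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], B)
    z <- sweep(xt %*% params$Wx + h %*% params$Wh, 2, params$b, "+")
    i <- sigmoid(z[, gi, drop = FALSE]); f <- sigmoid(z[, gf, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE]);    o <- sigmoid(z[, go, drop = FALSE])
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h_prev <- h
    h <- o * tc
    cache[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o, c = cst,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  hd <- if (!is.null(drop_mask)) h * drop_mask else h
  p <- sigmoid(sweep(hd %*% params$Wo, 2, params$bo, "+"))
  list(p = p, h = h, hd = hd, cache = cache, H = H)
}

lstm_backward <- function(params, fw, X, y, drop_mask) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- fw$H
  gi <- 1:H; gf <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H)
  go <- (3 * H + 1):(4 * H)
  dlogit <- (fw$p - y) / B
  gWo <- t(fw$hd) %*% dlogit
  gbo <- matrix(sum(dlogit), 1, 1)
  dh <- dlogit %*% t(params$Wo)
  if (!is.null(drop_mask)) dh <- dh * drop_mask
  dc <- matrix(0, B, H)
  gWx <- params$Wx * 0; gWh <- params$Wh * 0; gb <- params$b * 0
  for (t in rev(seq_len(Tn))) {
    ch <- fw$cache[[t]]
    do_ <- dh * ch$tc * ch$o * (1 - ch$o)
    dc <- dc + dh * ch$o * (1 - ch$tc^2)
    di <- dc * ch$g * ch$i * (1 - ch$i)
    df <- dc * ch$c_prev * ch$f * (1 - ch$f)
    dg <- dc * ch$i * (1 - ch$g^2)
    dz <- cbind(di, df, dg, do_)
    gWx <- gWx + t(ch$xt) %*% dz
    gWh <- gWh + t(ch$h_prev) %*% dz
    gb <- gb + matrix(colSums(dz), 1)
    dh <- dz %*% t(params$Wh)
    dc <- dc * ch$f
  }
  list(Wx = gWx, Wh = gWh, b = gb, Wo = gWo, bo = gbo)
}

#' Train an LSTM binary classifier
#'
#' Single recurrent layer (default 32 units) consuming 32-step sequences of
#' channel vectors, dropout on the final hidden state, and a sigmoid output;
#' Adam optimizer, batch 32, binary cross-entropy, early stopping on
#' validation accuracy.
#'
#' @param X n x time x channels array.
#' @param y 0/1 labels.
#' @param hidden recurrent units.
#' @param dropout dropout probability on the final hidden state.
#' @param lr,batch,epochs optimizer settings.
#' @param X_val,y_val optional validation set for early stopping.
#' @param patience early-stopping patience (epochs).
#' @param seed RNG seed.
#' @return An `eeg_lstm` model usable with [nn_predict()].
#' @export
lstm_train <- function(X, y, hidden = 32, dropout = 0.4, lr = 1e-3,
                       batch = 32, epochs = 40, X_val = NULL, y_val = NULL,
                       patience = 8, seed = 1) {
  with_seed(seed, {
    params <- lstm_init(dim(X)[3], hidden)
    st <- adam_state(params)
    best <- list(params = params, score = -Inf, wait = 0L)
    for (ep in seq_len(epochs)) {
      for (ib in minibatches(dim(X)[1], batch)) {
        Xb <- X[ib, , , drop = FALSE]
        mask <- matrix(stats::rbinom(length(ib) * hidden, 1, 1 - dropout) /
                         (1 - dropout), length(ib), hidden)
        fw <- lstm_forward(params, Xb, drop_mask = mask)
        grads <- lstm_backward(params, fw, Xb, y[ib], mask)
        upd <- adam_update(params, grads, st, lr)
        params <- upd$params; st <- upd$state
      }
      if (!is.null(X_val)) {
        p <- lstm_forward(params, X_val, dropout = 0)$p
        acc <- mean((p > 0.5) == y_val)
        if (acc > best$score) best <- list(params = params, score = acc,
                                           wait = 0L)
        else {
          best$wait <- best$wait + 1L
          if (best$wait >= patience) break
        }
      }
    }
    if (!is.null(X_val) && best$score > -Inf) params <- best$params
    structure(list(params = params, kind = "lstm"), class = "eeg_lstm")
  })
}
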