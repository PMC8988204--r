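# Neural-network layer primitives: parameter initialization, forward pass
# with caches, and hand-derived backward passes. Everything operates on
# row-major batches (n examples x features) of base R matrices; gradients
# are verified against numerical differentiation in the test suite.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

## ---- dense -----------------------------------------------------------

dense_init <- function(d, k) {
  list(W = glorot(d, k), b = matrix(0, 1, k))
}

dense_fwd <- function(X, p, act = c("relu", "linear")) {
  act <- match.arg(act)
  Z <- X %*% p$W
  Z <- sweep(Z, 2, p$b, "+")
  A <- if (act == "relu") pmax(Z, 0) else Z
  list(out = A, cache = list(X = X, Z = Z, act = act))
}

dense_bwd <- function(dA, cache, p) {
  dZ <- if (cache$act == "relu") dA * (cache$Z > 0) else dA
  list(dX = dZ %*% t(p$W),
       grads = list(W = crossprod(cache$X, dZ),
                    b = matrix(colSums(dZ), 1)))
}

## ---- dropout (inverted) ---------------------------------------------

dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = X, cache = NULL))
  }
  mask <- matrix(stats::rbinom(length(X), 1, 1 - rate), nrow(X)) / (1 - rate)
  list(out = X * mask, cache = mask)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

## ---- simple RNN (tanh), scalar input per step, last state ------------

rnn_init <- function(H) {
  list(Wx = glorot(1, H), Wh = glorot(H, H), b = matrix(0, 1, H))
}

rnn_last_fwd <- function(X, p) {
  n <- nrow(X); T_ <- ncol(X); H <- ncol(p$Wx)
  hs <- vector("list", T_)
  h <- matrix(0, n, H)
  bb <- matrix(p$b, n, H, byrow = TRUE)
  for (t in seq_len(T_)) {
    h <- tanh(X[, t, drop = FALSE] %*% p$Wx + h %*% p$Wh + bb)
    hs[[t]] <- h
  }
  list(out = h, cache = list(X = X, hs = hs))
}

rnn_last_bwd <- function(dhT, cache, p) {
  X <- cache$X; hs <- cache$hs
  n <- nrow(X); T_ <- ncol(X); H <- ncol(dhT)
  dWx <- matrix(0, 1, H); dWh <- matrix(0, H, H); db <- matrix(0, 1, H)
  dX <- matrix(0, n, T_)
  dh <- dhT
  for (t in rev(seq_len(T_))) {
    ht <- hs[[t]]
    dz <- dh * (1 - ht * ht)
    hprev <- if (t > 1) hs[[t - 1]] else matrix(0, n, H)
    dWx <- dWx + crossprod(X[, t, drop = FALSE], dz)
    dWh <- dWh + crossprod(hprev, dz)
    db <- db + colSums(dz)
    dX[, t] <- dz %*% t(p$Wx)
    dh <- dz %*% t(p$Wh)
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

## ---- LSTM, scalar input per step -------------------------------------
# Gate order in the 4H blocks: input, forget, cell (candidate), output.
# Forget-gate bias initialized at 1.

lstm_init <- function(H) {
  b <- matrix(0, 1, 4 * H)
  b[1, (H + 1):(2 * H)] <- 1
  list(Wx = glorot(1, 4 * H), Wh = glorot(H, 4 * H), b = b)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_fwd <- function(X, p, return_seq = FALSE) {
  n <- nrow(X); T_ <- ncol(X); H <- ncol(p$Wh) / 4
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  bb <- matrix(p$b, n, 4 * H, byrow = TRUE)
  gates <- vector("list", T_)
  for (t in seq_len(T_)) {
    z <- X[, t, drop = FALSE] %*% p$Wx + h %*% p$Wh + bb
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    gates[[t]] <- list(i = i, f = f, g = g, o = o, c = cc,
                       c_prev = c_prev, tc = tc, h = h)
  }
  out <- if (return_seq) lapply(gates, `[[`, "h") else h
  list(out = out, cache = list(X = X, gates = gates, H = H))
}

# dout: last-state gradient (n x H) or, for sequences, a list of n x H
# gradients (one per step; NULL entries allowed).
lstm_bwd <- function(dout, cache, p) {
  X <- cache$X; gates <- cache$gates; H <- cache$H
  n <- nrow(X); T_ <- ncol(X)
  seq_grad <- is.list(dout)
  dWx <- matrix(0, 1, 4 * H); dWh <- matrix(0, H, 4 * H)
  db <- matrix(0, 1, 4 * H)
  dX <- matrix(0, n, T_)
  dh <- if (seq_grad) matrix(0, n, H) else dout
  dc <- matrix(0, n, H)
  for (t in rev(seq_len(T_))) {
    gt <- gates[[t]]
    if (seq_grad && !is.null(dout[[t]])) dh <- dh + dout[[t]]
    do_ <- dh * gt$tc
    dc <- dc + dh * gt$o * (1 - gt$tc * gt$tc)
    di <- dc * gt$g
    dg <- dc * gt$i
    df <- dc * gt$c_prev
    dc_prev <- dc * gt$f
    dzi <- di * gt$i * (1 - gt$i)
    dzf <- df * gt$f * (1 - gt$f)
    dzg <- dg * (1 - gt$g * gt$g)
    dzo <- do_ * gt$o * (1 - gt$o)
    dz <- cbind(dzi, dzf, dzg, dzo)
    hprev <- if (t > 1) gates[[t - 1]]$h else matrix(0, n, H)
    dWx <- dWx + crossprod(X[, t, drop = FALSE], dz)
    dWh <- dWh + crossprod(hprev, dz)
    db <- db + colSums(dz)
    dX[, t] <- dz %*% t(p$Wx)
    dh <- dz %*% t(p$Wh)
    dc <- dc_prev
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

## ---- 1D convolution (kernel 3, same zero padding) + ReLU + global
##      average pooling over time ---------------------------------------

conv1d_gap_init <- function(filters = 16, kernel = 3) {
  stopifnot(kernel == 3)
  list(W = glorot(kernel, filters), b = matrix(0, 1, filters))
}

conv1d_gap_fwd <- function(X, p) {
  n <- nrow(X); T_ <- ncol(X); K <- ncol(p$W)
  Xm1 <- cbind(0, X[, -T_, drop = FALSE])
  Xp1 <- cbind(X[, -1, drop = FALSE], 0)
  Z <- vector("list", K)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    Zk <- p$W[1, k] * Xm1 + p$W[2, k] * X + p$W[3, k] * Xp1 + p$b[1, k]
    Z[[k]] <- Zk
    out[, k] <- rowMeans(pmax(Zk, 0))
  }
  list(out = out, cache = list(X = X, Xm1 = Xm1, Xp1 = Xp1, Z = Z))
}

conv1d_gap_bwd <- function(dY, cache, p) {
  X <- cache$X; T_ <- ncol(X); n <- nrow(X); K <- ncol(p$W)
  dW <- matrix(0, 3, K); db <- matrix(0, 1, K)
  dX <- matrix(0, n, T_)
  for (k in seq_len(K)) {
    dZk <- (matrix(dY[, k], n, T_) / T_) * (cache$Z[[k]] > 0)
    dW[1, k] <- sum(cache$Xm1 * dZk)
    dW[2, k] <- sum(cache$X * dZk)
    dW[3, k] <- sum(cache$Xp1 * dZk)
    db[1, k] <- sum(dZk)
    dX <- dX + p$W[2, k] * dZk
    dX[, -T_] <- dX[, -T_, drop = FALSE] + p$W[1, k] * dZk[, -1, drop = FALSE]
    dX[, -1] <- dX[, -1, drop = FALSE] + p$W[3, k] * dZk[, -T_, drop = FALSE]
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

## ---- temporal-channel attention block ---------------------------------
# (1) LSTM with C channels returns the full sequence (n x T x C);
# (2) per channel, a dense map over the time axis followed by a softmax
#     along time yields attention weights; (3) the sequence features and
#     attention weights are multiplied elementwise. The flattened product
#     (n x T*C, channel blocks) is the extracted feature; the per-day
#     attention (channel mean) is exposed for importance analysis.

attention_init <- function(T_, C = 5) {
  att <- lapply(seq_len(C), function(c_) {
    list(W = glorot(T_, T_), b = matrix(0, 1, T_))
  })
  list(lstm = lstm_init(C), att = att)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

attention_fwd <- function(X, p) {
  n <- nrow(X); T_ <- ncol(X); C <- ncol(p$lstm$Wh) / 4
  lf <- lstm_fwd(X, p$lstm, return_seq = TRUE)
  # S[[c]]: n x T matrix of channel c over time
  S <- lapply(seq_len(C), function(c_) {
    m <- matrix(0, n, T_)
    for (t in seq_len(T_)) m[, t] <- lf$out[[t]][, c_]
    m
  })
  A <- vector("list", C)
  M <- vector("list", C)
  for (c_ in seq_len(C)) {
    logits <- S[[c_]] %*% p$att[[c_]]$W
    logits <- sweep(logits, 2, p$att[[c_]]$b, "+")
    A[[c_]] <- softmax_rows(logits)
    M[[c_]] <- S[[c_]] * A[[c_]]
  }
  att_mean <- Reduce(`+`, A) / C
  list(out = do.call(cbind, M), attention = att_mean,
       cache = list(lstm = lf$cache, S = S, A = A, C = C, T_ = T_))
}

attention_bwd <- function(dF, cache, p) {
  C <- cache$C; T_ <- cache$T_; n <- nrow(dF)
  grads_att <- vector("list", C)
  dS <- vector("list", C)
  for (c_ in seq_len(C)) {
    dM <- dF[, (c_ - 1) * T_ + seq_len(T_), drop = FALSE]
    A <- cache$A[[c_]]; S <- cache$S[[c_]]
    dA <- dM * S
    dS_c <- dM * A
    # softmax backward, rowwise
    dZ <- A * (dA - rowSums(dA * A))
    grads_att[[c_]] <- list(W = crossprod(S, dZ),
                            b = matrix(colSums(dZ), 1))
    dS[[c_]] <- dS_c + dZ %*% t(p$att[[c_]]$W)
  }
  # route dS back into the LSTM sequence gradient
  dseq <- vector("list", T_)
  for (t in seq_len(T_)) {
    m <- matrix(0, n, C)
    for (c_ in seq_len(C)) m[, c_] <- dS[[c_]][, t]
    dseq[[t]] <- m
  }
  lb <- lstm_bwd(dseq, cache$lstm, p$lstm)
  list(dX = lb$dX, grads = list(lstm = lb$grads, att = grads_att))
}

## ---- parameter tree utilities ----------------------------------------

# Walk a nested list-of-matrices parameter tree, applying f(leaf) and
# keeping the structure.
param_map <- function(p, f) {
  if (is.matrix(p) || is.numeric(p)) return(f(p))
  lapply(p, param_map, f = f)
}

# Elementwise binary combination of two parameter trees.
param_map2 <- function(a, b, f) {
  if (is.matrix(a) || is.numeric(a)) return(f(a, b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- param_map2(a[[i]], b[[i]], f)
  out
}

param_count <- function(p) {
  total <- 0
  param_map(p, function(m) { total <<- total + length(m); m })
  total
}
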