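# Minimal dense / LSTM neural-network primitives with explicit gradients.
# Everything operates on base matrices (rows = batch); no external autodiff.
# Gradients are verified against finite differences in the test suite.

.glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- multilayer perceptron -------------------------------------------------

# sizes: c(input, hidden..., output); relu hidden, configurable output
mlp_new <- function(sizes, out_activation = c("linear", "sigmoid")) {
  out_activation <- match.arg(out_activation)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- .glorot(sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b, sizes = sizes, out = out_activation)
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], "+")
    acts[[l + 1L]] <- if (l < L) pmax(Z, 0)
      else switch(net$out, linear = Z, sigmoid = .sigmoid(Z))
  }
  list(out = acts[[L + 1L]], acts = acts)
}

# dOut: gradient of the loss wrt the network output (same shape as out).
# For a sigmoid output trained with binary cross-entropy pass
# (p - y) / n directly with `from_logits = TRUE` (the sigmoid'
# cancels); otherwise dOut is wrt post-activation values.
mlp_backward <- function(net, cache, dOut, from_logits = FALSE) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- dOut
  if (net$out == "sigmoid" && !from_logits) {
    p <- cache$acts[[L + 1L]]
    delta <- delta * p * (1 - p)
  }
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (cache$acts[[l + 1L]] > 0)
    dW[[l]] <- crossprod(cache$acts[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) delta <- delta %*% t(net$W[[l]])
  }
  dX <- delta %*% t(net$W[[1L]])
  list(W = dW, b = db, dX = dX)
}

# ---- LSTM ------------------------------------------------------------------

# single-layer LSTM; gate order i, f, g, o along the 4H columns
lstm_new <- function(input_dim, hidden_dim) {
  list(Wx = .glorot(input_dim, 4L * hidden_dim),
       Wh = .glorot(hidden_dim, 4L * hidden_dim),
       b = numeric(4L * hidden_dim),
       input_dim = input_dim, hidden_dim = hidden_dim)
}

lstm_zero_state <- function(net, batch) {
  list(h = matrix(0, batch, net$hidden_dim),
       c = matrix(0, batch, net$hidden_dim))
}

# Xs: list over time of (batch x input_dim) matrices
lstm_forward <- function(net, Xs, state = NULL) {
  H <- net$hidden_dim
  batch <- nrow(Xs[[1L]])
  if (is.null(state)) state <- lstm_zero_state(net, batch)
  TT <- length(Xs)
  cache <- vector("list", TT)
  hs <- vector("list", TT)
  h <- state$h; cc <- state$c
  for (t in seq_len(TT)) {
    z <- Xs[[t]] %*% net$Wx + h %*% net$Wh
    z <- sweep(z, 2L, net$b, "+")
    i <- .sigmoid(z[, 1:H, drop = FALSE])
    f <- .sigmoid(z[, H + 1:H, drop = FALSE])
    g <- tanh(z[, 2L * H + 1:H, drop = FALSE])
    o <- .sigmoid(z[, 3L * H + 1:H, drop = FALSE])
    c_new <- f * cc + i * g
    h_new <- o * tanh(c_new)
    cache[[t]] <- list(x = Xs[[t]], h_prev = h, c_prev = cc,
                       i = i, f = f, g = g, o = o, c = c_new)
    h <- h_new; cc <- c_new
    hs[[t]] <- h
  }
  list(hs = hs, state = list(h = h, c = cc), cache = cache)
}

# dHs: list over time of gradients wrt the hidden outputs
lstm_backward <- function(net, cache, dHs) {
  H <- net$hidden_dim
  TT <- length(cache)
  dWx <- net$Wx * 0; dWh <- net$Wh * 0; db <- numeric(4L * H)
  dh_next <- 0 * dHs[[TT]]; dc_next <- dh_next
  dXs <- vector("list", TT)
  for (t in rev(seq_len(TT))) {
    cc <- cache[[t]]
    dh <- dHs[[t]] + dh_next
    tc <- tanh(cc$c)
    do_ <- dh * tc
    dc <- dh * cc$o * (1 - tc^2) + dc_next
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dc_next <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dh_next <- dz %*% t(net$Wh)
    dXs[[t]] <- dz %*% t(net$Wx)
  }
  list(Wx = dWx, Wh = dWh, b = db, dXs = dXs)
}

# ---- parameter-list utilities ----------------------------------------------

# elementwise op over two nested lists with identical structure
.zip2 <- function(a, b, f) {
  if (!is.list(a)) return(f(a, b))
  for (i in seq_along(a)) a[[i]] <- .zip2(a[[i]], b[[i]], f)
  a
}

# apply f(param, grad) to every leaf of the GRADIENT structure; parameter
# containers may hold extra (non-trainable) metadata that is left untouched
.update_params <- function(p, g, f) {
  if (!is.list(g)) return(f(p, g))
  nm <- names(g)
  for (i in seq_along(g)) {
    key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else i
    p[[key]] <- .update_params(p[[key]], g[[i]], f)
  }
  p
}

.param_sumsq <- function(a) {
  if (is.list(a)) return(sum(vapply(a, .param_sumsq, numeric(1))))
  sum(a^2)
}

.clip_grads <- function(grads, clip) {
  if (!is.finite(clip)) return(grads)
  gn <- sqrt(.param_sumsq(grads))
  if (gn > clip) grads <- .zip2(grads, grads, function(g, .) g * (clip / gn))
  grads
}

# global-norm gradient clipping followed by a plain SGD step
sgd_step <- function(params, grads, lr, clip = Inf) {
  grads <- .clip_grads(grads, clip)
  .update_params(params, grads, function(p, g) p - lr * g)
}

# Adam state is initialised lazily from the first gradient's structure
adam_new <- function(...) list(m = NULL, v = NULL, t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = Inf) {
  grads <- .clip_grads(grads, clip)
  if (is.null(state$m)) {
    state$m <- .zip2(grads, grads, function(g, .) g * 0)
    state$v <- state$m
  }
  state$t <- state$t + 1L
  state$m <- .zip2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .zip2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- .zip2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(params = .update_params(params, upd, function(p, u) p - u),
       state = state)
}
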