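# Dense-layer primitives with hand-written backward passes. All activations
# operate on plain matrices; parameters live in nested lists so the optimizer
# can walk them generically. Row layout for encoder tensors is sample-major
# with position fastest: row (b - 1) * L + i holds sample b, position i.

# column-wise broadcast helpers (v has length ncol(X))
bcast_mul <- function(X, v) X * rep(v, each = nrow(X))
bcast_add <- function(X, v) X + rep(v, each = nrow(X))

lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# Xavier/Glorot uniform initialization
init_linear <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# fixed sinusoidal positional encoding, L x d
positional_encoding <- function(L, d) {
  pos <- matrix(0, L, d)
  for (i in seq_len(d)) {
    k <- (i - 1) %/% 2
    angle <- (seq_len(L) - 1) / 10000 ^ (2 * k / d)
    pos[, i] <- if (i %% 2 == 1) sin(angle) else cos(angle)
  }
  pos
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv_sd <- 1 / sqrt(rowMeans(xc ^ 2) + eps)
  xhat <- xc * inv_sd
  list(y = bcast_add(bcast_mul(xhat, g), b), xhat = xhat, inv_sd = inv_sd)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- bcast_mul(dY, g)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
    cache$inv_sd
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

batchnorm_fwd <- function(X, g, b, state, training, momentum = 0.1,
                          eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    xc <- bcast_add(X, -mu)
    v <- colMeans(xc ^ 2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- bcast_add(X, -mu)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- bcast_mul(xc, inv_sd)
  list(y = bcast_add(bcast_mul(xhat, g), b), xhat = xhat, inv_sd = inv_sd,
       state = state)
}

batchnorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- bcast_mul(dY, g)
  n <- nrow(dY)
  dX <- bcast_mul(dxhat - rep(colMeans(dxhat), each = n) -
                    xhat * rep(colMeans(dxhat * xhat), each = n),
                  cache$inv_sd)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# Multi-head self-attention over a batch of fixed-length sequences.
# X is (B * L) x d, sample-major. Per-head scores are built pairwise over the
# L x L position grid so the whole batch is processed with vectorized ops.
attention_fwd <- function(X, p, L, n_heads, head_dim) {
  B <- nrow(X) %/% L
  Q <- bcast_add(X %*% p$Wq, p$bq)
  K <- bcast_add(X %*% p$Wk, p$bk)
  V <- bcast_add(X %*% p$Wv, p$bv)
  O <- matrix(0, nrow(X), ncol(X))
  rows <- lapply(seq_len(L), function(i) seq(i, B * L, by = L))
  scal <- 1 / sqrt(head_dim)
  A_heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * head_dim + seq_len(head_dim)
    Qh <- lapply(rows, function(r) Q[r, cols, drop = FALSE])
    Kh <- lapply(rows, function(r) K[r, cols, drop = FALSE])
    Vh <- lapply(rows, function(r) V[r, cols, drop = FALSE])
    A <- matrix(0, B, L * L)
    for (i in seq_len(L)) {
      S <- matrix(0, B, L)
      for (j in seq_len(L)) S[, j] <- rowSums(Qh[[i]] * Kh[[j]]) * scal
      m <- S[, 1]
      if (L > 1) for (j in 2:L) m <- pmax(m, S[, j])
      E <- exp(S - m)
      Ai <- E / rowSums(E)
      A[, (i - 1L) * L + seq_len(L)] <- Ai
      Oi <- matrix(0, B, head_dim)
      for (j in seq_len(L)) Oi <- Oi + Ai[, j] * Vh[[j]]
      O[rows[[i]], cols] <- Oi
    }
    A_heads[[h]] <- A
  }
  out <- bcast_add(O %*% p$Wo, p$bo)
  list(out = out, cache = list(X = X, Q = Q, K = K, V = V, O = O,
                               A = A_heads, rows = rows, L = L, B = B,
                               n_heads = n_heads, head_dim = head_dim,
                               scal = scal))
}

attention_bwd <- function(dOut, cache, p) {
  X <- cache$X; rows <- cache$rows; L <- cache$L; B <- cache$B
  head_dim <- cache$head_dim; scal <- cache$scal
  dWo <- crossprod(cache$O, dOut)
  dbo <- colSums(dOut)
  dO <- tcrossprod(dOut, p$Wo)
  dQ <- matrix(0, nrow(X), ncol(X))
  dK <- matrix(0, nrow(X), ncol(X))
  dV <- matrix(0, nrow(X), ncol(X))
  for (h in seq_len(cache$n_heads)) {
    cols <- (h - 1L) * head_dim + seq_len(head_dim)
    Qh <- lapply(rows, function(r) cache$Q[r, cols, drop = FALSE])
    Kh <- lapply(rows, function(r) cache$K[r, cols, drop = FALSE])
    Vh <- lapply(rows, function(r) cache$V[r, cols, drop = FALSE])
    A <- cache$A[[h]]
    dVh <- lapply(seq_len(L), function(j) matrix(0, B, head_dim))
    dQh <- lapply(seq_len(L), function(i) matrix(0, B, head_dim))
    dKh <- lapply(seq_len(L), function(j) matrix(0, B, head_dim))
    for (i in seq_len(L)) {
      dOi <- dO[rows[[i]], cols, drop = FALSE]
      ji <- (i - 1L) * L
      Ai <- A[, ji + seq_len(L), drop = FALSE]
      dAi <- matrix(0, B, L)
      for (j in seq_len(L)) {
        dAi[, j] <- rowSums(dOi * Vh[[j]])
        dVh[[j]] <- dVh[[j]] + Ai[, j] * dOi
      }
      dSi <- Ai * (dAi - rowSums(Ai * dAi)) * scal
      for (j in seq_len(L)) {
        dQh[[i]] <- dQh[[i]] + dSi[, j] * Kh[[j]]
        dKh[[j]] <- dKh[[j]] + dSi[, j] * Qh[[i]]
      }
    }
    for (i in seq_len(L)) {
      dQ[rows[[i]], cols] <- dQh[[i]]
      dK[rows[[i]], cols] <- dKh[[i]]
      dV[rows[[i]], cols] <- dVh[[i]]
    }
  }
  list(dX = tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) +
         tcrossprod(dV, p$Wv),
       dWq = crossprod(X, dQ), dbq = colSums(dQ),
       dWk = crossprod(X, dK), dbk = colSums(dK),
       dWv = crossprod(X, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}

# generic SGD step over a nested parameter list; sublists align by name when
# both sides are named, by position otherwise
sgd_update <- function(params, grads, lr) {
  if (is.list(params)) {
    nms <- names(params)
    aligned <- !is.null(nms) && !is.null(names(grads)) && all(nms != "")
    for (i in seq_along(params)) {
      g <- if (aligned) grads[[nms[i]]] else grads[[i]]
      params[[i]] <- sgd_update(params[[i]], g, lr)
    }
    return(params)
  }
  params - lr * grads
}
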