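# Minimal neural-network core: linear / layer-norm / softmax-attention
# primitives with hand-derived gradients, plus Adam. Everything operates on
# dense base-R matrices (rows = batch*positions, cols = features) so the
# heavy lifting is BLAS GEMMs. No ML framework is available in this
# environment, and the package deliberately has no compiled dependencies.

init_mat <- function(nr, nc, scale = sqrt(2 / (nr + nc))) {
  matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
}

linear_fwd <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- sweep(Y, 2L, b, `+`)
  Y
}

# returns list(dX, dW, db)
linear_bwd <- function(dY, X, W, has_bias = TRUE) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY),
       db = if (has_bias) colSums(dY) else NULL)
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- Xc * inv
  Y <- sweep(xhat, 2L, g, `*`)
  Y <- sweep(Y, 2L, b, `+`)
  list(Y = Y, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2L, g, `*`)
  m <- ncol(xhat)
  dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

relu_fwd <- function(X) {
  X[X < 0] <- 0
  X
}

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  m[!is.finite(m)] <- 0  # fully masked rows
  E <- exp(S - m)
  E[!is.finite(E)] <- 0
  rs <- rowSums(E)
  rs[rs == 0] <- 1
  E / rs
}

# Multi-head scaled dot-product attention over a padded batch.
# Xq: (B*Lq x d), Xkv: (B*Lk x d); mask_k: (B x Lk) TRUE for real tokens;
# causal applies only when Lq == Lk. Weight list p: Wq, Wk, Wv, Wo.
attention_fwd <- function(Xq, Xkv, p, B, Lq, Lk, mask_k, causal = FALSE) {
  d <- ncol(Xq); H <- attr(p, "n_heads"); dk <- d %/% H
  Q <- Xq %*% p$Wq; K <- Xkv %*% p$Wk; V <- Xkv %*% p$Wv
  O <- matrix(0, nrow(Xq), d)
  A_list <- vector("list", B * H)
  scale <- 1 / sqrt(dk)
  for (b in seq_len(B)) {
    rq <- ((b - 1L) * Lq + 1L):(b * Lq)
    rk <- ((b - 1L) * Lk + 1L):(b * Lk)
    keymask <- mask_k[b, ]
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Qb <- Q[rq, cols, drop = FALSE]
      Kb <- K[rk, cols, drop = FALSE]
      S <- tcrossprod(Qb, Kb) * scale
      S[, !keymask] <- -Inf
      if (causal && Lq == Lk) S[upper.tri(S)] <- -Inf
      A <- softmax_rows(S)
      A_list[[(b - 1L) * H + h]] <- A
      O[rq, cols] <- A %*% V[rk, cols, drop = FALSE]
    }
  }
  list(Y = O %*% p$Wo, Q = Q, K = K, V = V, O = O, A = A_list,
       B = B, Lq = Lq, Lk = Lk, H = H, dk = dk, scale = scale)
}

# returns list(dXq, dXkv, dWq, dWk, dWv, dWo)
attention_bwd <- function(dY, cache, Xq, Xkv, p) {
  B <- cache$B; Lq <- cache$Lq; Lk <- cache$Lk
  H <- cache$H; dk <- cache$dk; scale <- cache$scale
  dWo <- crossprod(cache$O, dY)
  dO <- dY %*% t(p$Wo)
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (b in seq_len(B)) {
    rq <- ((b - 1L) * Lq + 1L):(b * Lq)
    rk <- ((b - 1L) * Lk + 1L):(b * Lk)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cache$A[[(b - 1L) * H + h]]
      dOb <- dO[rq, cols, drop = FALSE]
      Vb <- cache$V[rk, cols, drop = FALSE]
      dA <- tcrossprod(dOb, Vb)
      dV[rk, cols] <- dV[rk, cols] + crossprod(A, dOb)
      dS <- A * (dA - rowSums(dA * A))
      Qb <- cache$Q[rq, cols, drop = FALSE]
      Kb <- cache$K[rk, cols, drop = FALSE]
      dQ[rq, cols] <- (dS %*% Kb) * scale
      dK[rk, cols] <- dK[rk, cols] + crossprod(dS, Qb) * scale
    }
  }
  list(dXq = dQ %*% t(p$Wq),
       dXkv = dK %*% t(p$Wk) + dV %*% t(p$Wv),
       dWq = crossprod(Xq, dQ), dWk = crossprod(Xkv, dK),
       dWv = crossprod(Xkv, dV), dWo = dWo)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (!is.finite(gnorm)) stop("non-finite gradient norm", call. = FALSE)
  scale <- if (clip > 0 && gnorm > clip) clip / gnorm else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
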