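# Compact neural-network core: BLAS-backed convolutions via im2col, spatial
# and temporal attention, and Adam. Every backward pass is analytic and is
# verified against central finite differences in the test suite.

.im2col_cache <- new.env(parent = emptyenv())

# Evaluate expr with a temporarily seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# --- im2col index tables --------------------------------------------------

# 2D patch index table for kernel k x k, 'same' zero padding. Returns linear
# indices into the zero-padded (H+2p) x (W+2p) canvas; column-major, offset
# (di, dj) varying with di fastest.
idx_conv2d <- function(H, W, k) {
  key <- paste("c2", H, W, k)
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  i <- rep(seq_len(H), times = W)          # output pixel rows (col-major)
  j <- rep(seq_len(W), each = H)
  off <- expand.grid(di = seq_len(k) - 1L, dj = seq_len(k) - 1L)
  idx <- matrix(0L, H * W, k * k)
  for (q in seq_len(k * k)) {
    pi <- i + off$di[q]; pj <- j + off$dj[q]   # already includes +p shift - p
    idx[, q] <- (pj - 1L) * Hp + pi
  }
  out <- list(idx = idx, Hp = Hp, Wp = Wp, p = p)
  .im2col_cache[[key]] <- out
  out
}

# 1D patch index table for kernel k with replicate (edge) padding: indices
# clamp into 1..T so no explicit canvas is needed and a constant sequence
# maps to a constant convolution output.
idx_conv1d <- function(T_, k) {
  key <- paste("c1", T_, k)
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  t0 <- seq_len(T_)
  idx <- matrix(0L, T_, k)
  for (q in seq_len(k)) idx[, q] <- pmin(pmax(t0 + (q - 1L) - p, 1L), T_)
  .im2col_cache[[key]] <- idx
  idx
}

# Gather canvas rows into an (n_out x k*C) patch matrix.
im2col_gather <- function(canvas_flat, idx) {
  cols <- canvas_flat[as.vector(idx), , drop = FALSE]
  dim(cols) <- c(nrow(idx), ncol(idx) * ncol(canvas_flat))
  cols
}

# Scatter-add patch gradients back onto the canvas (transpose of gather).
im2col_scatter <- function(dcols, idx, n_canvas) {
  C <- ncol(dcols) / ncol(idx)
  dim(dcols) <- c(nrow(idx) * ncol(idx), C)
  acc <- rowsum(dcols, group = as.vector(idx))
  out <- matrix(0, n_canvas, C)
  out[as.integer(rownames(acc)), ] <- acc
  out
}

# --- 2D convolution (same padding, stride 1) ------------------------------

conv2d_fwd <- function(x, Wmat, b, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  tab <- idx_conv2d(H, W, k)
  xp <- array(0, c(tab$Hp, tab$Wp, C))
  xp[tab$p + seq_len(H), tab$p + seq_len(W), ] <- x
  dim(xp) <- c(tab$Hp * tab$Wp, C)
  cols <- im2col_gather(xp, tab$idx)
  y <- cols %*% Wmat
  y <- sweep(y, 2, b, "+")
  Cout <- ncol(Wmat)
  dim(y) <- c(H, W, Cout)
  list(y = y, cols = cols, dims = c(H, W, C), k = k)
}

conv2d_bwd <- function(dy, cache, Wmat) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]
  tab <- idx_conv2d(H, W, cache$k)
  Cout <- ncol(Wmat)
  dim(dy) <- c(H * W, Cout)
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dpad <- im2col_scatter(dy %*% t(Wmat), tab$idx, tab$Hp * tab$Wp)
  dim(dpad) <- c(tab$Hp, tab$Wp, C)
  dx <- dpad[tab$p + seq_len(H), tab$p + seq_len(W), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# --- 1D convolution over time (replicate padding, stride 1) ---------------

conv1d_fwd <- function(x, Wmat, b, k) {
  T_ <- nrow(x)
  idx <- idx_conv1d(T_, k)
  cols <- im2col_gather(x, idx)
  y <- sweep(cols %*% Wmat, 2, b, "+")
  list(y = y, cols = cols, T_ = T_, C = ncol(x), k = k)
}

conv1d_bwd <- function(dy, cache, Wmat) {
  idx <- idx_conv1d(cache$T_, cache$k)
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dx <- im2col_scatter(dy %*% t(Wmat), idx, cache$T_)
  list(dx = dx, dW = dW, db = db)
}

# --- pointwise / pooling ---------------------------------------------------

relu_fwd <- function(x) {
  m <- x > 0
  list(y = x * m, mask = m)
}
relu_bwd <- function(dy, cache) dy * cache$mask

# 2x2 max pooling, stride 2 (H, W even). Quadrant q in 1..4 encodes the
# (row offset, col offset) of the argmax within each window.
maxpool2_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  q1 <- x[ro, co, , drop = FALSE]; q2 <- x[re, co, , drop = FALSE]
  q3 <- x[ro, ce, , drop = FALSE]; q4 <- x[re, ce, , drop = FALSE]
  A <- cbind(as.vector(q1), as.vector(q2), as.vector(q3), as.vector(q4))
  arg <- max.col(A, ties.method = "first")
  y <- A[cbind(seq_len(nrow(A)), arg)]
  dim(y) <- c(H %/% 2L, W %/% 2L, C)
  list(y = y, arg = arg, dims = d)
}

maxpool2_bwd <- function(dy, cache) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]
  hh <- H %/% 2L; ww <- W %/% 2L
  dyv <- as.vector(dy)
  dx <- array(0, d)
  offs <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  for (q in 1:4) {
    sub <- numeric(hh * ww * C)
    sel <- cache$arg == q
    sub[sel] <- dyv[sel]
    dim(sub) <- c(hh, ww, C)
    dx[seq(offs[[q]][1], H, 2L), seq(offs[[q]][2], W, 2L), ] <- sub
  }
  dx
}

# Nearest-neighbour 2x upsampling.
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}
upsample2_bwd <- function(dy) {
  d <- dim(dy); H <- d[1]; W <- d[2]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  dy[ro, co, , drop = FALSE] + dy[re, co, , drop = FALSE] +
    dy[ro, ce, , drop = FALSE] + dy[re, ce, , drop = FALSE]
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Backward through a row-wise softmax: dz = A * (dA - rowSums(A * dA)).
softmax_rows_bwd <- function(dA, A) A * (dA - rowSums(A * dA))

# --- scaled dot-product attention -----------------------------------------

# Single-head attention with queries from Xq and keys/values from Xkv, plus
# a residual connection on Xkv: Y = Xkv + softmax(Q K'/sqrt(da)) V Wo.
# Self-attention is the Xq == Xkv case (caller passes the same matrix and
# adds the dXq/dXkv contributions).
attn_fwd <- function(Xq, Xkv, p) {
  da <- ncol(p$Wq)
  Q <- Xq %*% p$Wq
  K <- Xkv %*% p$Wk
  V <- Xkv %*% p$Wv
  A <- softmax_rows(Q %*% t(K) / sqrt(da))
  Hd <- A %*% V
  Y <- Xkv + Hd %*% p$Wo
  list(y = Y, Q = Q, K = K, V = V, A = A, Hd = Hd, Xq = Xq, Xkv = Xkv)
}

attn_bwd <- function(dY, cache, p) {
  da <- ncol(p$Wq)
  dWo <- crossprod(cache$Hd, dY)
  dHd <- dY %*% t(p$Wo)
  dA <- dHd %*% t(cache$V)
  dV <- crossprod(cache$A, dHd)
  dS <- softmax_rows_bwd(dA, cache$A)
  dQ <- dS %*% cache$K / sqrt(da)
  dK <- crossprod(dS, cache$Q) / sqrt(da)
  dXq <- dQ %*% t(p$Wq)
  dXkv <- dY + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dXq = dXq, dXkv = dXkv,
       dWq = crossprod(cache$Xq, dQ),
       dWk = crossprod(cache$Xkv, dK),
       dWv = crossprod(cache$Xkv, dV),
       dWo = dWo)
}

attn_init <- function(d, da) {
  list(Wq = he_init(d, da, d), Wk = he_init(d, da, d),
       Wv = he_init(d, da, d), Wo = he_init(da, d, da))
}

# --- cross-entropy head ----------------------------------------------------

# Mean cross-entropy of logits (n x K) against integer labels, with gradient
# in the logits. Weight 0 rows are excluded (used for padded frames).
softmax_ce <- function(logits, labels, weight = NULL) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  if (is.null(weight)) weight <- rep(1, n)
  sel <- cbind(seq_len(n), as.integer(labels))
  wsum <- sum(weight)
  loss <- -sum(weight * log(pmax(P[sel], 1e-12))) / wsum
  dz <- P
  dz[sel] <- dz[sel] - 1
  dz <- dz * (weight / wsum)
  list(loss = loss, dz = dz, P = P)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    if (weight_decay > 0) {
      params[[nm]] <- params[[nm]] - lr * weight_decay * params[[nm]]
    }
  }
  list(params = params, state = state)
}

# Elementwise accumulation of two grad lists sharing names.
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
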