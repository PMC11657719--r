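# Minimal neural-network engine (internal).
#
# Everything runs on plain double-precision matrices through BLAS.
# Batches are stored column-wise: a feature map with ch channels on an
# s x s grid is a (s*s*ch) x B matrix whose rows are ordered spatial-first
# (column-major within a channel), channels slowest. Convolutions are
# im2col gathers followed by a single GEMM; the gather/scatter index
# tables are precomputed once per geometry.

# ---- convolution geometry ---------------------------------------------------

.conv_geom <- function(in_side, in_ch, out_ch, kernel, stride, pad) {
  out_side <- (in_side + 2L * pad - kernel) %/% stride + 1L
  if (out_side < 1L) stop("convolution collapses the spatial dimension")
  patch <- in_ch * kernel * kernel
  npos <- out_side * out_side
  pr <- expand.grid(k1 = 0:(kernel - 1L), k2 = 0:(kernel - 1L),
                    ch = 0:(in_ch - 1L))
  po <- expand.grid(o1 = 0:(out_side - 1L), o2 = 0:(out_side - 1L))
  x1 <- outer(pr$k1, po$o1 * stride - pad, "+")     # patch x npos
  x2 <- outer(pr$k2, po$o2 * stride - pad, "+")
  valid <- x1 >= 0L & x1 < in_side & x2 >= 0L & x2 < in_side
  lin <- x2 * in_side + x1 + pr$ch * (in_side * in_side) + 1L
  idx <- matrix(as.integer(ifelse(valid, lin, 0L)), patch, npos)
  list(in_side = in_side, in_ch = in_ch, out_ch = out_ch,
       out_side = out_side, patch = patch, npos = npos,
       in_len = in_side * in_side * in_ch, idx = idx)
}

.conv_fwd <- function(X, W, b, gm) {
  .conv_fwd_cpp(X, W, b, gm$idx)
}

# Xin is the cached layer input; the im2col expansion is recomputed from
# it rather than cached (it is the largest object in the whole loop).
.conv_bwd <- function(dY, W, Xin, gm, need_dx = TRUE) {
  .conv_bwd_cpp(dY, W, Xin, gm$idx, need_dx)
}

# ---- batch normalization ----------------------------------------------------
# Per-channel statistics over batch and spatial positions (population form).

.bn_fwd <- function(X, gamma, beta, npos, ch, run_mean, run_var,
                    train, momentum = 0.1, eps = 1e-5) {
  .bn_fwd_cpp(X, gamma, beta, npos, ch, run_mean, run_var,
              train, momentum, eps)
}

.bn_bwd <- function(dY, cache, gamma, npos, ch) {
  .bn_bwd_cpp(dY, cache$xhat, as.vector(cache$inv_sd), gamma, npos, ch)
}

# ---- 2x2 max pooling (stride 2, trailing row/col dropped when odd) ----------

.pool_geom <- function(in_side, ch) {
  out_side <- in_side %/% 2L
  po <- expand.grid(o1 = 0:(out_side - 1L), o2 = 0:(out_side - 1L),
                    c = 0:(ch - 1L))
  base <- po$c * (in_side * in_side)
  K <- cbind(base + (2L * po$o2) * in_side + 2L * po$o1 + 1L,
             base + (2L * po$o2) * in_side + 2L * po$o1 + 2L,
             base + (2L * po$o2 + 1L) * in_side + 2L * po$o1 + 1L,
             base + (2L * po$o2 + 1L) * in_side + 2L * po$o1 + 2L)
  list(out_side = out_side, out_len = nrow(K), in_len = in_side^2 * ch, K = K)
}

.pool_fwd <- function(X, pg) {
  A1 <- X[pg$K[, 1L], , drop = FALSE]
  A2 <- X[pg$K[, 2L], , drop = FALSE]
  A3 <- X[pg$K[, 3L], , drop = FALSE]
  A4 <- X[pg$K[, 4L], , drop = FALSE]
  Y <- pmax(A1, A2, A3, A4)
  amax <- 4L - (A1 == Y) * 3L - (A1 != Y & A2 == Y) * 2L -
    (A1 != Y & A2 != Y & A3 == Y) * 1L       # first max wins (deterministic)
  list(Y = Y, amax = amax)
}

.pool_bwd <- function(dY, cache, pg) {
  B <- ncol(dY)
  chosen <- pg$K[cbind(rep(seq_len(pg$out_len), B), as.vector(cache$amax))]
  lin <- chosen + rep(seq_len(B) - 1L, each = pg$out_len) * pg$in_len
  dX <- matrix(0, pg$in_len, B)
  dX[lin] <- dY               # pool windows are disjoint: no accumulation
  dX
}

# ---- misc layers ------------------------------------------------------------

.relu_fwd <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}

.softmax_cols <- function(L) {
  C <- nrow(L); B <- ncol(L)
  mx <- L[cbind(max.col(t(L), ties.method = "first"), seq_len(B))]
  E <- exp(L - rep(mx, each = C))
  E / rep(colSums(E), each = C)
}

.l2norm_cols <- function(V, eps = 1e-12) {
  nv <- pmax(sqrt(colSums(V * V)), eps)
  list(Z = V * rep(1 / nv, each = nrow(V)), nv = nv)
}

.l2norm_cols_bwd <- function(dZ, Z, nv) {
  d <- nrow(Z)
  (dZ - Z * rep(colSums(Z * dZ), each = d)) * rep(1 / nv, each = d)
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# Updates params and the moment estimates in place (they are owned
# exclusively by the training loop); returns the state for its counter.
.adam_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  .adam_step_cpp(params, grads, state$m, state$v, state$t,
                 lr, weight_decay, beta1, beta2, eps)
  state
}
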