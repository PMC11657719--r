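# The convolutional backbone and the two contrastive heads.
#
# Backbone (single convolutional block):
#   conv(1 -> c1, kernel 7, stride 2, pad 1) -> ReLU -> batch norm
#   conv(c1 -> c2, kernel 7, stride 2, pad 1) -> ReLU -> batch norm
#   max pool (2x2) -> flatten -> linear -> d-dimensional embedding
# The ReLU-then-batch-norm ordering is deliberate (it mirrors the block
# this architecture is modelled on) even though batch-norm-first is the
# more common convention.
#
# Instance head g_I: linear(d -> d) -> ReLU -> linear(d -> 128), outputs
# scaled to unit Euclidean norm so cosine similarity is a plain dot
# product in the contrastive loss.
# Cluster head g_C: linear(d -> d) -> ReLU -> linear(d -> C) -> softmax,
# producing a probability vector over the C clusters per sample.

#' Network architecture configuration
#'
#' The kernel size (7), stride (2), padding (1) and pool size (2) of the
#' convolutional block are fixed architecture constants. Channel widths,
#' embedding dimension and instance-head dimension are configurable; the
#' defaults (c1 = 8, c2 = 16, d = 512) are deliberately small: FCGR
#' clustering datasets hold hundreds to a few thousand images, and a
#' compact backbone both avoids overfitting and keeps CPU training fast.
#'
#' @param clusters Number of clusters C (output dimension of the cluster
#'   head); at least 2.
#' @param k FCGR resolution; the input image is 2^k x 2^k. Default 6.
#' @param channels Integer vector `c(c1, c2)` of convolution channel widths.
#' @param embedding_dim Backbone output dimension d.
#' @param instance_dim Output dimension of the instance head (default 128).
#' @return An object of class `network_config` including the derived
#'   spatial dimensions of every stage.
#' @examples
#' network_config(clusters = 3)$flat_len  # 36 * c2 for k = 6
#' @export
network_config <- function(clusters, k = 6L, channels = c(8L, 16L),
                           embedding_dim = 512L, instance_dim = 128L) {
  clusters <- as.integer(clusters)
  k <- as.integer(k)
  channels <- as.integer(channels)
  if (clusters < 2L) stop("clusters must be at least 2")
  if (k < 1L) stop("k must be a positive integer")
  if (length(channels) != 2L || any(channels < 1L))
    stop("channels must be two positive integers")
  if (embedding_dim < 1L || instance_dim < 1L)
    stop("embedding_dim and instance_dim must be positive")
  side <- as.integer(2^k)
  s1 <- (side + 2L - 7L) %/% 2L + 1L
  if (s1 < 1L) stop("input too small for the convolutional block (k >= 5 needed)")
  s2 <- (s1 + 2L - 7L) %/% 2L + 1L
  if (s2 < 2L) stop("input too small for the convolutional block (k >= 5 needed)")
  sp <- s2 %/% 2L
  structure(list(clusters = clusters, k = k, side = side,
                 channels = channels,
                 kernel = 7L, stride = 2L, pad = 1L, pool = 2L,
                 conv1_side = s1, conv2_side = s2, pool_side = sp,
                 flat_len = sp * sp * channels[[2L]],
                 embedding_dim = as.integer(embedding_dim),
                 instance_dim = as.integer(instance_dim)),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(paste0("network config: %dx%d input (k=%d) -> conv[%d]@%d -> ",
                     "conv[%d]@%d -> pool@%d -> %d -> embed %d; ",
                     "instance head %d, cluster head %d\n"),
              x$side, x$side, x$k, x$channels[1], x$conv1_side,
              x$channels[2], x$conv2_side, x$pool_side, x$flat_len,
              x$embedding_dim, x$instance_dim, x$clusters))
  invisible(x)
}

# Fan-in-bounded uniform initialization (U(+/- 1/sqrt(fan_in)) for both
# weights and biases) from the model's seed. Keeping the initial logits
# small matters here: an over-confident random cluster head starts close
# to a collapsed assignment, which the low learning rate cannot undo
# within the fixed epoch budget.
.init_network <- function(config, seed) {
  set.seed(seed)
  c1 <- config$channels[[1L]]; c2 <- config$channels[[2L]]
  d <- config$embedding_dim; di <- config$instance_dim; C <- config$clusters
  fan <- function(nout, nin) {
    bnd <- 1 / sqrt(nin)
    matrix(stats::runif(nout * nin, -bnd, bnd), nout, nin)
  }
  fanb <- function(nout, nin) stats::runif(nout, -1 / sqrt(nin), 1 / sqrt(nin))
  params <- list(
    c1W = fan(c1, 49L), c1b = fanb(c1, 49L),
    bn1g = rep(1, c1), bn1b = numeric(c1),
    c2W = fan(c2, c1 * 49L), c2b = fanb(c2, c1 * 49L),
    bn2g = rep(1, c2), bn2b = numeric(c2),
    fW = fan(d, config$flat_len), fb = fanb(d, config$flat_len),
    i1W = fan(d, d), i1b = fanb(d, d),
    i2W = fan(di, d), i2b = fanb(di, d),
    g1W = fan(d, d), g1b = fanb(d, d),
    g2W = fan(C, d), g2b = fanb(C, d))
  structure(list(config = config, seed = seed, params = params,
                 run1_mean = numeric(c1), run1_var = rep(1, c1),
                 run2_mean = numeric(c2), run2_var = rep(1, c2),
                 gm1 = .conv_geom(config$side, 1L, c1, 7L, 2L, 1L),
                 gm2 = .conv_geom(config$conv1_side, c1, c2, 7L, 2L, 1L),
                 pg = .pool_geom(config$conv2_side, c2)),
            class = "tcc_network")
}

#' @export
print.tcc_network <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("twin-contrastive network (seed %d, %d parameters)\n",
              x$seed, np))
  print(x$config)
  invisible(x)
}

# Full forward pass. X: (side^2 x B) matrix of normalized FCGRs.
# Returns H (d x B), Z (instance unit vectors, di x B), P (probs, C x B)
# and, in training mode, the caches needed for the backward pass.
.net_forward <- function(net, X, train = FALSE) {
  p <- net$params
  cfg <- net$config
  if (nrow(X) != cfg$side^2)
    stop("input side length does not match the network configuration (",
         "expected ", cfg$side, "x", cfg$side, " images)")
  n1 <- cfg$conv1_side^2; n2 <- cfg$conv2_side^2
  c1 <- cfg$channels[[1L]]; c2 <- cfg$channels[[2L]]

  y1 <- .conv_fwd(X, p$c1W, p$c1b, net$gm1)
  r1 <- .relu_fwd(y1)
  b1 <- .bn_fwd(r1$Y, p$bn1g, p$bn1b, n1, c1,
                net$run1_mean, net$run1_var, train)
  y2 <- .conv_fwd(b1$Y, p$c2W, p$c2b, net$gm2)
  r2 <- .relu_fwd(y2)
  b2 <- .bn_fwd(r2$Y, p$bn2g, p$bn2b, n2, c2,
                net$run2_mean, net$run2_var, train)
  pl <- .pool_fwd(b2$Y, net$pg)
  H <- p$fW %*% pl$Y + p$fb

  u1 <- .relu_fwd(p$i1W %*% H + p$i1b)
  V <- p$i2W %*% u1$Y + p$i2b
  zn <- .l2norm_cols(V)

  u2 <- .relu_fwd(p$g1W %*% H + p$g1b)
  Lg <- p$g2W %*% u2$Y + p$g2b
  P <- .softmax_cols(Lg)

  out <- list(H = H, Z = zn$Z, P = P)
  if (train) {
    out$cache <- list(X = X, r1 = r1$mask, b1 = b1,
                      r2 = r2$mask, b2 = b2, pl = pl,
                      pooled = pl$Y, u1 = u1, u2 = u2, zn = zn)
  }
  out
}

# Backward pass from head-space gradients dZ (on the unit instance
# vectors) and dP (on the cluster probabilities). Returns the gradient
# list (same names as params) and the updated running BN statistics.
.net_backward <- function(net, fwd, dZ, dP) {
  p <- net$params
  cfg <- net$config
  ch <- fwd$cache
  n1 <- cfg$conv1_side^2; n2 <- cfg$conv2_side^2
  c1 <- cfg$channels[[1L]]; c2 <- cfg$channels[[2L]]
  g <- list()

  # instance head
  dV <- .l2norm_cols_bwd(dZ, fwd$Z, ch$zn$nv)
  g$i2W <- tcrossprod(dV, ch$u1$Y); g$i2b <- rowSums(dV)
  dU1 <- crossprod(p$i2W, dV) * ch$u1$mask
  g$i1W <- tcrossprod(dU1, fwd$H); g$i1b <- rowSums(dU1)
  dH <- crossprod(p$i1W, dU1)

  # cluster head (through the softmax)
  dLg <- fwd$P * (dP - rep(colSums(fwd$P * dP), each = nrow(dP)))
  g$g2W <- tcrossprod(dLg, ch$u2$Y); g$g2b <- rowSums(dLg)
  dU2 <- crossprod(p$g2W, dLg) * ch$u2$mask
  g$g1W <- tcrossprod(dU2, fwd$H); g$g1b <- rowSums(dU2)
  dH <- dH + crossprod(p$g1W, dU2)

  # backbone
  g$fW <- tcrossprod(dH, ch$pooled); g$fb <- rowSums(dH)
  dPool <- crossprod(p$fW, dH)
  dB2 <- .pool_bwd(dPool, ch$pl, net$pg)
  bn2 <- .bn_bwd(dB2, ch$b2, p$bn2g, n2, c2)
  g$bn2g <- bn2$dgamma; g$bn2b <- bn2$dbeta
  dZ2 <- bn2$dX * ch$r2
  cv2 <- .conv_bwd(dZ2, p$c2W, ch$b1$Y, net$gm2, need_dx = TRUE)
  g$c2W <- cv2$dW; g$c2b <- cv2$db
  bn1 <- .bn_bwd(cv2$dX, ch$b1, p$bn1g, n1, c1)
  g$bn1g <- bn1$dgamma; g$bn1b <- bn1$dbeta
  dZ1 <- bn1$dX * ch$r1
  cv1 <- .conv_bwd(dZ1, p$c1W, ch$X, net$gm1, need_dx = FALSE)
  g$c1W <- cv1$dW; g$c1b <- cv1$db

  g[names(p)]
}

#' Backbone forward pass
#'
#' Maps a batch of normalized FCGRs to d-dimensional embeddings. In
#' `"eval"` mode batch normalization uses the running statistics collected
#' during training, so the embedding of a sample does not depend on which
#' other samples share its batch.
#'
#' @param net A `tcc_network` (from a trained model's `$network`, or an
#'   untrained one created internally by [train_single()]).
#' @param batch A list of `normalized_fcgr` objects, or a numeric matrix
#'   with one flattened (column-major) grid per column.
#' @param mode `"eval"` (default) or `"train"`.
#' @return Numeric matrix, one row per sample, `embedding_dim` columns.
#' @export
backbone_forward <- function(net, batch, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  X <- .as_input_matrix(batch, net$config)
  t(.net_forward(net, X, train = (mode == "train"))$H)
}

#' Instance head forward pass
#'
#' Projects backbone embeddings to the instance contrastive space; each
#' output row has unit Euclidean norm (an epsilon floor guards the
#' degenerate all-zero projection).
#'
#' @param net A `tcc_network`.
#' @param embeddings Numeric matrix, one embedding per row.
#' @return Numeric matrix of unit-norm rows, `instance_dim` columns.
#' @export
instance_head_forward <- function(net, embeddings) {
  H <- t(as.matrix(embeddings))
  p <- net$params
  U <- .relu_fwd(p$i1W %*% H + p$i1b)$Y
  t(.l2norm_cols(p$i2W %*% U + p$i2b)$Z)
}

#' Cluster head forward pass
#'
#' Projects backbone embeddings to cluster-membership probabilities; each
#' output row lies on the C-simplex (non-negative, sums to one).
#'
#' @param net A `tcc_network`.
#' @param embeddings Numeric matrix, one embedding per row.
#' @return Assignment matrix, one row per sample, `clusters` columns.
#' @export
cluster_head_forward <- function(net, embeddings) {
  H <- t(as.matrix(embeddings))
  p <- net$params
  U <- .relu_fwd(p$g1W %*% H + p$g1b)$Y
  t(.softmax_cols(p$g2W %*% U + p$g2b))
}

.as_input_matrix <- function(batch, config) {
  if (is.matrix(batch)) {
    if (nrow(batch) != config$side^2)
      stop("input side length does not match the network configuration")
    return(batch)
  }
  if (!is.list(batch) || !all(vapply(batch, inherits, TRUE, "normalized_fcgr")))
    stop("batch must be a matrix or a list of 'normalized_fcgr' objects")
  ks <- vapply(batch, `[[`, 1L, "k")
  if (any(ks != config$k))
    stop("input side length does not match the network configuration")
  vapply(batch, function(b) as.vector(b$grid), numeric(config$side^2))
}
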