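# Twin contrastive losses.
#
# Both losses are normalized-temperature cross-entropies (InfoNCE/NT-Xent)
# over cosine similarities. The instance loss contrasts the 2n augmented
# samples of a batch in the row space of the feature matrix (each sample's
# positive is its partner view, the other 2n-2 samples are negatives). The
# cluster loss applies the same construction in the column space: column j
# of the n x C assignment matrix -- the over-the-batch activation profile
# of cluster j -- is the representation of that cluster, its positive is
# the same cluster's column under the other augmentation view, and an
# entropy regularizer on the batch-mean cluster distribution of each view
# discourages the degenerate solution that dumps every sample into one
# cluster (the regularizer is minimal, -2*log(C), when both marginals are
# uniform).

#' Loss configuration
#'
#' @param alpha Weight of the instance-level term in the combined loss,
#'   in \[0, 1\]. Default 0.7.
#' @param tau_i Instance-level temperature (> 0). Default 0.1; the low
#'   temperature sharpens individual-instance discrimination.
#' @param tau_c Cluster-level temperature (> 0). Default 1.0; the high
#'   temperature favours group-level discrimination.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.7, tau_i = 0.1, tau_c = 1.0) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (tau_i <= 0 || tau_c <= 0) stop("temperatures must be positive")
  structure(list(alpha = alpha, tau_i = tau_i, tau_c = tau_c),
            class = "loss_config")
}

# NT-Xent over the 2v columns of Z (unit columns, d x 2v); column i is
# paired with column i +/- v. Returns the mean per-anchor loss and the
# gradient with respect to the columns of Z.
.ntxent <- function(Z, tau, grad = FALSE) {
  m <- ncol(Z)
  v <- m %/% 2L
  S <- crossprod(Z) / tau
  diag(S) <- -Inf
  pos <- c(seq_len(v) + v, seq_len(v))         # partner of column i
  rm <- apply(S, 1L, max)
  E <- exp(S - rm)                             # rows: anchors
  den <- rowSums(E)
  loss <- mean(-(S[cbind(seq_len(m), pos)] - rm) + log(den))
  if (!grad) return(list(loss = loss))
  G <- E / den
  G[cbind(seq_len(m), pos)] <- G[cbind(seq_len(m), pos)] - 1
  G <- G / (tau * m)
  G[!is.finite(G)] <- 0
  dZ <- Z %*% (G + t(G))
  list(loss = loss, dZ = dZ)
}

#' Instance-level contrastive loss
#'
#' NT-Xent over the 2n stacked instance projections of a batch: for each
#' anchor, the positive is its partner view of the same original sequence,
#' every other sample in the batch is a negative, similarity is cosine and
#' the per-anchor cross-entropies are averaged over all 2n anchors. When
#' all 2n embeddings coincide the loss equals `log(2n - 1)`.
#'
#' @param z_weak,z_strong Numeric matrices, n x d, row i of each being the
#'   two views of sequence i. Rows are expected unit-norm (the instance
#'   head guarantees this); they are re-normalized defensively.
#' @param tau_i Temperature (> 0).
#' @return Non-negative scalar.
#' @export
instance_loss <- function(z_weak, z_strong, tau_i = 0.1) {
  z_weak <- as.matrix(z_weak); z_strong <- as.matrix(z_strong)
  if (!all(dim(z_weak) == dim(z_strong))) stop("view shapes differ")
  if (nrow(z_weak) < 2L) stop("instance loss needs at least 2 sequences")
  if (tau_i <= 0) stop("tau_i must be positive")
  Z <- .l2norm_cols(t(rbind(z_weak, z_strong)))$Z
  .ntxent(Z, tau_i)$loss
}

#' Cluster-level contrastive loss
#'
#' Treats column j of each view's n x C assignment matrix as the
#' representation of cluster j, L2-normalizes the 2C columns and applies
#' NT-Xent across them (positive = the same cluster under the other view,
#' temperature `tau_c`), then adds the negative entropy of the batch-mean
#' cluster distribution of each view. The entropy term attains its minimum
#' `-2 * log(C)` when both cluster marginals are uniform, penalizing
#' collapsed assignments.
#'
#' @param p_weak,p_strong Assignment matrices (n x C, rows on the simplex).
#' @param tau_c Temperature (> 0).
#' @return Scalar (contrastive term plus entropy term).
#' @export
cluster_loss <- function(p_weak, p_strong, tau_c = 1.0) {
  p_weak <- as.matrix(p_weak); p_strong <- as.matrix(p_strong)
  .check_assignment(p_weak); .check_assignment(p_strong)
  if (!all(dim(p_weak) == dim(p_strong))) stop("view shapes differ")
  if (nrow(p_weak) < 2L) stop("cluster loss needs at least 2 sequences")
  if (ncol(p_weak) < 2L) stop("cluster loss needs at least 2 clusters")
  if (tau_c <= 0) stop("tau_c must be positive")
  Q <- .l2norm_cols(cbind(p_weak, p_strong))$Z
  .ntxent(Q, tau_c)$loss + .neg_entropy(p_weak) + .neg_entropy(p_strong)
}

.neg_entropy <- function(P) {
  m <- pmax(colMeans(P), 1e-12)
  sum(m * log(m))
}

.check_assignment <- function(P, tol = 1e-6) {
  if (any(P < -tol) || any(P > 1 + tol) ||
      any(abs(rowSums(P) - 1) > 1e-4))
    stop("assignment matrix rows must be probability vectors")
  invisible(P)
}

#' Combined twin contrastive loss
#'
#' @param l_ins Instance-level loss value.
#' @param l_clu Cluster-level loss value.
#' @param alpha Weight in \[0, 1\]; the combination is
#'   `alpha * l_ins + (1 - alpha) * l_clu`.
#' @return Scalar.
#' @export
twin_loss <- function(l_ins, l_clu, alpha = 0.7) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  alpha * l_ins + (1 - alpha) * l_clu
}

# Training-path losses with gradients. Z: instance projections (di x 2n,
# unit columns, first n weak); P: cluster probabilities (C x 2n).
# Returns loss components and gradients dZ (on unit vectors) and dP (on
# probabilities), already weighted by alpha / (1 - alpha).
.twin_loss_grad <- function(Z, P, cfg) {
  n2 <- ncol(Z)
  n <- n2 %/% 2L
  ins <- .ntxent(Z, cfg$tau_i, grad = TRUE)

  Pw <- P[, seq_len(n), drop = FALSE]
  Ps <- P[, seq_len(n) + n, drop = FALSE]
  Q <- cbind(t(Pw), t(Ps))                     # n x 2C
  qn <- .l2norm_cols(Q)
  clu <- .ntxent(qn$Z, cfg$tau_c, grad = TRUE)
  dQ <- .l2norm_cols_bwd(clu$dZ, qn$Z, qn$nv)
  C <- nrow(P)
  dP <- cbind(t(dQ[, seq_len(C), drop = FALSE]),
              t(dQ[, seq_len(C) + C, drop = FALSE]))
  # entropy regularizer: d/dP[j, i] of sum m log m is (log m_j + 1) / n
  mw <- pmax(rowMeans(Pw), 1e-12)
  ms <- pmax(rowMeans(Ps), 1e-12)
  dP[, seq_len(n)] <- dP[, seq_len(n)] + (log(mw) + 1) / n
  dP[, seq_len(n) + n] <- dP[, seq_len(n) + n] + (log(ms) + 1) / n
  l_clu <- clu$loss + sum(mw * log(mw)) + sum(ms * log(ms))

  list(l_ins = ins$loss, l_clu = l_clu,
       l_train = cfg$alpha * ins$loss + (1 - cfg$alpha) * l_clu,
       dZ = cfg$alpha * ins$dZ, dP = (1 - cfg$alpha) * dP)
}
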