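# Ensemble voting: cluster-index alignment across members, then soft or
# hard majority voting.
#
# Independently initialized models converge to arbitrary permutations of
# the same clustering, so their cluster indices must be reconciled before
# votes can be combined. Member 1 serves as the fixed reference; every
# other member's indices are permuted to maximize hard-assignment
# agreement with it, via optimal assignment on the agreement matrix.

#' Align another member's cluster indices to a reference member
#'
#' Builds the C x C agreement matrix counting sequences hard-assigned to
#' cluster a by the reference and cluster b by the other member, and
#' returns the relabelling of the other member's clusters that maximizes
#' total agreement (Hungarian method). Hard assignments break probability
#' ties towards the lowest cluster index, and the assignment search is
#' deterministic, so tied alignments always resolve the same way.
#'
#' @param other,reference Assignment matrices of identical shape (n x C).
#' @return Integer vector `perm` of length C: the other member's cluster
#'   `j` is relabelled to reference cluster `perm[j]`.
#' @export
align_clusters <- function(other, reference) {
  reference <- as.matrix(reference); other <- as.matrix(other)
  if (!all(dim(reference) == dim(other)))
    stop("assignment matrices must have identical shape")
  C <- ncol(reference)
  ra <- max.col(reference, ties.method = "first")
  oa <- max.col(other, ties.method = "first")
  agree <- matrix(0L, C, C)
  for (j in seq_len(C))
    agree[, j] <- tabulate(ra[oa == j], nbins = C)
  # maximize agreement = minimize negated counts; the solver matches
  # reference cluster a to other cluster ans[a], so the label mapping
  # (other cluster j -> reference cluster perm[j]) is its inverse
  ans <- min_cost_assignment(max(agree) - agree)
  perm <- integer(C)
  perm[ans] <- seq_len(C)
  perm
}

.apply_alignment <- function(P, perm) {
  out <- P
  out[, perm] <- P[, seq_along(perm)]
  out
}

.collect_aligned <- function(predictions) {
  if (length(predictions) == 0L) stop("empty ensemble")
  predictions <- lapply(predictions, as.matrix)
  dims <- vapply(predictions, dim, integer(2L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all ensemble members must share the same n x C shape")
  ref <- predictions[[1L]]
  lapply(predictions, function(P)
    .apply_alignment(P, align_clusters(P, ref)))
}

#' Soft (probability-averaging) majority vote
#'
#' Aligns each member to member 1, averages the aligned probability
#' matrices entrywise and assigns each sequence to the row-wise argmax of
#' the mean (ties to the lowest cluster index). The mean matrix is itself
#' a valid assignment matrix.
#'
#' @param predictions List of assignment matrices (one per ensemble
#'   member, same n x C shape).
#' @return List with `cluster` (integer labels) and `probabilities` (the
#'   aligned mean matrix).
#' @export
soft_vote <- function(predictions) {
  aligned <- .collect_aligned(predictions)
  mean_p <- Reduce(`+`, aligned) / length(aligned)
  list(cluster = max.col(mean_p, ties.method = "first"),
       probabilities = mean_p)
}

#' Hard (modal-label) majority vote
#'
#' Aligns each member to member 1, hard-assigns each member's sequences
#' and takes the most frequent aligned label per sequence; ties break to
#' the lowest cluster index.
#'
#' @inheritParams soft_vote
#' @return List with `cluster` (integer labels) and `probabilities` (the
#'   per-sequence vote shares).
#' @export
hard_vote <- function(predictions) {
  aligned <- .collect_aligned(predictions)
  C <- ncol(aligned[[1L]])
  n <- nrow(aligned[[1L]])
  hard <- vapply(aligned, function(P) max.col(P, ties.method = "first"),
                 integer(n))
  hard <- matrix(hard, nrow = n)
  shares <- t(apply(hard, 1L, tabulate, nbins = C)) / ncol(hard)
  list(cluster = max.col(shares, ties.method = "first"),
       probabilities = shares)
}
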