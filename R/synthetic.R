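# Synthetic labelled DNA cluster benchmarks.
#
# Two generative modes:
#   * ancestor_mutation: each cluster is an i.i.d.-uniform ancestor plus
#     independent per-site substitutions at rate (1 - identity) per
#     member; substitution-only, so "identity" has an exact alignment-free
#     (Hamming) meaning. Length variation comes from drawing each
#     cluster's ancestor length from the configured range. This emulates
#     identity-threshold benchmark families (clusters whose members all
#     sit within a fixed identity of the cluster centre).
#   * markov_signature: each cluster gets its own first-order Markov
#     transition matrix, a convex mix of the uniform matrix and a random
#     stochastic matrix; members are independent chains. This emulates the
#     "genomic signature" premise that taxa differ in short-range k-mer
#     composition.

#' Specification of a synthetic clustered dataset
#'
#' @param mode `"ancestor_mutation"` or `"markov_signature"`.
#' @param clusters Number of clusters (>= 2).
#' @param size Sequences per cluster: a single count, or a `c(min, max)`
#'   range from which each cluster's size is drawn uniformly (emulating
#'   unbalanced benchmarks).
#' @param length_range `c(min, max)` sequence length in bp.
#' @param identity Within-cluster identity in (0, 1\] (ancestor_mutation
#'   mode): expected fraction of positions a member shares with its
#'   cluster ancestor.
#' @param signature_strength s in (0, 1\] (markov_signature mode): the
#'   cluster transition matrix is `(1-s) * uniform + s * random`; s -> 0
#'   makes clusters statistically indistinguishable.
#' @param seed Random seed; generation is fully reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(mode = c("ancestor_mutation", "markov_signature"),
                           clusters = 10L, size = 40L,
                           length_range = c(653L, 2062L),
                           identity = 0.97, signature_strength = 0.5,
                           seed = 1L) {
  mode <- match.arg(mode)
  clusters <- as.integer(clusters)
  size <- as.integer(size)
  length_range <- as.integer(length_range)
  if (clusters < 2L) stop("clusters must be at least 2")
  if (!length(size) %in% 1:2 || any(size < 1L))
    stop("size must be a positive count or c(min, max) range")
  if (length(size) == 2L && size[2L] < size[1L])
    stop("size range must be increasing")
  if (length(length_range) != 2L || length_range[1L] < 1L ||
      length_range[2L] < length_range[1L])
    stop("length_range must be an increasing positive pair")
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
  if (signature_strength <= 0 || signature_strength > 1)
    stop("signature_strength must be in (0, 1]")
  structure(list(mode = mode, clusters = clusters, size = size,
                 length_range = length_range, identity = identity,
                 signature_strength = signature_strength,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  sz <- if (length(x$size) == 1L) x$size else
    paste(x$size[1L], "-", x$size[2L])
  par <- if (x$mode == "ancestor_mutation")
    sprintf("identity %.2f", x$identity) else
    sprintf("signature strength %.2f", x$signature_strength)
  cat(sprintf("synthetic spec: %s, %d clusters x %s seqs, %d-%d bp, %s, seed %d\n",
              x$mode, x$clusters, sz, x$length_range[1L],
              x$length_range[2L], par, x$seed))
  invisible(x)
}

#' Draw a uniform random ancestor sequence
#'
#' Bases are i.i.d. uniform over A, C, G, T, using the current RNG state
#' (seed with `set.seed()` for reproducibility).
#'
#' @param length Sequence length (>= 1).
#' @return A residue string.
#' @export
generate_ancestor <- function(length) {
  length <- as.integer(length)
  if (length < 1L) stop("length must be positive")
  paste(sample(.BASES, length, replace = TRUE), collapse = "")
}

#' Derive a cluster of sequences from an ancestor
#'
#' Each member substitutes every ancestor site independently with
#' probability `1 - identity`, drawing the replacement uniformly from the
#' three alternative bases, so the expected member-to-ancestor Hamming
#' identity equals `identity`. (Two members differ through two independent
#' mutation layers; their expected pairwise identity is
#' `1 - 2q(1 - q/3)` with `q = (1 - identity)`, slightly above
#' `identity^2` because independent hits can coincide.)
#'
#' @param ancestor Residue string (the cluster centre).
#' @param size Number of members.
#' @param identity Within-cluster identity in (0, 1].
#' @return Character vector of `size` residue strings.
#' @export
generate_cluster <- function(ancestor, size, identity) {
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
  size <- as.integer(size)
  if (size < 1L) stop("size must be positive")
  ch <- strsplit(ancestor, "", fixed = TRUE)[[1L]]
  code0 <- match(ch, .BASES) - 1L
  L <- length(ch)
  q <- 1 - identity
  vapply(seq_len(size), function(i) {
    out <- ch
    hit <- which(stats::runif(L) < q)
    if (length(hit)) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      out[hit] <- .BASES[((code0[hit] + shift) %% 4L) + 1L]
    }
    paste(out, collapse = "")
  }, character(1L))
}

#' Generate one cluster of Markov-signature sequences
#'
#' The cluster's first-order transition matrix is
#' `(1 - s) * uniform + s * R` where `R` is a random stochastic matrix
#' drawn from the current RNG stream (each row i.i.d. uniform, row
#' normalized), and every member is an independent chain of length drawn
#' uniformly from `length_range`.
#'
#' @param spec A [synthetic_spec()] (supplies `signature_strength` and
#'   `length_range`).
#' @param size Number of members.
#' @return Character vector of residue strings.
#' @export
generate_signature_cluster <- function(spec, size) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  s <- spec$signature_strength
  R <- matrix(stats::runif(16L), 4L, 4L)
  R <- R / rowSums(R)
  Tm <- (1 - s) / 4 + s * R
  cum <- t(apply(Tm, 1L, cumsum))
  vapply(seq_len(as.integer(size)), function(i) {
    L <- sample.int(spec$length_range[2L] - spec$length_range[1L] + 1L, 1L) +
      spec$length_range[1L] - 1L
    st <- integer(L)
    st[1L] <- sample.int(4L, 1L)
    u <- stats::runif(L)
    if (L > 1L)
      for (t in 2:L)
        st[t] <- findInterval(u[t], cum[st[t - 1L], ]) + 1L
    paste(.BASES[st], collapse = "")
  }, character(1L))
}

#' Generate a labelled synthetic dataset
#'
#' Concatenates the clusters of `spec` into one dataset. Sequence ids are
#' sequential (`seq00001`, ...) and encode nothing about the cluster; the
#' returned label table is the ground truth for post-hoc evaluation.
#' Generation is fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `sequences` (named character vector) and `labels`
#'   (data frame with columns `id`, `label`).
#' @examples
#' d <- generate_dataset(synthetic_spec(clusters = 2, size = 3,
#'                                      length_range = c(100, 120)))
#' table(d$labels$label)
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  set.seed(spec$seed)
  seqs <- character(0)
  labs <- character(0)
  for (cl in seq_len(spec$clusters)) {
    size <- if (length(spec$size) == 1L) spec$size else
      sample.int(spec$size[2L] - spec$size[1L] + 1L, 1L) + spec$size[1L] - 1L
    members <- if (spec$mode == "ancestor_mutation") {
      L <- sample.int(spec$length_range[2L] - spec$length_range[1L] + 1L, 1L) +
        spec$length_range[1L] - 1L
      generate_cluster(generate_ancestor(L), size, spec$identity)
    } else {
      generate_signature_cluster(spec, size)
    }
    seqs <- c(seqs, members)
    labs <- c(labs, rep(sprintf("cluster%02d", cl), size))
  }
  ids <- sprintf("seq%05d", seq_along(seqs))
  names(seqs) <- ids
  list(sequences = seqs,
       labels = data.frame(id = ids, label = labs, stringsAsFactors = FALSE))
}
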