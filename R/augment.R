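# Mimic-sequence generation: weak/strong augmentation pairs.
#
# A positive pair is two augmented copies of the same sequence, produced by
# a weak and a strong transformation from the same family (mutation or
# fragmentation). Augmentations act on the raw DNA, not on the FCGR image:
# image-space transforms such as flips or crops would correspond to drastic
# rearrangements of the underlying sequence, whereas substitutions and
# fragments mirror natural genetic variation.

#' Weak/strong augmentation policy
#'
#' For mutation, `weak`/`strong` are per-site transition rates mu1 < mu2
#' (mu is the transition probability; transversions occur at 0.5*mu, so the
#' total per-site change probability is 1.5*mu which must not exceed 1).
#' For fragmentation, `weak`/`strong` are fragment lengths len1 > len2
#' (the shorter fragment is the stronger distortion). The defaults are the
#' mutation pair mu1 = 1e-4, mu2 = 1e-2.
#'
#' @param kind `"mutation"` or `"fragmentation"`.
#' @param weak Weak-transform parameter (mu1 or len1).
#' @param strong Strong-transform parameter (mu2 or len2).
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(kind = c("mutation", "fragmentation"),
                                weak = if (kind == "mutation") 1e-4 else NULL,
                                strong = if (kind == "mutation") 1e-2 else NULL) {
  kind <- match.arg(kind)
  if (is.null(weak) || is.null(strong))
    stop("weak and strong parameters are required")
  if (kind == "mutation") {
    if (!(weak >= 0 && weak < strong))
      stop("mutation policy requires 0 <= mu1 < mu2")
    if (1.5 * strong > 1)
      stop("mutation policy requires 1.5 * mu2 <= 1")
  } else {
    weak <- as.integer(weak); strong <- as.integer(strong)
    if (!(strong >= 1 && strong < weak))
      stop("fragmentation policy requires 1 <= len2 < len1")
  }
  structure(list(kind = kind, weak = weak, strong = strong),
            class = "augmentation_policy")
}

#' @export
print.augmentation_policy <- function(x, ...) {
  cat(sprintf("augmentation policy: %s (weak = %g, strong = %g)\n",
              x$kind, x$weak, x$strong))
  invisible(x)
}

#' Apply random substitution mutations to a sequence
#'
#' Each position independently undergoes a transition (A<->G, C<->T) with
#' probability `mu` and a transversion with probability `0.5 * mu`; the two
#' possible transversion targets are chosen with equal probability
#' (0.25*mu each). This 2:1 transition:transversion weighting reflects the
#' empirical excess of transitions over transversions in real genomes.
#' Positions holding non-ACGT characters are left untouched; length is
#' always preserved. Randomness comes from the R RNG, so results are
#' reproducible under `set.seed()`.
#'
#' @param sequence A single residue string.
#' @param mu Per-site transition probability; requires `1.5 * mu <= 1`.
#' @return The mutated residue string (names preserved).
#' @export
mutate_dna <- function(sequence, mu) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  if (mu < 0 || 1.5 * mu > 1)
    stop("mu must satisfy 0 <= 1.5 * mu <= 1")
  if (mu == 0) return(sequence)
  out <- .mutate_cpp(sequence, mu)
  names(out) <- names(sequence)
  out
}

#' Extract a random contiguous fragment
#'
#' The start position is drawn uniformly over all valid offsets, so every
#' length-`len` window of the input is equally likely.
#'
#' @param sequence A single residue string.
#' @param len Fragment length, `1 <= len <= nchar(sequence)`.
#' @return The fragment (names preserved).
#' @export
fragment_dna <- function(sequence, len) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  n <- nchar(sequence)
  len <- as.integer(len)
  if (len <= 0L || len > n)
    stop("fragment length must be in 1..", n)
  start <- sample.int(n - len + 1L, 1L)
  out <- substr(sequence, start, start + len - 1L)
  names(out) <- names(sequence)
  out
}

#' Generate a weak/strong positive pair of mimic sequences
#'
#' Applies the policy's weak transform and strong transform to the same
#' input, drawing fresh randomness for each element. During training a new
#' pair is generated every epoch rather than fixed once per sequence, which
#' increases the effective diversity of positive pairs.
#'
#' @param sequence A single residue string (possibly named).
#' @param policy An [augmentation_policy()].
#' @return List with elements `weak` and `strong`; ids (names) gain
#'   `_w` / `_s` suffixes.
#' @export
make_positive_pair <- function(sequence, policy = augmentation_policy()) {
  if (!inherits(policy, "augmentation_policy"))
    stop("policy must be an 'augmentation_policy' object")
  if (policy$kind == "mutation") {
    w <- mutate_dna(sequence, policy$weak)
    s <- mutate_dna(sequence, policy$strong)
  } else {
    w <- fragment_dna(sequence, policy$weak)
    s <- fragment_dna(sequence, policy$strong)
  }
  if (!is.null(names(sequence))) {
    names(w) <- paste0(names(sequence), "_w")
    names(s) <- paste0(names(sequence), "_s")
  }
  list(weak = w, strong = s)
}
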