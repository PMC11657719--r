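# Frequency Chaos Game Representation (FCGR) encoding.
#
# The chaos game places the corners of the unit square at A = (0,0),
# C = (0,1), G = (1,1), T = (1,0) (clockwise from the bottom-left), starts
# from the centre and, for each nucleotide read left to right, jumps halfway
# towards that nucleotide's corner. At resolution k the square is cut into a
# 2^k x 2^k grid and the cell holding the point reached after k steps is a
# bijective address of the k-mer, so the grid of cell counts is exactly the
# k-mer frequency table arranged as a grayscale image.
#
# The midpoint recursion implies that the j-th character of the k-mer
# contributes bit j-1 (LSB first) of the final cell's x and y coordinates:
# x-bit 1 for G/T, y-bit 1 for C/G. Rows are indexed 0 at the TOP of the
# image (grayscale convention), so C sits at cell (0,0) and A at
# (2^k - 1, 0).

.BASES <- c("A", "C", "G", "T")
.XBIT <- c(A = 0L, C = 0L, G = 1L, T = 1L)
.YBIT <- c(A = 0L, C = 1L, G = 1L, T = 0L)

#' Grid cell of a k-mer under the chaos game
#'
#' Returns the (row, col) cell, both 0-based with row 0 at the top of the
#' image, of the 2^k x 2^k FCGR grid reached by playing the chaos game on
#' `kmer` from the centre of the unit square.
#'
#' @param kmer A string of length `k` over A, C, G, T.
#' @param k Resolution (positive integer).
#' @return Integer vector `c(row, col)`.
#' @examples
#' kmer_cell("A", 1)   # bottom-left cell (1, 0)
#' kmer_cell("CG", 2)  # (0, 2)
#' @export
kmer_cell <- function(kmer, k) {
  if (!is.character(kmer) || length(kmer) != 1L || nchar(kmer) != k)
    stop("kmer must be a single string of length k")
  ch <- strsplit(toupper(kmer), "", fixed = TRUE)[[1L]]
  if (!all(ch %in% .BASES)) stop("kmer contains characters outside {A,C,G,T}")
  w <- 2L^(seq_len(k) - 1L)
  col <- sum(.XBIT[ch] * w)
  row <- 2L^k - 1L - sum(.YBIT[ch] * w)
  c(row = as.integer(row), col = as.integer(col))
}

#' Encode a DNA sequence as an FCGR count matrix
#'
#' Slides a width-`k` window over the residues with step 1; every window
#' made only of A, C, G, T increments the count of its [kmer_cell()].
#' Windows containing any other character (N or an IUPAC ambiguity code)
#' are skipped entirely and do not contribute to `counted`, so for a pure
#' ACGT sequence of length n, `counted == n - k + 1`.
#'
#' @param sequence A single residue string (possibly named).
#' @param k Resolution; the grid is 2^k x 2^k. Default 6.
#' @return An object of class `fcgr`: list with elements `k`, `grid`
#'   (integer count matrix, row 1 = top of the image) and `counted`.
#' @examples
#' encode_fcgr("ACGT", k = 1)
#' @export
encode_fcgr <- function(sequence, k = 6L) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  n <- nchar(sequence)
  if (n < k) stop("sequence shorter than k (", n, " < ", k, ")")
  res <- .fcgr_counts_cpp(sequence, k)
  structure(list(k = k, grid = res$grid, counted = res$counted),
            class = "fcgr")
}

#' @export
print.fcgr <- function(x, ...) {
  cat(sprintf("FCGR k=%d (%dx%d), %d k-mers counted\n",
              x$k, nrow(x$grid), ncol(x$grid), x$counted))
  invisible(x)
}

#' Normalize an FCGR matrix for network input
#'
#' Applies per-matrix min-max rescaling to \[0, 1\] (removing the effect of
#' sequence length on absolute counts) followed by a per-matrix z-score with
#' the population standard deviation, so a non-constant grid ends up with
#' mean 0 and standard deviation 1. A constant grid (all counts equal, e.g.
#' a homopolymer) maps to the all-zero grid.
#'
#' @param x An `fcgr` object from [encode_fcgr()].
#' @return An object of class `normalized_fcgr`: list with `k` and a
#'   real-valued `grid`.
#' @export
normalize_fcgr <- function(x) {
  if (!inherits(x, "fcgr")) stop("x must be an 'fcgr' object")
  structure(list(k = x$k, grid = .normalize_grid(x$grid)),
            class = "normalized_fcgr")
}

.normalize_grid <- function(g) {
  lo <- min(g); hi <- max(g)
  if (hi == lo) return(matrix(0, nrow(g), ncol(g)))
  m <- (g - lo) / (hi - lo)
  mu <- mean(m)
  sdp <- sqrt(mean((m - mu)^2))
  (m - mu) / sdp
}

# Encode + normalize a set of sequences into a (side^2 x n) column matrix,
# the layout consumed by the network (column-major flattening of the grid).
.encode_norm_matrix <- function(sequences, k) {
  side <- 2L^as.integer(k)
  out <- matrix(0, side * side, length(sequences))
  for (i in seq_along(sequences)) {
    f <- encode_fcgr(sequences[[i]], k)
    out[, i] <- as.vector(.normalize_grid(f$grid))
  }
  out
}

#' Write an FCGR matrix as plain text (and optionally a grayscale image)
#'
#' The text file is a whitespace-delimited count matrix, row 1 = top image
#' row. When `png` is not `NULL` and the png package is available, a
#' grayscale rendering (dark = frequent k-mer) is written as well.
#'
#' @param x An `fcgr` object.
#' @param path Output path for the text matrix.
#' @param png Optional path for a grayscale PNG rendering.
#' @return Invisibly, `path`.
#' @export
write_fcgr <- function(x, path, png = NULL) {
  if (!inherits(x, "fcgr")) stop("x must be an 'fcgr' object")
  utils::write.table(x$grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(png)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required to write image output")
    g <- x$grid
    hi <- max(g)
    img <- if (hi == 0) matrix(1, nrow(g), ncol(g)) else 1 - g / hi
    png::writePNG(img, png)
  }
  invisible(path)
}
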