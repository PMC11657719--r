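# Hungarian-matched evaluation of a clustering against reference labels.
#
# Cluster indices carry no meaning across runs, so accuracy is computed
# after finding the one-to-one cluster-to-class matching that maximizes
# the total matched count (linear assignment / Hungarian method). Labels
# are only ever consumed here, post hoc; nothing in the training path
# sees them.

#' Minimum-cost linear assignment (Hungarian method)
#'
#' Solves the linear assignment problem for an n x m cost matrix with
#' n <= m (taller matrices are padded internally with zero-cost dummy
#' columns; rows assigned to a dummy get `NA`). The implementation is the
#' shortest-augmenting-path algorithm with row/column potentials
#' (O(n^2 m)) and is fully deterministic, so ties always resolve the same
#' way.
#'
#' @param cost Numeric cost matrix (finite entries).
#' @return Integer vector: for each row, the index of its assigned column.
#' @examples
#' min_cost_assignment(matrix(c(4, 2, 1, 3), 2, 2))  # 2 1
#' @export
min_cost_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (length(cost) == 0L) stop("cost matrix must be non-empty")
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  n <- nrow(cost); m <- ncol(cost)
  real_m <- m
  if (n > m) {
    cost <- cbind(cost, matrix(0, n, n - m))
    m <- n
  }
  u <- numeric(n)                  # row potentials
  v <- numeric(m + 1L)             # column potentials, v[1] = virtual col 0
  p <- integer(m + 1L)             # p[j+1]: row matched to column j
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      jbest <- which.min(minv[free])
      j1 <- free[jbest]
      delta <- minv[j1]
      usedj <- which(used) - 1L              # columns in the tree (incl. 0)
      rows_in_tree <- p[usedj + 1L]
      u[rows_in_tree] <- u[rows_in_tree] + delta
      v[usedj + 1L] <- v[usedj + 1L] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {                                  # augment along the path
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans[ans > real_m] <- NA_integer_
  ans
}

#' Confusion matrix of predicted clusters against true classes
#'
#' @param pred Predicted cluster labels.
#' @param truth True class labels (same length).
#' @return An integer matrix, rows = true classes, columns = predicted
#'   clusters, entries = co-occurrence counts.
#' @export
cluster_confusion <- function(pred, truth) {
  if (length(pred) == 0L) stop("empty input")
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  tab <- table(truth = factor(truth), pred = factor(pred))
  mat <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  mat
}

#' Hungarian-matched clustering accuracy
#'
#' Finds the one-to-one matching between predicted clusters and true
#' classes that maximizes the total number of correctly matched sequences
#' (rectangular confusion matrices are padded with zero-count dummies),
#' and reports the resulting accuracy, mapping and confusion matrix.
#' Accuracy is invariant under any relabelling of predicted clusters or
#' of true classes.
#'
#' @param pred Predicted cluster labels.
#' @param truth True class labels (same length).
#' @return An object of class `evaluation_report`: list with `confusion`
#'   (true x predicted counts), `mapping` (named character vector,
#'   predicted cluster -> matched true class), `accuracy` and `n`.
#' @examples
#' hungarian_accuracy(c(1, 1, 2, 2), c("a", "a", "b", "b"))$accuracy  # 1
#' @export
hungarian_accuracy <- function(pred, truth) {
  conf <- cluster_confusion(pred, truth)
  n <- sum(conf)
  r <- nrow(conf); c <- ncol(conf)
  sq <- matrix(0L, max(r, c), max(r, c))
  sq[seq_len(r), seq_len(c)] <- conf
  assign <- min_cost_assignment(max(sq) - sq)   # maximize matched counts
  matched <- 0L
  mapping <- character(0)
  for (i in seq_len(r)) {
    j <- assign[[i]]
    if (!is.na(j) && j <= c) {
      matched <- matched + sq[i, j]
      mapping[colnames(conf)[j]] <- rownames(conf)[i]
    }
  }
  mapping <- mapping[order(names(mapping))]
  structure(list(confusion = conf, mapping = mapping,
                 accuracy = matched / n, n = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Hungarian-matched clustering accuracy: %.4f (n = %d)\n",
              x$accuracy, x$n))
  cat("cluster -> class mapping:\n")
  for (nm in names(x$mapping))
    cat(sprintf("  %s -> %s\n", nm, x$mapping[[nm]]))
  cat("confusion matrix (rows = truth, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report as a machine-readable key-value file
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "evaluation_report"))
    stop("report must be an 'evaluation_report'")
  lines <- c(sprintf("accuracy\t%.6f", report$accuracy),
             sprintf("n\t%d", report$n),
             vapply(names(report$mapping), function(nm)
               sprintf("map\t%s\t%s", nm, report$mapping[[nm]]), ""),
             apply(cbind(rownames(report$confusion)[row(report$confusion)],
                         colnames(report$confusion)[col(report$confusion)],
                         as.vector(report$confusion)), 1L,
                   function(r) paste(c("confusion", r), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Evaluate an assignments file against a labels file
#'
#' Joins the two tables on sequence id (ids present in only one file are
#' dropped with a warning) and computes [hungarian_accuracy()] on the
#' overlap.
#'
#' @param assignments Path to a file written by [write_assignments()].
#' @param labels Path to a two-column label file, see [read_labels()].
#' @return An `evaluation_report`.
#' @export
evaluate_run <- function(assignments, labels) {
  asg <- read_assignments(assignments)
  lab <- read_labels(labels)
  common <- intersect(asg$id, lab$id)
  if (length(common) == 0L)
    stop("no overlapping ids between assignments and labels")
  dropped <- (nrow(asg) - length(common)) + (nrow(lab) - length(common))
  if (dropped > 0L)
    warning(dropped, " id(s) present in only one of the two files were dropped")
  hungarian_accuracy(asg$cluster[match(common, asg$id)],
                     lab$label[match(common, lab$id)])
}
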