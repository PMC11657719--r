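# Independent brute-force oracles used to verify the vectorized
# implementations. These are deliberately naive (dictionary counting,
# double loops, full permutation enumeration) and share no code with the
# package internals they check.

# FCGR oracle: tally the sliding windows in a dictionary, then route each
# distinct k-mer through kmer_cell.
slow_fcgr <- function(sequence, k) {
  side <- 2L^k
  grid <- matrix(0L, side, side)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  windows <- substring(sequence, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  windows <- windows[!grepl("[^ACGT]", windows)]
  tab <- table(windows)
  for (km in names(tab)) {
    cell <- kmer_cell(km, k)
    grid[cell[1L] + 1L, cell[2L] + 1L] <-
      grid[cell[1L] + 1L, cell[2L] + 1L] + as.integer(tab[[km]])
  }
  list(grid = grid, counted = sum(tab))
}

# NT-Xent instance-loss oracle: explicit double loop over anchors and
# candidates on the stacked 2n samples.
slow_instance_loss <- function(z_weak, z_strong, tau) {
  Z <- rbind(z_weak, z_strong)
  Z <- Z / sqrt(rowSums(Z^2))
  m <- nrow(Z)
  n <- m / 2
  total <- 0
  for (i in seq_len(m)) {
    p <- if (i <= n) i + n else i - n
    num <- exp(sum(Z[i, ] * Z[p, ]) / tau)
    den <- 0
    for (j in seq_len(m)) if (j != i)
      den <- den + exp(sum(Z[i, ] * Z[j, ]) / tau)
    total <- total - log(num / den)
  }
  total / m
}

# Cluster-loss oracle: loop over the 2C normalized columns plus the
# marginal-entropy term of each view.
slow_cluster_loss <- function(p_weak, p_strong, tau) {
  C <- ncol(p_weak)
  cols <- cbind(p_weak, p_strong)
  cols <- sweep(cols, 2, pmax(sqrt(colSums(cols^2)), 1e-12), "/")
  m <- 2L * C
  total <- 0
  for (j in seq_len(m)) {
    p <- if (j <= C) j + C else j - C
    num <- exp(sum(cols[, j] * cols[, p]) / tau)
    den <- 0
    for (l in seq_len(m)) if (l != j)
      den <- den + exp(sum(cols[, j] * cols[, l]) / tau)
    total <- total - log(num / den)
  }
  neg_ent <- function(P) {
    mm <- pmax(colMeans(P), 1e-12)
    sum(mm * log(mm))
  }
  total / m + neg_ent(p_weak) + neg_ent(p_strong)
}

# All permutations of a vector (for exhaustive assignment search).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Exhaustive-minimum linear assignment for square cost matrices.
slow_assignment_cost <- function(cost) {
  best <- Inf
  for (p in all_perms(seq_len(nrow(cost))))
    best <- min(best, sum(cost[cbind(seq_len(nrow(cost)), p)]))
  best
}

# Exhaustive Hungarian-matched accuracy over all cluster relabelings.
slow_accuracy <- function(pred, truth) {
  pf <- factor(pred); tf <- factor(truth)
  conf <- table(tf, pf)
  r <- nrow(conf); c <- ncol(conf)
  d <- max(r, c)
  sq <- matrix(0L, d, d)
  sq[seq_len(r), seq_len(c)] <- conf
  best <- 0
  for (p in all_perms(seq_len(d)))
    best <- max(best, sum(sq[cbind(seq_len(d), p)]))
  best / length(pred)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
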