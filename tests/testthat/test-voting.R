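random_assignment <- function(n, C) {
  P <- matrix(stats::rexp(n * C), n, C)
  P / rowSums(P)
}

test_that("alignment recovers a known column permutation", {
  set.seed(21)
  for (trial in 1:10) {
    n <- 50; C <- sample(2:6, 1)
    ref <- random_assignment(n, C)
    perm <- sample(C)
    other <- ref[, perm]              # other's cluster j = ref cluster perm[j]
    got <- align_clusters(other, ref)
    expect_identical(got, as.integer(perm))
    aligned <- fcgrclust:::.apply_alignment(other, got)
    expect_equal(aligned, ref)
  }
})

test_that("alignment of identical members is the identity", {
  set.seed(3)
  P <- random_assignment(30, 4)
  expect_identical(align_clusters(P, P), 1:4)
})

test_that("degenerate one-cluster members still get a valid permutation", {
  P <- random_assignment(20, 3)
  Q <- matrix(0, 20, 3); Q[, 2] <- 1
  perm <- align_clusters(Q, P)
  expect_identical(sort(perm), 1:3)
})

test_that("soft voting averages aligned probabilities, argmax ties to lowest", {
  m1 <- matrix(c(0.6, 0.4, 0.2, 0.8), 2, 2, byrow = TRUE)
  vote <- soft_vote(list(m1, m1, m1))
  expect_identical(vote$cluster, c(1L, 2L))
  expect_equal(vote$probabilities, m1)
  m2 <- matrix(c(0.2, 0.8, 0.6, 0.4), 2, 2, byrow = TRUE)
  # alignment flips m2's columns (its hard labels are the mirror of m1's)
  vote2 <- soft_vote(list(m1, m2))
  expect_equal(vote2$probabilities, matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2,
                                           byrow = TRUE))
  tie <- matrix(0.5, 2, 2)
  expect_identical(soft_vote(list(tie))$cluster, c(1L, 1L))
  expect_error(soft_vote(list()), "empty")
})

test_that("hard voting takes the modal aligned label with low-index ties", {
  n <- 4
  mk <- function(labs) {
    P <- matrix(0, n, 3)
    P[cbind(seq_len(n), labs)] <- 1
    P
  }
  members <- list(mk(c(1, 2, 3, 3)), mk(c(1, 2, 3, 3)), mk(c(1, 2, 3, 1)),
                  mk(c(2, 2, 3, 3)), mk(c(1, 2, 1, 3)))
  expect_identical(hard_vote(members)$cluster, c(1L, 2L, 3L, 3L))
  two <- list(mk(c(1, 2, 1, 2)), mk(c(2, 2, 1, 1)))
  # the two members disagree after alignment on rows 1 and 4: tie -> lowest
  expect_identical(hard_vote(list(mk(c(1, 1, 2, 2)),
                                  mk(c(1, 2, 1, 2))))$cluster[1], 1L)
})

test_that("voting is invariant to relabeling of individual members", {
  set.seed(31)
  n <- 40; C <- 4
  members <- replicate(3, random_assignment(n, C), simplify = FALSE)
  base_soft <- soft_vote(members)
  base_hard <- hard_vote(members)
  shuffled <- lapply(members, function(P) P[, sample(C)])
  shuffled[[1]] <- members[[1]]      # keep the reference member fixed
  expect_identical(soft_vote(shuffled)$cluster, base_soft$cluster)
  expect_identical(hard_vote(shuffled)$cluster, base_hard$cluster)
})

test_that("the soft-vote mean matrix is itself a valid assignment matrix", {
  set.seed(13)
  members <- replicate(4, random_assignment(25, 3), simplify = FALSE)
  M <- soft_vote(members)$probabilities
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(rowSums(M), rep(1, 25), tolerance = 1e-9)
})
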