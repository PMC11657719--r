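test_that("confusion matrix counts co-occurrences", {
  conf <- cluster_confusion(c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2),
                            rep(c("a", "b"), each = 5))
  expect_identical(unname(conf), matrix(c(5L, 0L, 0L, 5L), 2, 2))
  conf2 <- cluster_confusion(rep(0, 10), rep(c("a", "b"), each = 5))
  expect_identical(unname(conf2), matrix(c(5L, 5L), 2, 1))
  expect_error(cluster_confusion(integer(0), integer(0)), "empty")
  expect_error(cluster_confusion(1:3, 1:4), "length")
})

test_that("assignment solver equals exhaustive permutation search", {
  set.seed(55)
  for (trial in 1:100) {
    C <- sample(2:6, 1)
    cost <- matrix(stats::runif(C * C, 0, 10), C, C)
    a <- min_cost_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(C), a)]), slow_assignment_cost(cost),
                 tolerance = 1e-9)
  }
})

test_that("hungarian accuracy reproduces the worked 2x2 example", {
  pred <- c(rep("p1", 5), rep("p2", 1), rep("p1", 2), rep("p2", 4))
  truth <- c(rep("t1", 6), rep("t2", 6))
  rep_ <- hungarian_accuracy(pred, truth)
  expect_equal(rep_$accuracy, 0.75)
  expect_identical(unname(rep_$mapping), c("t1", "t2"))
})

test_that("accuracy equals exhaustive search on random labelings", {
  set.seed(66)
  for (trial in 1:40) {
    n <- sample(10:40, 1)
    C <- sample(2:5, 1)
    pred <- sample(seq_len(C), n, replace = TRUE)
    truth <- sample(letters[seq_len(sample(2:5, 1))], n, replace = TRUE)
    expect_equal(hungarian_accuracy(pred, truth)$accuracy,
                 slow_accuracy(pred, truth))
  }
})

test_that("accuracy is invariant under label permutations", {
  set.seed(4)
  n <- 60
  pred <- sample(1:4, n, replace = TRUE)
  truth <- sample(letters[1:4], n, replace = TRUE)
  base <- hungarian_accuracy(pred, truth)$accuracy
  perm <- sample(4)
  expect_equal(hungarian_accuracy(perm[pred], truth)$accuracy, base)
  relab <- stats::setNames(letters[4:1], letters[1:4])
  expect_equal(hungarian_accuracy(pred, relab[truth])$accuracy, base)
  # permutation-relabelled predictions of the truth score 1
  expect_equal(hungarian_accuracy(perm[match(truth, letters[1:4])],
                                  truth)$accuracy, 1)
})

test_that("degenerate single-cluster predictions score the best single class", {
  pred <- rep(1, 10)
  truth <- rep(c("a", "b"), each = 5)
  expect_equal(hungarian_accuracy(pred, truth)$accuracy, 0.5)
})

test_that("evaluate_run joins on id, warns on partial overlap, errors on none", {
  asg <- withr::local_tempfile(fileext = ".tsv")
  lab <- withr::local_tempfile(fileext = ".tsv")
  write_assignments(asg, c("a", "b", "c", "d"), c(1, 1, 2, 2))
  writeLines(c("a\tx", "b\tx", "c\ty", "d\ty"), lab)
  expect_equal(evaluate_run(asg, lab)$accuracy, 1)
  writeLines(c("a\tx", "b\tx", "c\ty", "d\ty", "e\ty"), lab)
  expect_warning(rep_ <- evaluate_run(asg, lab), "dropped")
  expect_identical(rep_$n, 4L)
  writeLines(c("q\tx", "r\ty"), lab)
  expect_error(suppressWarnings(evaluate_run(asg, lab)), "overlap")
})

test_that("reports round trip through the key-value file", {
  rep_ <- hungarian_accuracy(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  f <- withr::local_tempfile(fileext = ".txt")
  write_report(rep_, f)
  lines <- readLines(f)
  expect_match(lines[1], "^accuracy\t1")
  expect_match(lines[2], "^n\t4$")
})
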