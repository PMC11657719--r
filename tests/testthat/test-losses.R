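test_that("instance loss matches the closed form for identical embeddings", {
  for (n in c(2L, 5L, 9L)) {
    Z <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
    expect_equal(instance_loss(Z, Z, tau_i = 0.3), log(2 * n - 1),
                 tolerance = 1e-6)
  }
})

test_that("both losses agree with brute-force enumeration oracles", {
  set.seed(77)
  for (trial in 1:50) {
    n <- sample(2:8, 1)
    d <- sample(2:6, 1)
    C <- sample(2:5, 1)
    tau_i <- stats::runif(1, 0.05, 1)
    tau_c <- stats::runif(1, 0.5, 2)
    Zw <- matrix(stats::rnorm(n * d), n, d)
    Zs <- matrix(stats::rnorm(n * d), n, d)
    Zw <- Zw / sqrt(rowSums(Zw^2))
    Zs <- Zs / sqrt(rowSums(Zs^2))
    expect_equal(instance_loss(Zw, Zs, tau_i),
                 slow_instance_loss(Zw, Zs, tau_i), tolerance = 1e-6)
    Pw <- matrix(stats::rexp(n * C), n, C); Pw <- Pw / rowSums(Pw)
    Ps <- matrix(stats::rexp(n * C), n, C); Ps <- Ps / rowSums(Ps)
    expect_equal(cluster_loss(Pw, Ps, tau_c),
                 slow_cluster_loss(Pw, Ps, tau_c), tolerance = 1e-6)
  }
})

test_that("instance loss is symmetric in the views and rotation invariant", {
  set.seed(8)
  n <- 6; d <- 5
  Zw <- matrix(stats::rnorm(n * d), n, d); Zw <- Zw / sqrt(rowSums(Zw^2))
  Zs <- matrix(stats::rnorm(n * d), n, d); Zs <- Zs / sqrt(rowSums(Zs^2))
  expect_equal(instance_loss(Zw, Zs, 0.2), instance_loss(Zs, Zw, 0.2))
  rot <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
  expect_equal(instance_loss(Zw %*% rot, Zs %*% rot, 0.2),
               instance_loss(Zw, Zs, 0.2), tolerance = 1e-9)
})

test_that("instance loss decreases as positives become more similar", {
  set.seed(12)
  d <- 8; n <- 5
  base <- matrix(stats::rnorm(n * d), n, d); base <- base / sqrt(rowSums(base^2))
  noise <- matrix(stats::rnorm(n * d), n, d)
  mix <- function(lam) {
    Zs <- base + lam * noise
    instance_loss(base, Zs / sqrt(rowSums(Zs^2)), 0.5)
  }
  expect_lt(mix(0.05), mix(0.5))
  expect_lt(mix(0.5), mix(2))
})

test_that("cluster loss penalizes collapse and rewards balanced assignment", {
  n <- 8; C <- 4
  balanced <- diag(C)[rep(seq_len(C), each = n / C), ]
  collapsed <- matrix(0, n, C); collapsed[, 1] <- 1
  expect_lt(cluster_loss(balanced, balanced, 1),
            cluster_loss(collapsed, collapsed, 1))
  uniform <- matrix(1 / C, n, C)
  # entropy term alone: uniform marginals give the -2 log C minimum
  expect_equal(cluster_loss(uniform, uniform, 1) -
                 slow_cluster_loss(uniform, uniform, 1), 0, tolerance = 1e-9)
  expect_equal(fcgrclust:::.neg_entropy(uniform) * 2, -2 * log(C))
})

test_that("losses validate their inputs", {
  Z <- matrix(1, 1, 4)
  expect_error(instance_loss(Z, Z, 0.1), "at least 2")
  expect_error(instance_loss(matrix(1, 3, 4), matrix(1, 2, 4), 0.1), "shapes")
  P <- matrix(0.5, 4, 2)
  expect_error(cluster_loss(P, P * 2, 1), "probability")
  expect_error(twin_loss(1, 1, 1.2), "alpha")
})

test_that("twin loss is the alpha-weighted combination", {
  expect_identical(twin_loss(2, 1, 1), 2)
  expect_identical(twin_loss(2, 1, 0), 1)
  expect_equal(twin_loss(2, 1, 0.7), 1.7)
})
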