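test_that("datasets are reproducible from the seed", {
  spec <- synthetic_spec(clusters = 3, size = 4, length_range = c(100, 200),
                         seed = 9)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a, b)
  spec2 <- synthetic_spec(clusters = 3, size = 4, length_range = c(100, 200),
                          seed = 10)
  expect_false(identical(generate_dataset(spec2)$sequences, a$sequences))
})

test_that("ancestors are uniform over the alphabet", {
  set.seed(1)
  expect_error(generate_ancestor(0), "positive")
  s <- strsplit(generate_ancestor(200000), "")[[1]]
  for (b in c("A", "C", "G", "T"))
    expect_lt(abs(sum(s == b) - 50000), 4 * sqrt(200000 * 0.25 * 0.75))
})

test_that("cluster members sit at the requested identity to the ancestor", {
  set.seed(2)
  anc <- generate_ancestor(1000)
  members <- generate_cluster(anc, 100, identity = 0.9)
  expect_identical(unique(nchar(members)), 1000L)
  aa <- strsplit(anc, "")[[1]]
  ids <- vapply(members, function(m)
    mean(strsplit(m, "")[[1]] == aa), numeric(1))
  expect_gt(mean(ids), 0.88)
  expect_lt(mean(ids), 0.92)
  # pairwise identity: two independent mutation layers with collisions
  q <- 0.1
  expected <- 1 - 2 * q * (1 - q) - q^2 * (1 - 1 / 3)
  pw <- replicate(200, {
    ij <- sample(100, 2)
    mean(strsplit(members[ij[1]], "")[[1]] == strsplit(members[ij[2]], "")[[1]])
  })
  expect_lt(abs(mean(pw) - expected), 0.01)
  expect_identical(generate_cluster(anc, 3, identity = 1),
                   rep(anc, 3))
})

test_that("signature clusters have distinct dinucleotide composition", {
  dinuc <- function(seqs) {
    m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))
    for (s in seqs) {
      ch <- strsplit(s, "")[[1]]
      t <- table(factor(ch[-length(ch)], rownames(m)),
                 factor(ch[-1], rownames(m)))
      m <- m + t
    }
    m / sum(m)
  }
  spec <- synthetic_spec(mode = "markov_signature", clusters = 2, size = 10,
                         length_range = c(500, 800),
                         signature_strength = 1, seed = 5)
  dat <- generate_dataset(spec)
  g1 <- dinuc(dat$sequences[dat$labels$label == "cluster01"])
  g2 <- dinuc(dat$sequences[dat$labels$label == "cluster02"])
  expect_gt(sqrt(sum((g1 - g2)^2)), 0.05)
  lens <- nchar(dat$sequences)
  expect_true(all(lens >= 500 & lens <= 800))
})

test_that("dataset assembly yields the requested sizes and anonymous ids", {
  spec <- synthetic_spec(clusters = 3, size = 10, length_range = c(80, 120),
                         seed = 3)
  dat <- generate_dataset(spec)
  expect_identical(length(dat$sequences), 30L)
  expect_identical(unname(table(dat$labels$label)), as.table(rep(10L, 3)),
                   ignore_attr = TRUE)
  expect_identical(dat$labels$id, sprintf("seq%05d", 1:30))
  ranged <- synthetic_spec(clusters = 4, size = c(5, 15),
                           length_range = c(80, 120), seed = 3)
  sizes <- table(generate_dataset(ranged)$labels$label)
  expect_true(all(sizes >= 5 & sizes <= 15))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(clusters = 1), "clusters")
  expect_error(synthetic_spec(identity = 0), "identity")
  expect_error(synthetic_spec(signature_strength = 1.5), "strength")
  expect_error(synthetic_spec(length_range = c(200, 100)), "length_range")
})
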