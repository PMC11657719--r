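test_that("kmer_cell follows the clockwise-from-bottom-left corner convention", {
  expect_identical(unname(kmer_cell("A", 1)), c(1L, 0L))
  expect_identical(unname(kmer_cell("C", 1)), c(0L, 0L))
  expect_identical(unname(kmer_cell("G", 1)), c(0L, 1L))
  expect_identical(unname(kmer_cell("T", 1)), c(1L, 1L))
  expect_identical(unname(kmer_cell("AA", 2)), c(3L, 0L))
  expect_identical(unname(kmer_cell("CG", 2)), c(0L, 2L))
  expect_error(kmer_cell("AN", 2), "outside")
  expect_error(kmer_cell("A", 2), "length")
})

test_that("kmer_cell is a bijection between k-mers and grid cells", {
  for (k in 1:3) {
    kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k)))
    cells <- vapply(kmers, function(km) {
      cell <- kmer_cell(km, k)
      cell[1L] * as.integer(2^k) + cell[2L]
    }, integer(1))
    expect_identical(sort(unname(cells)), as.integer(0:(4^k - 1)))
  }
})

test_that("encode_fcgr matches brute-force dictionary counting", {
  set.seed(101)
  for (trial in 1:12) {
    k <- sample(c(1L, 2L, 4L, 6L), 1)
    n <- sample(100:800, 1)
    s <- random_dna(n)
    fast <- encode_fcgr(s, k)
    slow <- slow_fcgr(s, k)
    expect_identical(fast$grid, slow$grid)
    expect_identical(fast$counted, n - k + 1L)
    expect_identical(sum(fast$grid), n - k + 1L)
  }
})

test_that("windows containing non-ACGT characters are skipped entirely", {
  f <- encode_fcgr("ACNGT", 2)
  expect_identical(f$counted, 2L)
  expect_identical(sum(f$grid), 2L)
  slow <- slow_fcgr("ACNGT", 2)
  expect_identical(f$grid, slow$grid)
  hom <- encode_fcgr("AAAA", 2)
  expect_identical(hom$grid[4L, 1L], 3L)
  expect_identical(sum(hom$grid), 3L)
  expect_error(encode_fcgr("AC", 3), "shorter")
})

test_that("FCGR is not reverse-complement canonical", {
  set.seed(7)
  s <- random_dna(500)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_false(identical(encode_fcgr(s, 4)$grid, encode_fcgr(rc, 4)$grid))
})

test_that("normalization min-max rescales then z-scores with population sd", {
  f <- structure(list(k = 1L, grid = matrix(c(0L, 2L, 1L, 3L), 2, 2),
                      counted = 6L), class = "fcgr")
  nm <- normalize_fcgr(f)
  expect_equal(nm$grid, matrix(c(-1.3416408, 0.4472136, -0.4472136, 1.3416408),
                               2, 2), tolerance = 1e-6)
  set.seed(3)
  g <- normalize_fcgr(encode_fcgr(random_dna(300), 3))$grid
  expect_equal(mean(g), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean((g - mean(g))^2)), 1, tolerance = 1e-6)
})

test_that("constant grids normalize to all zeros", {
  f <- encode_fcgr("AAAAAA", 1)   # only the A cell is hit, but grid varies
  hom <- structure(list(k = 1L, grid = matrix(2L, 2, 2), counted = 8L),
                   class = "fcgr")
  expect_true(all(normalize_fcgr(hom)$grid == 0))
})

test_that("write_fcgr emits a readable plain-text matrix", {
  f <- encode_fcgr("ACGTACGT", 2)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_fcgr(f, out)
  back <- as.matrix(utils::read.table(out, sep = "\t"))
  dimnames(back) <- NULL
  expect_identical(back, f$grid)
})
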