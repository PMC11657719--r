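# Training-loop contracts on tiny problems (the end-to-end recovery runs
# live in test-acceptance.R).

tiny_data <- function(seed = 17) {
  generate_dataset(synthetic_spec(mode = "markov_signature", clusters = 2,
                                  size = 8, length_range = c(300, 400),
                                  signature_strength = 0.9, seed = seed))
}

test_that("configs validate their invariants", {
  expect_error(training_config(batch_size = 1), "batch_size")
  expect_error(training_config(epochs = -1), "epochs")
  expect_error(training_config(ensemble = 0), "ensemble")
  expect_error(loss_config(alpha = 1.5), "alpha")
  expect_error(loss_config(tau_i = 0), "positive")
  expect_error(network_config(clusters = 1), "clusters")
})

test_that("zero epochs returns the seeded initialization untouched", {
  dat <- tiny_data()
  cfg <- training_config(epochs = 0, batch_size = 8, ensemble = 1)
  m <- train_single(dat$sequences, clusters = 2, config = cfg, seed = 5)
  ref <- fcgrclust:::.init_network(m$network$config, 5)
  expect_identical(m$network$params, ref$params)
  expect_identical(nrow(m$history), 0L)
})

test_that("training is reproducible from the seed", {
  dat <- tiny_data()
  cfg <- training_config(epochs = 3, batch_size = 8, ensemble = 1,
                         channels = c(4L, 8L), embedding_dim = 32L)
  a <- train_single(dat$sequences, clusters = 2, config = cfg, seed = 7)
  b <- train_single(dat$sequences, clusters = 2, config = cfg, seed = 7)
  expect_identical(a$history, b$history)
  expect_identical(a$network$params, b$network$params)
  c <- train_single(dat$sequences, clusters = 2, config = cfg, seed = 8)
  expect_false(identical(a$network$params, c$network$params))
})

test_that("predictions are valid, deterministic assignment matrices", {
  dat <- tiny_data()
  cfg <- training_config(epochs = 2, batch_size = 8, ensemble = 1,
                         channels = c(4L, 8L), embedding_dim = 32L)
  m <- train_single(dat$sequences, clusters = 2, config = cfg, seed = 1)
  P <- predict_probabilities(m, dat$sequences)
  expect_identical(dim(P), c(16L, 2L))
  expect_equal(unname(rowSums(P)), rep(1, 16), tolerance = 1e-6)
  expect_identical(P, predict_probabilities(m, dat$sequences))
  expect_error(predict_probabilities(m, c(x = "ACG")), "at least k")
})

test_that("ensembles derive member seeds from the base seed", {
  dat <- tiny_data()
  cfg <- training_config(epochs = 1, batch_size = 8, ensemble = 3, seed = 40,
                         channels = c(4L, 8L), embedding_dim = 32L)
  ens <- train_ensemble(dat$sequences, clusters = 2, config = cfg)
  expect_identical(vapply(ens, `[[`, 1L, "seed"), 40:42)
  expect_false(identical(ens[[1]]$network$params, ens[[2]]$network$params))
  ens2 <- train_ensemble(dat$sequences, clusters = 2, config = cfg)
  expect_identical(lapply(ens, `[[`, "history"), lapply(ens2, `[[`, "history"))
})

test_that("the loss decreases on well-separated signature data", {
  dat <- generate_dataset(synthetic_spec(mode = "markov_signature",
                                         clusters = 3, size = 12,
                                         length_range = c(400, 600),
                                         signature_strength = 0.8, seed = 23))
  cfg <- training_config(epochs = 25, batch_size = 36, ensemble = 1)
  m <- train_single(dat$sequences, clusters = 3, config = cfg, seed = 2)
  expect_lt(m$history$l_train[25], m$history$l_train[1])
})

test_that("the fitted object exposes the standard methods", {
  dat <- tiny_data()
  cfg <- training_config(epochs = 2, batch_size = 8, ensemble = 2,
                         channels = c(4L, 8L), embedding_dim = 32L)
  fit <- fcgr_tcc(dat$sequences, clusters = 2, config = cfg)
  expect_s3_class(fit, "fcgr_tcc")
  expect_identical(length(fit$cluster), 16L)
  expect_identical(fitted(fit), fit$probabilities)
  expect_identical(predict(fit), fit$cluster)
  expect_identical(predict(fit, dat$sequences, type = "class"),
                   stats::setNames(fit$cluster, names(dat$sequences)))
  expect_output(print(fit), "clusters")
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(fit$models[[1]], f)
  expect_identical(predict_probabilities(load_model(f), dat$sequences),
                   predict_probabilities(fit$models[[1]], dat$sequences))
})

test_that("training rejects degenerate inputs", {
  cfg <- training_config(epochs = 1, batch_size = 4, ensemble = 1)
  expect_error(train_single(c(a = "ACGTACGT"), 2, cfg), "at least 2")
  expect_error(train_single(c(a = "ACGT", b = "ACG"), 2, cfg), "at least k")
})
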