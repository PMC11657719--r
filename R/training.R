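# Joint training of backbone + heads on augmented pairs, plus the
# high-level fitting interface.

#' Training configuration
#'
#' Defaults follow the published hyperparameter study this implementation
#' is built around: Adam with learning rate 7e-5 and weight decay 1e-4,
#' batch size 512, 150 epochs, FCGR resolution k = 6, mutation
#' augmentation with mu1 = 1e-4 / mu2 = 1e-2, loss weights alpha = 0.7,
#' tau_I = 0.1, tau_C = 1.0, and a five-model ensemble. No learning-rate
#' schedule is used.
#'
#' @param loss A [loss_config()].
#' @param lr Adam learning rate.
#' @param weight_decay L2 weight decay added to the gradient.
#' @param batch_size Sequences per batch (augmented to 2x this many
#'   samples); at least 2.
#' @param epochs Number of passes over the dataset (>= 0).
#' @param ensemble Number of independently seeded models (>= 1).
#' @param seed Base random seed; ensemble member m uses `seed + m - 1`.
#' @param policy An [augmentation_policy()].
#' @param k FCGR resolution.
#' @param channels,embedding_dim,instance_dim Backbone architecture, see
#'   [network_config()].
#' @return An object of class `training_config`.
#' @export
training_config <- function(loss = loss_config(), lr = 7e-5,
                            weight_decay = 1e-4, batch_size = 512L,
                            epochs = 150L, ensemble = 5L, seed = 1L,
                            policy = augmentation_policy(), k = 6L,
                            channels = c(8L, 16L), embedding_dim = 512L,
                            instance_dim = 128L) {
  if (!inherits(loss, "loss_config")) stop("loss must be a loss_config")
  if (!inherits(policy, "augmentation_policy"))
    stop("policy must be an augmentation_policy")
  batch_size <- as.integer(batch_size)
  epochs <- as.integer(epochs)
  ensemble <- as.integer(ensemble)
  if (batch_size < 2L) stop("batch_size must be at least 2")
  if (epochs < 0L) stop("epochs must be non-negative")
  if (ensemble < 1L) stop("ensemble must be at least 1")
  if (lr <= 0 || weight_decay < 0) stop("invalid optimizer settings")
  structure(list(loss = loss, lr = lr, weight_decay = weight_decay,
                 batch_size = batch_size, epochs = epochs,
                 ensemble = ensemble, seed = as.integer(seed),
                 policy = policy, k = as.integer(k),
                 channels = as.integer(channels),
                 embedding_dim = as.integer(embedding_dim),
                 instance_dim = as.integer(instance_dim)),
            class = "training_config")
}

#' Train a single twin-contrastive model
#'
#' Each epoch the sequences are reshuffled and cut into batches of at most
#' `batch_size`. For every batch, a fresh weak/strong mimic pair is drawn
#' per sequence (augmentations are never cached across epochs), both views
#' are FCGR-encoded and normalized, forwarded jointly through the backbone
#' and both heads, and one Adam step is taken on the combined twin loss.
#' The trailing incomplete batch is kept; batches reduced to a single
#' sequence are skipped, as one positive pair has no negatives. With a
#' fixed seed the whole trajectory is reproducible.
#'
#' @param sequences Named character vector of DNA sequences (>= 2).
#' @param clusters Target number of clusters C.
#' @param config A [training_config()].
#' @param seed Seed for this model (initialization, shuffling and
#'   augmentation). Defaults to `config$seed`.
#' @param verbose Print an epoch-level loss line every `verbose` epochs
#'   (0 = silent).
#' @return An object of class `tcc_model`: list with the trained
#'   `network`, `history` (per-epoch mean losses), `seed`, `clusters` and
#'   `config`.
#' @export
train_single <- function(sequences, clusters, config = training_config(),
                         seed = config$seed, verbose = 0L) {
  .check_sequences(sequences)
  n <- length(sequences)
  if (n < 2L) stop("at least 2 sequences are required")
  if (any(nchar(sequences) < config$k))
    stop("all sequences must be at least k = ", config$k, " bases long")
  cfg <- network_config(clusters = clusters, k = config$k,
                        channels = config$channels,
                        embedding_dim = config$embedding_dim,
                        instance_dim = config$instance_dim)
  net <- .init_network(cfg, seed)
  opt <- .adam_init(net$params)
  hist <- data.frame(epoch = integer(), l_ins = numeric(),
                     l_clu = numeric(), l_train = numeric())
  if (config$epochs > 0L) {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq.int(1L, n, by = config$batch_size)
      acc <- c(0, 0, 0); wt <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1L, n)]
        nb <- length(idx)
        if (nb < 2L) next
        X <- matrix(0, cfg$side^2, 2L * nb)
        for (j in seq_len(nb)) {
          pair <- make_positive_pair(sequences[[idx[j]]], config$policy)
          X[, j] <- .encode_norm_matrix(pair$weak, config$k)
          X[, j + nb] <- .encode_norm_matrix(pair$strong, config$k)
        }
        fwd <- .net_forward(net, X, train = TRUE)
        net$run1_mean <- fwd$cache$b1$run_mean
        net$run1_var <- fwd$cache$b1$run_var
        net$run2_mean <- fwd$cache$b2$run_mean
        net$run2_var <- fwd$cache$b2$run_var
        ls <- .twin_loss_grad(fwd$Z, fwd$P, config$loss)
        grads <- .net_backward(net, fwd, ls$dZ, ls$dP)
        opt <- .adam_step(net$params, grads, opt,
                          config$lr, config$weight_decay)
        acc <- acc + nb * c(ls$l_ins, ls$l_clu, ls$l_train)
        wt <- wt + nb
      }
      if (wt > 0) {
        hist <- rbind(hist, data.frame(epoch = ep, l_ins = acc[1] / wt,
                                       l_clu = acc[2] / wt,
                                       l_train = acc[3] / wt))
        if (verbose > 0L && (ep %% verbose == 0L || ep == config$epochs))
          message(sprintf("epoch %4d  L_ins %.4f  L_clu %.4f  L_train %.4f",
                          ep, acc[1] / wt, acc[2] / wt, acc[3] / wt))
      }
    }
  }
  structure(list(network = net, history = hist, seed = seed,
                 clusters = cfg$clusters, config = config),
            class = "tcc_model")
}

#' @export
print.tcc_model <- function(x, ...) {
  cat(sprintf("twin-contrastive model: %d clusters, seed %d, %d epochs\n",
              x$clusters, x$seed, nrow(x$history)))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("final losses: L_ins %.4f, L_clu %.4f, L_train %.4f\n",
                last$l_ins, last$l_clu, last$l_train))
  }
  invisible(x)
}

#' Cluster-membership probabilities for original sequences
#'
#' Encodes each original (non-augmented) sequence as a normalized FCGR and
#' runs the backbone and cluster head in eval mode (batch normalization
#' uses running statistics, so the output is deterministic and independent
#' of batch composition).
#'
#' @param model A `tcc_model` from [train_single()].
#' @param sequences Named character vector of sequences.
#' @return Assignment matrix: one row per sequence (rownames = ids),
#'   `clusters` columns, rows summing to one.
#' @export
predict_probabilities <- function(model, sequences) {
  if (!inherits(model, "tcc_model")) stop("model must be a 'tcc_model'")
  .check_sequences(sequences)
  if (any(nchar(sequences) < model$config$k))
    stop("all sequences must be at least k = ", model$config$k,
         " bases long")
  X <- .encode_norm_matrix(sequences, model$config$k)
  P <- t(.net_forward(model$network, X, train = FALSE)$P)
  rownames(P) <- names(sequences)
  colnames(P) <- paste0("cluster", seq_len(ncol(P)))
  P
}

#' Train an ensemble of independently seeded models
#'
#' Member m is trained by [train_single()] with seed `config$seed + m - 1`,
#' giving each member its own initialization, shuffling and augmentation
#' stream. Ensemble size 1 behaves exactly like [train_single()].
#'
#' @inheritParams train_single
#' @return List of `tcc_model` objects.
#' @export
train_ensemble <- function(sequences, clusters, config = training_config(),
                           verbose = 0L) {
  lapply(seq_len(config$ensemble), function(m) {
    if (verbose > 0L)
      message(sprintf("-- ensemble member %d/%d (seed %d)",
                      m, config$ensemble, config$seed + m - 1L))
    train_single(sequences, clusters, config,
                 seed = config$seed + m - 1L, verbose = verbose)
  })
}

#' Cluster DNA sequences by twin contrastive learning of FCGR images
#'
#' The top-level fitting interface: trains an ensemble of convolutional
#' twin-contrastive models on mimic-pair augmentations of the input
#' sequences, aligns the ensemble members' cluster indices to the first
#' member by Hungarian matching of hard-assignment agreement, combines
#' them by soft (default) or hard majority voting, and returns the fitted
#' clustering. Ground-truth labels play no role here; use
#' [hungarian_accuracy()] afterwards to score against a reference.
#'
#' @param sequences Named character vector of DNA sequences, e.g. from
#'   [read_fasta()].
#' @param clusters Target number of clusters C (>= 2). Like most
#'   centroid-style methods (and unlike density-based clustering), the
#'   method needs the cluster count up front.
#' @param config A [training_config()].
#' @param voting `"soft"` (average aligned probabilities, default) or
#'   `"hard"` (modal aligned label).
#' @param verbose Epoch-print interval, see [train_single()].
#' @return An object of class `fcgr_tcc` with components `cluster`
#'   (integer assignments 1..C), `probabilities` (aligned ensemble-mean
#'   assignment matrix), `models`, `alignments`, `voting`, `config` and
#'   `call`. Supports `print`, `summary`, `plot` (loss curves),
#'   `fitted` and `predict`.
#' @examples
#' \donttest{
#' spec <- synthetic_spec(mode = "markov_signature", clusters = 2,
#'                        size = 10, length_range = c(400, 600),
#'                        signature_strength = 0.8, seed = 7)
#' dat <- generate_dataset(spec)
#' cfg <- training_config(epochs = 5, batch_size = 20, ensemble = 1)
#' fit <- fcgr_tcc(dat$sequences, clusters = 2, config = cfg)
#' table(fit$cluster, dat$labels$label)
#' }
#' @export
fcgr_tcc <- function(sequences, clusters, config = training_config(),
                     voting = c("soft", "hard"), verbose = 0L) {
  voting <- match.arg(voting)
  models <- train_ensemble(sequences, clusters, config, verbose = verbose)
  preds <- lapply(models, predict_probabilities, sequences = sequences)
  perms <- lapply(preds, align_clusters, reference = preds[[1L]])
  if (voting == "soft") {
    vote <- soft_vote(preds)
  } else {
    vote <- hard_vote(preds)
  }
  structure(list(cluster = vote$cluster, probabilities = vote$probabilities,
                 models = models, alignments = perms, voting = voting,
                 config = config, n = length(sequences),
                 ids = names(sequences), call = match.call()),
            class = "fcgr_tcc")
}

#' @export
print.fcgr_tcc <- function(x, ...) {
  cat(sprintf("FCGR twin-contrastive clustering: %d sequences, %d clusters, %d-model %s vote\n",
              x$n, ncol(x$probabilities), length(x$models), x$voting))
  cat("cluster sizes:\n")
  print(table(cluster = x$cluster))
  invisible(x)
}

#' @export
summary.fcgr_tcc <- function(object, ...) {
  cat(sprintf("FCGR twin-contrastive clustering of %d sequences into %d clusters\n",
              object$n, ncol(object$probabilities)))
  cat(sprintf("ensemble: %d models (seeds %s), %s voting\n",
              length(object$models),
              paste(vapply(object$models, `[[`, 1L, "seed"), collapse = ", "),
              object$voting))
  cat(sprintf("epochs: %d, batch size: %d, k = %d\n",
              object$config$epochs, object$config$batch_size,
              object$config$k))
  cat("cluster sizes:\n")
  print(table(cluster = object$cluster))
  cat(sprintf("mean maximum membership probability: %.3f\n",
              mean(apply(object$probabilities, 1L, max))))
  invisible(object)
}

#' @export
fitted.fcgr_tcc <- function(object, ...) object$probabilities

#' Predict cluster memberships for new sequences
#'
#' Runs every ensemble member on the new sequences in eval mode, applies
#' the cluster alignment fixed at fit time and combines the members with
#' the fit's voting rule.
#'
#' @param object A fitted `fcgr_tcc` object.
#' @param newdata Named character vector of sequences; defaults to
#'   refusing (the fit already stores assignments for its own data).
#' @param type `"class"` for hard labels, `"prob"` for the ensemble-mean
#'   assignment matrix.
#' @param ... Unused.
#' @export
predict.fcgr_tcc <- function(object, newdata = NULL,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "class") return(object$cluster)
    return(object$probabilities)
  }
  preds <- lapply(object$models, predict_probabilities,
                  sequences = newdata)
  aligned <- Map(.apply_alignment, preds, object$alignments)
  if (object$voting == "soft") {
    mean_p <- Reduce(`+`, aligned) / length(aligned)
    labels <- max.col(mean_p, ties.method = "first")
  } else {
    hard <- vapply(aligned, function(P)
      max.col(P, ties.method = "first"), integer(nrow(aligned[[1L]])))
    hard <- matrix(hard, ncol = length(aligned))
    labels <- apply(hard, 1L, function(v)
      which.max(tabulate(v, nbins = ncol(object$probabilities))))
    mean_p <- Reduce(`+`, aligned) / length(aligned)
  }
  if (type == "class") stats::setNames(labels, names(newdata)) else mean_p
}

#' @export
plot.fcgr_tcc <- function(x, ...) {
  hs <- lapply(x$models, `[[`, "history")
  if (all(vapply(hs, nrow, 1L) == 0L)) {
    warning("no training history to plot (epochs = 0)")
    return(invisible(x))
  }
  ylim <- range(unlist(lapply(hs, function(h) h$l_train)))
  xlim <- c(1, max(vapply(hs, nrow, 1L)))
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "epoch",
                 ylab = "twin contrastive loss",
                 main = "training loss per ensemble member", ...)
  for (i in seq_along(hs))
    graphics::lines(hs[[i]]$epoch, hs[[i]]$l_train, col = i)
  graphics::legend("topright", legend = paste("seed",
                   vapply(x$models, `[[`, 1L, "seed")),
                   col = seq_along(hs), lty = 1, bty = "n")
  invisible(x)
}

#' Save / load a trained model
#'
#' Checkpoints hold all weights, batch-norm running statistics, the
#' architecture configuration and the seed, so a reloaded model reproduces
#' predictions exactly.
#'
#' @param model A `tcc_model`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, c("tcc_model", "fcgr_tcc")))
    stop("model must be a 'tcc_model' or 'fcgr_tcc' object")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  m <- readRDS(path)
  if (!inherits(m, c("tcc_model", "fcgr_tcc")))
    stop("file does not contain a saved model: ", path)
  m
}
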