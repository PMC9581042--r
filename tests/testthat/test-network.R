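# Network forward pass, scoring, ensembles and learning capacity.

ns <- asNamespace("interpeprank")

# tiny labeled graph set reused across blocks
tiny_graphs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pd <- ipr_make_planted_dataset(n_targets = 2, decoys_per_target = 10,
                                     seed = 77, receptor_len_range = c(30L, 34L),
                                     peptide_len_range = c(5L, 6L), msa_depth = 6)
      cache <<- pd
    }
    cache
  }
})

test_that("network configuration validates and round-trips through YAML", {
  cfg <- ipr_network_config(n_bins = 3, embedding_dim = 5,
                            conv_channels = c(8L, 12L), dense_sizes = c(16L, 8L),
                            pooling = "sum", edge_dropout = 0.2)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), path)
  back <- do.call(ipr_network_config, yaml::read_yaml(path))
  expect_equal(back, cfg)
  expect_error(ipr_network_config(n_bins = 5), "n_bins")
  expect_error(ipr_network_config(edge_dropout = 1), "edge_dropout")
})

test_that("bin centers and score expectation", {
  expect_equal(ipr_bin_centers(4), c(0.125, 0.375, 0.625, 0.875))
  expect_equal(ipr_bin_centers(2), c(0.25, 0.75))
  # score bounded by the extreme bin centers for any simplex
  set.seed(1)
  for (nb in 2:4) {
    p <- matrix(rexp(10 * nb), 10L)
    p <- p / rowSums(p)
    s <- ipr_score_from_probs(p)
    expect_true(all(s >= (0.5 / nb) - 1e-12 & s <= 1 - 0.5 / nb + 1e-12))
  }
  expect_error(ipr_score_from_probs(c(0.5, 0.2)), "simplex")
})

test_that("forward pass: simplex output, padding invariance, equivariance", {
  pd <- tiny_graphs()
  cfg <- ipr_network_config(conv_channels = c(8L, 8L), embedding_dim = 4L,
                            dense_sizes = c(12L, 6L))
  params <- ns$init_params(cfg, seed = 5)
  fw <- ns$nn_forward(ns$ipr_batch(pd$graphs[1:4]), params, cfg)
  expect_equal(unname(rowSums(fw$probs)), rep(1, 4L), tolerance = 1e-9)

  # same residues, different padding: identical probabilities
  cx <- ipr_make_toy_complex(40, 5, seed = 9)
  prof <- ipr_profile(ipr_make_toy_msa(paste(vapply(cx$receptor, `[[`, "", "aa1"),
                                             collapse = ""), depth = 6, seed = 2))
  g100 <- suppressWarnings(ipr_featurize(cx, prof, max_nodes = 100))
  g120 <- suppressWarnings(ipr_featurize(cx, prof, max_nodes = 120))
  p100 <- ns$nn_forward(ns$ipr_batch(list(g100)), params, cfg)$probs
  p120 <- ns$nn_forward(ns$ipr_batch(list(g120)), params, cfg)$probs
  expect_equal(p100, p120, tolerance = 1e-6)
  expect_equal(which.max(p100), which.max(p120))

  # permuting real node order (with consistent edges) leaves pooling unchanged
  n <- sum(g100$node_mask)
  set.seed(4); perm <- sample(n)
  gp <- g100
  gp$node_features[seq_len(n), ] <- g100$node_features[perm, ]
  gp$edge_features[seq_len(n), seq_len(n), ] <- g100$edge_features[perm, perm, ]
  gp$node_index <- g100$node_index[perm, ]
  pp <- ns$nn_forward(ns$ipr_batch(list(gp)), params, cfg)$probs
  expect_equal(pp, p100, tolerance = 1e-5)
})

test_that("embedding maps identical residues identically and widths add up", {
  pd <- tiny_graphs()
  cfg <- ipr_network_config(embedding_dim = 6L, conv_channels = 8L)
  params <- ns$init_params(cfg, seed = 2)
  batch <- ns$ipr_batch(pd$graphs[1L])
  H0 <- cbind(batch$X[, 1:21] %*% params$We, batch$X[, 22:64])
  expect_equal(ncol(H0), 6L + 43L)
  same <- which(batch$X[, 1L] == 1)  # all alanines embed identically
  if (length(same) >= 2L)
    expect_equal(H0[same[1L], 1:6], H0[same[2L], 1:6])
})

test_that("edge-conditioned convolution matches a brute-force loop oracle", {
  # 3-node hand-sized graph with fixed tiny weights
  cfg <- ipr_network_config(embedding_dim = 2L, conv_channels = 3L,
                            dense_sizes = c(4L, 3L), filter_hidden = 2L)
  params <- ns$init_params(cfg, seed = 8)
  pd <- tiny_graphs()
  g <- pd$graphs[[2L]]
  n <- 3L
  gg <- g
  gg$node_features <- g$node_features[1:3, , drop = FALSE]
  gg$edge_features <- g$edge_features[1:3, 1:3, , drop = FALSE]
  gg$node_mask <- rep(TRUE, 3L)
  gg$node_index <- g$node_index[1:3, ]
  batch <- ns$ipr_batch(list(gg))
  fw <- ns$nn_forward(batch, params, cfg, keep_cache = TRUE)
  H1 <- fw$cache$Hs[[1L]]

  # independent re-implementation: explicit loops over nodes and edges
  X <- gg$node_features
  H0 <- cbind(X[, 1:21] %*% params$We, X[, 22:64])
  pl <- params$conv[[1L]]
  oracle <- matrix(0, n, 3L)
  for (i in 1:n) {
    agg <- numeric(3L); deg <- 0L
    for (j in 1:n) {
      e <- gg$edge_features[i, j, ]
      if (e[["identity"]] == 0) next
      deg <- deg + 1L
      gact <- pmax(t(pl$FW1) %*% e + pl$Fb1, 0)
      theta <- t(pl$FW2) %*% gact + pl$Fb2
      Theta <- matrix(theta, 3L, nrow(pl$Wroot))
      agg <- agg + as.numeric(Theta %*% H0[j, ])
    }
    z <- as.numeric(t(pl$Wroot) %*% H0[i, ]) + agg / max(deg, 1L) + pl$b
    oracle[i, ] <- pmax(z, 0)
  }
  expect_equal(H1, oracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("message passing is local: no edges means no mixing", {
  cfg <- ipr_network_config(conv_channels = 8L, embedding_dim = 4L,
                            dense_sizes = c(6L, 4L))
  params <- ns$init_params(cfg, seed = 3)
  pd <- tiny_graphs()
  g <- pd$graphs[[1L]]
  # zero out the whole edge tensor: output driven by root term and bias only
  gz <- g
  gz$edge_features[] <- 0
  fw <- ns$nn_forward(ns$ipr_batch(list(gz)), params, cfg, keep_cache = TRUE)
  H0 <- fw$cache$layers[[1L]]$H_in
  pl <- params$conv[[1L]]
  expected <- pmax(H0 %*% pl$Wroot +
                     matrix(pl$b, nrow(H0), 8L, byrow = TRUE), 0)
  expect_equal(fw$cache$Hs[[1L]], expected, tolerance = 1e-12)

  # two graphs in one batch: perturbing one cannot change the other
  b2 <- ns$ipr_batch(pd$graphs[1:2])
  p2 <- ns$nn_forward(b2, params, cfg)$probs
  mod <- pd$graphs[[2L]]
  mod$node_features[1:10, 22:42] <- 5
  b2b <- ns$ipr_batch(list(pd$graphs[[1L]], mod))
  p2b <- ns$nn_forward(b2b, params, cfg)$probs
  expect_equal(p2[1L, ], p2b[1L, ])
  expect_false(isTRUE(all.equal(p2[2L, ], p2b[2L, ])))
})

test_that("training is seeded-reproducible and inert at zero learning rate", {
  pd <- tiny_graphs()
  cfg <- ipr_network_config(conv_channels = c(8L, 8L), embedding_dim = 4L,
                            dense_sizes = c(8L, 6L))
  f1 <- interpeprank(pd$graphs, config = cfg, max_epochs = 3, seed = 42)
  f2 <- interpeprank(pd$graphs, config = cfg, max_epochs = 3, seed = 42)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)

  z1 <- interpeprank(pd$graphs, config = cfg, max_epochs = 1,
                     learning_rate = 0, seed = 7)
  z5 <- interpeprank(pd$graphs, config = cfg, max_epochs = 5,
                     learning_rate = 0, seed = 7)
  expect_equal(z1$weights, z5$weights, tolerance = 1e-12)
})

test_that("a small network can overfit 50 decoys to near-perfect accuracy", {
  pd <- ipr_make_planted_dataset(n_targets = 1, decoys_per_target = 50,
                                 seed = 55, receptor_len_range = c(36L, 40L),
                                 peptide_len_range = c(6L, 7L), msa_depth = 6)
  cfg <- ipr_network_config(conv_channels = c(16L, 16L), embedding_dim = 6L,
                            dense_sizes = c(24L, 12L), edge_dropout = 0)
  fit <- interpeprank(pd$graphs, config = cfg, max_epochs = 150,
                      batch_size = 50, seed = 12)
  probs <- predict(fit, pd$graphs, type = "probs")
  pred_bin <- max.col(probs) - 1L
  true_bin <- ipr_assign_bin(pd$labels$lrmsd_norm, 2L)
  expect_gte(mean(pred_bin == true_bin), 0.99)
})

test_that("ensembles average member scores", {
  pd <- tiny_graphs()
  cfg <- ipr_network_config(conv_channels = 8L, embedding_dim = 4L,
                            dense_sizes = c(6L, 4L))
  m1 <- interpeprank(pd$graphs, config = cfg, max_epochs = 2, seed = 1)
  m2 <- interpeprank(pd$graphs, config = cfg, max_epochs = 2, seed = 2)
  ens <- ipr_ensemble(m1, m2)
  s1 <- predict(m1, pd$graphs); s2 <- predict(m2, pd$graphs)
  expect_equal(unname(predict(ens, pd$graphs)), unname((s1 + s2) / 2))
  # single member: identity; identical members: the member score
  expect_equal(predict(ipr_ensemble(m1), pd$graphs), s1)
  expect_equal(predict(ipr_ensemble(m1, m1, m1), pd$graphs), s1)
  expect_error(ipr_ensemble(list()), "at least one")
})

test_that("fit object methods and checkpoints work", {
  pd <- tiny_graphs()
  cfg <- ipr_network_config(conv_channels = 8L, embedding_dim = 4L,
                            dense_sizes = c(6L, 4L))
  fit <- interpeprank(pd$graphs, config = cfg, max_epochs = 2, seed = 1)
  expect_output(print(fit), "decoy scorer")
  expect_output(print(summary(fit)), "parameters")
  expect_named(fitted(fit))
  expect_equal(unname(residuals(fit)),
               unname(fitted(fit)) - pd$labels$lrmsd_norm[
                 match(names(fitted(fit)), pd$labels$id)])
  expect_type(coef(fit), "list")

  path <- withr::local_tempfile(fileext = ".rds")
  ipr_save_model(fit, path)
  expect_equal(predict(ipr_load_model(path), pd$graphs[1:2]),
               predict(fit, pd$graphs[1:2]))

  dir <- withr::local_tempdir()
  ens <- ipr_ensemble(fit, fit)
  ipr_write_ensemble(ens, dir)
  back <- ipr_read_ensemble(dir)
  expect_equal(predict(back, pd$graphs[1:2]), predict(ens, pd$graphs[1:2]))
})
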