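# Decoy graph construction: node selection, edge channels, featurization,
# padding and edge dropout.

test_that("node selection keeps the peptide and the nearest receptor residues", {
  # under the cap: everything kept
  cx <- ipr_make_toy_complex(40, 5, seed = 1)
  sel <- suppressWarnings(ipr_select_nodes(cx, max_nodes = 100))
  expect_length(sel$residues, 45L)

  # collinear receptor with known distances: brute-force nearest-k oracle
  rec <- lapply(1:30, function(i) point_res("A", i, 2 * i))
  pep <- list(point_res("B", 1, 0))
  cx2 <- point_complex(rec, pep)
  sel2 <- ipr_select_nodes(cx2, max_nodes = 11)
  dists <- vapply(rec, function(r) abs(r$xyz[1L, 1L]), numeric(1L))
  oracle <- sort(order(dists)[1:10])
  expect_equal(sel2$receptor, oracle)
  # order: peptide first, then receptor in chain order
  expect_equal(vapply(sel2$residues, `[[`, character(1L), "chain_id"),
               c("B", rep("A", 10L)))

  # ties at equal distance break toward the lower residue index
  rec3 <- list(point_res("A", 1, -3), point_res("A", 2, 3), point_res("A", 3, -3.0))
  cx3 <- point_complex(rec3, pep)
  sel3 <- ipr_select_nodes(cx3, max_nodes = 3)
  expect_equal(sel3$receptor, c(1L, 2L))

  expect_error(ipr_select_nodes(cx2, max_nodes = 0), "peptide")
})

test_that("edge channels: self, peptide bond, 4.5 A proximity, identity union", {
  two_at <- function(d) list(point_res("A", 1, 0), point_res("B", 1, d))
  for (d in c(4.4, 4.5)) {
    E <- ipr_build_edges(two_at(d))
    expect_equal(unname(E[1L, 2L, "proximity"]), 1, info = sprintf("d = %.1f", d))
    expect_equal(unname(E[2L, 1L, "proximity"]), 1)
  }
  E <- ipr_build_edges(two_at(4.6))
  expect_equal(unname(E[1L, 2L, "proximity"]), 0)

  # single residue: only self + identity on the diagonal
  E1 <- ipr_build_edges(list(point_res("A", 1, 0)))
  expect_equal(E1[1L, 1L, ], c(self = 1, sequence = 0, proximity = 0, identity = 1))
  expect_equal(sum(E1), 2)

  # sequence edges need a genuine C-N peptide bond in the same chain
  bonded <- list(
    ipr_residue("A", 1, "ALA", matrix(c(0, 0, 0, 1.4, 0, 0), 2L, 3L, byrow = TRUE,
                                      dimnames = list(c("CA", "C"), NULL))),
    ipr_residue("A", 2, "ALA", matrix(c(2.7, 0, 0, 4, 0, 0), 2L, 3L, byrow = TRUE,
                                      dimnames = list(c("N", "CA"), NULL))))
  expect_equal(unname(ipr_build_edges(bonded)[1L, 2L, "sequence"]), 1)
  # same geometry, different chains: no bond
  crossed <- bonded; crossed[[2L]]$chain_id <- "B"
  expect_equal(unname(ipr_build_edges(crossed)[1L, 2L, "sequence"]), 0)
  # chain break (C-N far apart): no bond even within a chain
  broken <- bonded
  broken[[2L]]$xyz <- broken[[2L]]$xyz + 5
  expect_equal(unname(ipr_build_edges(broken)[1L, 2L, "sequence"]), 0)
})

test_that("edge sets match a brute-force all-pairs distance oracle", {
  set.seed(11)
  for (rep in 1:3) {
    res <- lapply(1:8, function(i) {
      natoms <- sample(1:3, 1L)
      xyz <- matrix(runif(3L * natoms, 0, 12), natoms, 3L)
      rownames(xyz) <- c("CA", "CB", "CG")[seq_len(natoms)]
      ipr_residue("A", i, "ALA", xyz)
    })
    E <- ipr_build_edges(res)
    for (i in 1:8) for (j in 1:8) {
      if (i == j) next
      dmin <- min(vapply(seq_len(nrow(res[[i]]$xyz)), function(a)
        min(sqrt(rowSums(sweep(res[[j]]$xyz, 2L, res[[i]]$xyz[a, ])^2))),
        numeric(1L)))
      expect_equal(unname(E[i, j, "proximity"]), as.numeric(dmin <= 4.5))
    }
    expect_equal(E[, , "identity"],
                 pmax(E[, , "self"], E[, , "sequence"], E[, , "proximity"]))
  }
})

test_that("featurization assembles the 64-column node matrix and padding", {
  cx <- ipr_make_toy_complex(40, 5, seed = 2)
  msa <- ipr_make_toy_msa(paste(vapply(cx$receptor, `[[`, "", "aa1"),
                                collapse = ""), depth = 10, seed = 3)
  prof <- ipr_profile(msa)
  g <- suppressWarnings(ipr_featurize(cx, prof, max_nodes = 100,
                                      label = list(lrmsd = 2)))
  expect_equal(dim(g$node_features), c(100L, 64L))
  expect_equal(dim(g$edge_features), c(100L, 100L, 4L))
  # peptide rows: indicator 1, evolutionary features exactly zero
  pep_rows <- which(g$node_index$is_peptide)
  expect_equal(g$node_features[pep_rows, 64L], rep(1, 5L))
  expect_equal(sum(abs(g$node_features[pep_rows, 22:63])), 0)
  # receptor rows carry the profile
  expect_equal(g$node_features[6L, 22:42], unname(prof$pssm[1L, ]))
  # padding: all-zero rows, mask false
  expect_false(any(g$node_mask[46:100]))
  expect_equal(sum(abs(g$node_features[46:100, ])), 0)
  expect_equal(sum(abs(g$edge_features[46:100, , ])), 0)
  # label normalization derived from lrmsd
  expect_equal(g$label$lrmsd_norm, 1 / (1 + (2 / 4)^2))

  # profile not covering the receptor errors with the residue
  short <- prof; short$pssm <- prof$pssm[1:10, ]; short$self_entropy <- prof$self_entropy[1:10, ]
  expect_error(suppressWarnings(ipr_featurize(cx, short)), "A11")
})

test_that("featurization is invariant to receptor renumbering", {
  cx <- ipr_make_toy_complex(40, 5, seed = 4)
  prof <- ipr_profile(ipr_make_toy_msa(paste(vapply(cx$receptor, `[[`, "", "aa1"),
                                             collapse = ""), depth = 8, seed = 1))
  g1 <- suppressWarnings(ipr_featurize(cx, prof))
  cx2 <- cx
  cx2$receptor <- lapply(cx$receptor, function(r) { r$res_seq <- r$res_seq + 100L; r })
  g2 <- suppressWarnings(ipr_featurize(cx2, prof))
  expect_identical(g1$node_features, g2$node_features)
  expect_identical(g1$edge_features, g2$edge_features)
})

test_that("edge dropout is seeded, symmetric and hits the target rate", {
  cx <- ipr_make_toy_complex(94, 6, seed = 6)
  prof <- ipr_profile(ipr_make_toy_msa(paste(vapply(cx$receptor, `[[`, "", "aa1"),
                                             collapse = ""), depth = 5, seed = 1))
  g <- ipr_featurize(cx, prof)
  expect_identical(ipr_edge_dropout(g, 0), g)
  d1 <- ipr_edge_dropout(g, 0.2, seed = 9)
  d2 <- ipr_edge_dropout(g, 0.2, seed = 9)
  expect_identical(d1, d2)
  # symmetric pairs dropped together; identity stays the union
  expect_equal(d1$edge_features[, , "identity"], t(d1$edge_features[, , "identity"]))
  expect_equal(d1$edge_features[, , "identity"],
               pmax(d1$edge_features[, , "self"], d1$edge_features[, , "sequence"],
                    d1$edge_features[, , "proximity"]))
  # empirical drop fraction within 3 sigma of the binomial expectation
  idm <- g$edge_features[, , "identity"]
  n_pos <- sum(idm[upper.tri(idm, diag = TRUE)] != 0)
  dropped <- mean(vapply(1:20, function(s) {
    dd <- ipr_edge_dropout(g, 0.2, seed = s)
    1 - sum(dd$edge_features[, , "identity"]) / sum(idm)
  }, numeric(1L)))
  expect_lt(abs(dropped - 0.2), 3 * sqrt(0.2 * 0.8 / (20 * n_pos)))
  expect_error(ipr_edge_dropout(g, 1.2), "rate")
})

test_that("selected nodes capture the full peptide-receptor interface", {
  pd <- small_planted()
  for (g in pd$graphs[seq(1, length(pd$graphs), by = 12)]) {
    n <- sum(g$node_mask)
    prox <- g$edge_features[seq_len(n), seq_len(n), "proximity"]
    is_pep <- g$node_index$is_peptide
    # every proximity contact involving the peptide is inside the node set
    # by construction; check contacts exist and are consistent
    expect_true(all(prox == t(prox)))
  }
  # direct check on an over-cap complex: contacting receptor residues are
  # all selected
  cx <- ipr_make_toy_complex(170, 25, seed = 3)
  ns <- asNamespace("interpeprank")
  d <- ns$residue_min_dist(cx$receptor, cx$peptide)
  contacting <- which(apply(d, 1L, min) <= 4.5)
  sel <- ipr_select_nodes(cx, max_nodes = 100)
  expect_true(all(contacting %in% sel$receptor))
})

test_that("graph containers round-trip with a manifest", {
  pd <- small_planted()
  gs <- pd$graphs[1:5]
  path <- withr::local_tempfile(fileext = ".rds")
  ipr_write_graphs(gs, path)
  back <- ipr_read_graphs(path)
  expect_identical(back, gs)
  man <- read.delim(paste0(path, ".manifest.tsv"))
  expect_equal(nrow(man), 5L)
  expect_equal(man$id, vapply(gs, `[[`, "", "id"))
})
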