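# Decoy graph construction: node selection, edge channels, featurization,
# zero-padding and training-time edge dropout.

EDGE_CHANNELS <- c("self", "sequence", "proximity", "identity")
N_NODE_FEATURES <- 64L  # 21 one-hot + 21 PSSM + 21 self-entropy + 1 peptide flag

#' Select the residues that become graph nodes
#'
#' All peptide residues are always included; if the complex has more than
#' `max_nodes` residues, the receptor residues are ranked by their minimum
#' heavy-atom distance to any peptide heavy atom and the closest
#' `max_nodes - peptide length` are kept (ties broken by lower residue
#' index). Node order is peptide residues in chain order, then the selected
#' receptor residues in chain order.
#'
#' @param complex An [ipr_complex()].
#' @param max_nodes Node cap, 100 by default.
#' @return List with `peptide` (indices into `complex$peptide`), `receptor`
#'   (indices into `complex$receptor`, chain order) and `residues` (the
#'   ordered residue list).
#' @export
ipr_select_nodes <- function(complex, max_nodes = 100L) {
  np <- length(complex$peptide)
  nr <- length(complex$receptor)
  if (np > max_nodes)
    stopf("peptide has %d residues but max_nodes is %d", np, max_nodes)
  if (np + nr <= max_nodes) {
    rec_idx <- seq_len(nr)
  } else {
    d <- residue_min_dist(complex$receptor, complex$peptide)
    dmin <- apply(d, 1L, min)
    keep <- order(dmin, seq_len(nr))[seq_len(max_nodes - np)]
    rec_idx <- sort(keep)
  }
  list(peptide = seq_len(np), receptor = rec_idx,
       residues = c(complex$peptide, complex$receptor[rec_idx]))
}

#' Build the four-channel edge tensor for an ordered residue list
#'
#' Channels (in order): `self` (diagonal of real nodes), `sequence`
#' (peptide-bonded chain neighbours, C-N distance <= `bond_cutoff`),
#' `proximity` (any heavy-atom pair within `proximity_cutoff`, inclusive),
#' and `identity` (the union of the other three). All channels except
#' `self` are symmetric.
#'
#' @param residues Ordered list of [ipr_residue()] records.
#' @param n_pad Padded matrix size (>= number of residues); padded
#'   rows/columns are all zero.
#' @param proximity_cutoff Heavy-atom contact cutoff in Angstrom (4.5).
#' @param bond_cutoff C-N distance (Angstrom) below which consecutive
#'   residues of a chain count as peptide-bonded.
#' @return Numeric array `n_pad x n_pad x 4` with channel dimnames.
#' @export
ipr_build_edges <- function(residues, n_pad = length(residues),
                            proximity_cutoff = 4.5, bond_cutoff = 2.0) {
  n <- length(residues)
  if (n_pad < n) stopf("n_pad (%d) smaller than residue count (%d)", n_pad, n)
  E <- array(0, dim = c(n_pad, n_pad, 4L),
             dimnames = list(NULL, NULL, EDGE_CHANNELS))
  if (n == 0L) return(E)
  E[cbind(seq_len(n), seq_len(n), 1L)] <- 1

  # proximity: residue-level minimum heavy-atom distance
  if (n > 1L) {
    d <- residue_min_dist(residues, residues)
    prox <- (d <= proximity_cutoff)
    diag(prox) <- FALSE
    E[seq_len(n), seq_len(n), "proximity"] <- prox * 1

    # sequence: peptide bond between residues of the same chain
    chains <- vapply(residues, `[[`, character(1L), "chain_id")
    getat <- function(r, nm) {
      if (nm %in% rownames(r$xyz)) r$xyz[nm, ] else NULL
    }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (chains[i] != chains[j]) next
      ci <- getat(residues[[i]], "C"); nj <- getat(residues[[j]], "N")
      cj <- getat(residues[[j]], "C"); ni <- getat(residues[[i]], "N")
      bonded <- (!is.null(ci) && !is.null(nj) && sqrt(sum((ci - nj)^2)) <= bond_cutoff) ||
                (!is.null(cj) && !is.null(ni) && sqrt(sum((cj - ni)^2)) <= bond_cutoff)
      if (bonded) E[i, j, "sequence"] <- E[j, i, "sequence"] <- 1
    }
  }
  E[, , "identity"] <- pmax(E[, , "self"], E[, , "sequence"], E[, , "proximity"])
  E
}

#' Featurize a decoy complex into the padded network input graph
#'
#' Assembles the node feature matrix (columns 1-21 one-hot amino acid,
#' 22-42 PSSM, 43-63 self-entropy, 64 peptide indicator), the 4-channel
#' edge tensor and the padding mask. Peptide residues get all-zero PSSM
#' and self-entropy: peptides are too short for a meaningful alignment.
#'
#' @param complex An [ipr_complex()].
#' @param profile An [ipr_profile()] covering every receptor residue
#'   (row i = receptor residue i).
#' @param max_nodes Padded graph size (default 100).
#' @param label Optional list with decoy metadata, e.g. `lrmsd`,
#'   `target_id`, `group_id`; `lrmsd_norm` is derived when `lrmsd` is given.
#' @param proximity_cutoff,bond_cutoff Passed to [ipr_build_edges()].
#' @return An object of class `ipr_graph`: `node_features`
#'   (max_nodes x 64), `edge_features` (max_nodes x max_nodes x 4),
#'   `node_mask`, `node_index` (chain, res_seq, icode, is_peptide per real
#'   node), `label`, `id`.
#' @export
ipr_featurize <- function(complex, profile, max_nodes = 100L, label = NULL,
                          proximity_cutoff = 4.5, bond_cutoff = 2.0) {
  sel <- ipr_select_nodes(complex, max_nodes)
  res <- sel$residues
  n <- length(res)
  if (nrow(profile$pssm) != length(complex$receptor)) {
    miss <- if (nrow(profile$pssm) < length(complex$receptor))
      residue_key(complex$receptor[[nrow(profile$pssm) + 1L]]) else "<extra rows>"
    stopf("profile has %d positions for %d receptor residues (first uncovered: %s)",
          nrow(profile$pssm), length(complex$receptor), miss)
  }
  np <- length(sel$peptide)
  aa1 <- vapply(res, `[[`, character(1L), "aa1")
  X <- matrix(0, max_nodes, N_NODE_FEATURES)
  X[seq_len(n), 1:21] <- ipr_one_hot(aa1)
  rec_rows <- np + seq_along(sel$receptor)
  X[rec_rows, 22:42] <- profile$pssm[sel$receptor, , drop = FALSE]
  X[rec_rows, 43:63] <- profile$self_entropy[sel$receptor, , drop = FALSE]
  X[seq_len(np), 64] <- 1

  if (!is.null(label) && !is.null(label$lrmsd) && is.null(label$lrmsd_norm))
    label$lrmsd_norm <- ipr_normalize_lrmsd(label$lrmsd)

  structure(list(
    node_features = X,
    edge_features = ipr_build_edges(res, n_pad = max_nodes,
                                    proximity_cutoff = proximity_cutoff,
                                    bond_cutoff = bond_cutoff),
    node_mask = seq_len(max_nodes) <= n,
    node_index = data.frame(
      chain = vapply(res, `[[`, character(1L), "chain_id"),
      res_seq = vapply(res, `[[`, integer(1L), "res_seq"),
      icode = vapply(res, `[[`, character(1L), "icode"),
      is_peptide = seq_len(n) <= np, stringsAsFactors = FALSE),
    label = label,
    id = complex$id), class = "ipr_graph")
}

#' @export
print.ipr_graph <- function(x, ...) {
  cat(sprintf("<ipr_graph '%s'> %d real nodes / %d padded, %d directed edges\n",
              x$id, sum(x$node_mask), length(x$node_mask),
              sum(x$edge_features[, , "identity"] != 0)))
  invisible(x)
}

#' Training-time edge dropout
#'
#' Each real undirected edge position (including self edges) is zeroed
#' across all four channels with probability `rate`; symmetric pairs are
#' dropped together so the identity channel stays the union of the others.
#'
#' @param graph An `ipr_graph`.
#' @param rate Dropout probability in \[0, 1).
#' @param seed Optional seed for a reproducible mask (RNG state restored).
#' @return The graph with dropped edges.
#' @export
ipr_edge_dropout <- function(graph, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stopf("dropout rate must be in [0, 1)")
  if (rate == 0) return(graph)
  with_seed(seed, {
    idm <- graph$edge_features[, , "identity"]
    pos <- which(upper.tri(idm, diag = TRUE) & idm != 0, arr.ind = TRUE)
    drop <- runif(nrow(pos)) < rate
    if (any(drop)) {
      pd <- pos[drop, , drop = FALSE]
      for (k in seq_len(4L)) {
        graph$edge_features[cbind(pd, k)] <- 0
        graph$edge_features[cbind(pd[, 2:1, drop = FALSE], k)] <- 0
      }
    }
  })
  graph
}

#' Write / read a decoy graph set
#'
#' Graph sets are stored as one serialized container file per set, with a
#' sidecar TSV manifest (`<path>.manifest.tsv`) mapping decoy id to its
#' index in the container plus its label columns.
#'
#' @param graphs List of `ipr_graph` objects.
#' @param path Container file (conventionally `.rds`).
#' @return `path` (write) or the list of graphs (read).
#' @export
ipr_write_graphs <- function(graphs, path) {
  saveRDS(graphs, path)
  man <- data.frame(
    id = vapply(graphs, `[[`, character(1L), "id"),
    index = seq_along(graphs),
    n_nodes = vapply(graphs, function(g) sum(g$node_mask), integer(1L)),
    target_id = vapply(graphs, function(g) g$label$target_id %||% NA_character_, character(1L)),
    group_id = vapply(graphs, function(g) g$label$group_id %||% NA_character_, character(1L)),
    lrmsd = vapply(graphs, function(g) g$label$lrmsd %||% NA_real_, numeric(1L)),
    stringsAsFactors = FALSE)
  write_tsv(man, paste0(path, ".manifest.tsv"))
  invisible(path)
}

#' @rdname ipr_write_graphs
#' @export
ipr_read_graphs <- function(path) readRDS(path)
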