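# Deterministic synthetic fixtures: toy peptide-protein complexes with an
# idealized backbone, rigid-perturbation decoy sets with controlled LRMSD,
# mutational toy alignments, and a separable "planted-signal" labeled
# dataset for training smoke tests.
#
# Geometry: residues carry backbone heavy atoms (N, CA, C, O) placed along a
# parametric curve at arc-length spacings N-CA 1.46, CA-C 1.52, C-N(next)
# 1.33 Angstrom, so consecutive residues of a segment are peptide-bonded
# (C-N < 2 Angstrom) by construction. The receptor is two parallel
# alpha-helix segments (CA radius 2.3, rise 1.5, 100 degrees per residue)
# separated by a groove; the native peptide is an extended strand lying in
# the groove, in heavy-atom contact with both segments.

HELIX_RADIUS <- 2.3
RES_ARC <- 1.46 + 1.52 + 1.33          # backbone arc length per residue
HELIX_ANG_RATE <- (100 * pi / 180) / RES_ARC
HELIX_RISE_RATE <- 1.5 / RES_ARC

# Backbone atoms of `n` residues along an ideal alpha-helix with axis
# parallel to z through (x0, y0).
helix_residues <- function(n, x0 = 0, y0 = 0, phase = 0, z0 = NULL) {
  if (is.null(z0)) z0 <- -(n * 1.5) / 2
  point <- function(s) {
    th <- phase + HELIX_ANG_RATE * s
    c(x0 + HELIX_RADIUS * cos(th), y0 + HELIX_RADIUS * sin(th),
      z0 + HELIX_RISE_RATE * s)
  }
  lapply(seq_len(n), function(i) {
    s0 <- (i - 1L) * RES_ARC
    N <- point(s0); CA <- point(s0 + 1.46); C <- point(s0 + 2.98)
    thC <- phase + HELIX_ANG_RATE * (s0 + 2.98)
    O <- C + 1.23 * c(cos(thC), sin(thC), 0)
    rbind(N = N, CA = CA, C = C, O = O)
  })
}

# Extended strand along z through (x0, y0); carbonyl O points along +y.
strand_residues <- function(n, x0, y0 = 0, z0 = NULL) {
  if (is.null(z0)) z0 <- -(n * RES_ARC) / 2
  lapply(seq_len(n), function(i) {
    s0 <- z0 + (i - 1L) * RES_ARC
    N <- c(x0, y0, s0); CA <- c(x0, y0, s0 + 1.46); C <- c(x0, y0, s0 + 2.98)
    O <- C + c(0, 1.23, 0)
    rbind(N = N, CA = CA, C = C, O = O)
  })
}

residues_from_atoms <- function(atom_list, seq1, chain, start_res = 1L) {
  lapply(seq_along(atom_list), function(i)
    ipr_residue(chain, start_res + i - 1L, AA1_TO_3[seq1[i]], atom_list[[i]]))
}

#' Generate a toy native peptide-protein complex
#'
#' Idealized backbone geometry: the receptor (chain A) is two parallel
#' helical segments whose gap forms a binding groove; the peptide (chain B)
#' is an extended strand placed in the groove, guaranteeing a non-empty
#' heavy-atom interface at 4.5 Angstrom. Sequences are drawn uniformly from
#' the 20 amino acids under the seed; output is byte-reproducible.
#'
#' @param receptor_len,peptide_len Residue counts.
#' @param groove_gap Distance (Angstrom) between the two helix axes; the
#'   peptide sits midway.
#' @param seed RNG seed for the sequences.
#' @param id Complex identifier.
#' @return An [ipr_complex()].
#' @export
ipr_make_toy_complex <- function(receptor_len = 80L, peptide_len = 9L,
                                 groove_gap = 13, seed = 1L, id = "toy") {
  with_seed(seed, {
    n1 <- ceiling(receptor_len / 2); n2 <- receptor_len - n1
    rec_seq <- sample(AA20, receptor_len, replace = TRUE)
    pep_seq <- sample(AA20, peptide_len, replace = TRUE)
    atoms <- c(helix_residues(n1, 0, 0, phase = 0),
               if (n2 > 0) helix_residues(n2, groove_gap, 0, phase = pi))
    receptor <- residues_from_atoms(atoms, rec_seq, "A")
    peptide <- residues_from_atoms(strand_residues(peptide_len, groove_gap / 2),
                                   pep_seq, "B")
    suppressWarnings(ipr_complex(receptor, peptide, id = id))
  })
}

rotation_about_axis <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

transform_peptide <- function(native, R = diag(3L), t = c(0, 0, 0), id) {
  P <- do.call(rbind, lapply(native$peptide, `[[`, "xyz"))
  ctr <- colMeans(P)
  peptide <- lapply(native$peptide, function(res) {
    res$xyz <- sweep(sweep(res$xyz, 2L, ctr) %*% t(R), 2L, ctr + t, `+`)
    res
  })
  suppressWarnings(ipr_complex(native$receptor, peptide, id = id))
}

# RMS displacement of the peptide backbone under rotation R about its centroid.
peptide_rot_rms <- function(native, R) {
  P <- do.call(rbind, lapply(native$peptide, `[[`, "xyz"))
  Pc <- sweep(P, 2L, colMeans(P))
  sqrt(mean(rowSums((Pc %*% t(R) - Pc)^2)))
}

#' Generate a rigid-perturbation decoy set with controlled LRMSD
#'
#' Each decoy is the native with the peptide rigidly transformed: an
#' optional rotation about the peptide centroid plus a translation whose
#' magnitude is solved analytically so that the achieved LRMSD equals the
#' requested target (rotation about the centroid and translation contribute
#' orthogonally to the squared displacement). Every decoy is verified with
#' [ipr_lrmsd()]; misses beyond 10 percent are retried and then error.
#'
#' @param native An [ipr_complex()].
#' @param lrmsd_targets Numeric vector of target LRMSD values (Angstrom).
#' @param seed RNG seed.
#' @param rotate Include a random rotation component (pure translations are
#'   exact by construction).
#' @param direction Optional fixed translation direction (3-vector);
#'   random per decoy when `NULL`.
#' @return List with `decoys` (list of complexes) and `labels` (data.frame
#'   `decoy_id`, `target_lrmsd`, `lrmsd`, `is_correct`).
#' @export
ipr_make_decoy_set <- function(native, lrmsd_targets, seed = 1L,
                               rotate = TRUE, direction = NULL) {
  with_seed(seed, {
    decoys <- vector("list", length(lrmsd_targets))
    achieved <- numeric(length(lrmsd_targets))
    for (k in seq_along(lrmsd_targets)) {
      target <- lrmsd_targets[k]
      id <- sprintf("%s_d%03d", native$id, k)
      if (target <= 0) {
        decoys[[k]] <- transform_peptide(native, id = id)
        achieved[k] <- ipr_lrmsd(decoys[[k]], native)
        next
      }
      ok <- FALSE
      for (attempt in 1:5) {
        R <- diag(3L); rot_rms <- 0
        if (rotate) {
          axis <- rnorm(3L)
          ang <- runif(1L, 0, 25 * pi / 180)
          R <- rotation_about_axis(axis, ang)
          rot_rms <- peptide_rot_rms(native, R)
          while (rot_rms > 0.8 * target) {
            ang <- ang * 0.6
            R <- rotation_about_axis(axis, ang)
            rot_rms <- peptide_rot_rms(native, R)
          }
        }
        dir <- if (is.null(direction)) rnorm(3L) else direction
        dir <- dir / sqrt(sum(dir^2))
        t <- dir * sqrt(target^2 - rot_rms^2)
        cand <- transform_peptide(native, R, t, id = id)
        got <- ipr_lrmsd(cand, native)
        if (abs(got - target) <= 0.1 * target) {
          decoys[[k]] <- cand; achieved[k] <- got; ok <- TRUE; break
        }
      }
      if (!ok)
        stopf("could not realize LRMSD target %.2f Angstrom within 10%%", target)
    }
    list(decoys = decoys,
         labels = data.frame(
           decoy_id = vapply(decoys, `[[`, character(1L), "id"),
           target_lrmsd = lrmsd_targets, lrmsd = achieved,
           is_correct = achieved < 4.0, stringsAsFactors = FALSE))
  })
}

#' Generate a mutational toy alignment for a query sequence
#'
#' Rows are seeded point-mutated copies of the query: each position mutates
#' with probability `mutation_rate` to a uniformly drawn amino acid, and is
#' replaced by a gap with probability `gap_rate`. The first row is the
#' unmutated query, so conserved columns (rate 0) give frequency 1 for the
#' query letter.
#'
#' @param query Ungapped amino-acid string.
#' @param depth Number of alignment rows (including the query).
#' @param mutation_rate,gap_rate Per-position probabilities in \[0, 1).
#' @param seed RNG seed.
#' @return An `ipr_msa`.
#' @export
ipr_make_toy_msa <- function(query, depth = 30L, mutation_rate = 0.1,
                             gap_rate = 0, seed = 1L) {
  if (mutation_rate < 0 || mutation_rate >= 1) stopf("mutation_rate must be in [0, 1)")
  with_seed(seed, {
    q <- strsplit(toupper(query), "")[[1L]]
    L <- length(q)
    rows <- c(paste(q, collapse = ""),
              vapply(seq_len(max(depth - 1L, 0L)), function(i) {
                r <- q
                mut <- runif(L) < mutation_rate
                r[mut] <- sample(AA20, sum(mut), replace = TRUE)
                gap <- runif(L) < gap_rate
                r[gap] <- "-"
                paste(r, collapse = "")
              }, character(1L)))
    ipr_msa(rows, names = c("query", sprintf("hom%03d", seq_len(length(rows) - 1L))))
  })
}

# One synthetic target: native complex, toy MSA, and a class-balanced decoy
# set where correct decoys (LRMSD < 4) stay in the native groove and
# incorrect decoys (LRMSD >= 8) are translated onto an outside face of one
# of the two receptor segments, carrying systematically fewer
# peptide-receptor contacts. This geometric difference is the planted,
# target-transferable signal.
gen_planted_target <- function(tid, seed, decoys_per_target = 100L,
                               receptor_len_range = c(56L, 76L),
                               peptide_len_range = c(8L, 12L),
                               msa_depth = 30L, mutation_rate = 0.15,
                               groove_gap = 13) {
  with_seed(seed, {
    rl <- sample(receptor_len_range[1L]:receptor_len_range[2L], 1L)
    pl <- sample(peptide_len_range[1L]:peptide_len_range[2L], 1L)
    seeds <- sample.int(1e6, 3L)
    native <- ipr_make_toy_complex(rl, pl, groove_gap, seed = seeds[1L], id = tid)
    msa <- ipr_make_toy_msa(complex_sequence(native$receptor), msa_depth,
                            mutation_rate, seed = seeds[2L])
    n_cor <- ceiling(decoys_per_target / 2)
    n_inc <- decoys_per_target - n_cor
    cor_set <- ipr_make_decoy_set(native, runif(n_cor, 0.5, 3.5),
                                  seed = seeds[3L], rotate = TRUE)
    # incorrect decoys: pure translation onto an outside face
    inc <- lapply(seq_len(n_inc), function(k) {
      side <- sample(c(-1, 1), 1L)
      t <- c(side * (groove_gap + runif(1L, 1, 6)),
             runif(1L, -2, 2), runif(1L, -4, 4))
      transform_peptide(native, t = t,
                        id = sprintf("%s_d%03d", tid, n_cor + k))
    })
    decoys <- c(cor_set$decoys, inc)
    lrmsd <- c(cor_set$labels$lrmsd,
               vapply(inc, ipr_lrmsd, numeric(1L), native = native))
    list(native = native, msa = msa, decoys = decoys, lrmsd = lrmsd)
  })
}

#' Generate the planted-signal labeled decoy dataset
#'
#' For each synthetic target, half the decoys are correct (LRMSD < 4
#' Angstrom, native-like groove contacts with both receptor segments) and
#' half are incorrect (LRMSD >= 8 Angstrom, translated onto an outside
#' receptor face with systematically fewer peptide-receptor proximity
#' edges). The contact-density difference is a geometric signal that
#' transfers across targets, so a small network can learn it and be
#' evaluated on held-out targets. Targets are paired into homology groups
#' (`group_id`) for grouped splitting.
#'
#' @param n_targets Number of synthetic targets.
#' @param decoys_per_target Decoys per target (split evenly between
#'   classes).
#' @param seed Master RNG seed; everything below derives from it.
#' @param max_nodes Padded graph size.
#' @param ... Passed to the per-target generator (receptor/peptide length
#'   ranges, MSA depth, mutation rate).
#' @return List with `graphs` (labeled `ipr_graph` list), `labels`
#'   (data.frame `id`, `target_id`, `group_id`, `lrmsd`, `lrmsd_norm`,
#'   `is_correct`) and `targets` (per-target natives and MSAs).
#' @export
ipr_make_planted_dataset <- function(n_targets = 20L, decoys_per_target = 100L,
                                     seed = 1L, max_nodes = 100L, ...) {
  stopifnot(n_targets >= 1L, decoys_per_target >= 2L)
  graphs <- list(); rows <- list(); targets <- list()
  for (t in seq_len(n_targets)) {
    tid <- sprintf("t%02d", t)
    grp <- sprintf("g%02d", ceiling(t / 2))
    gt <- gen_planted_target(tid, seed = seed * 1000L + t,
                             decoys_per_target = decoys_per_target, ...)
    profile <- ipr_profile(gt$msa)
    for (k in seq_along(gt$decoys)) {
      g <- ipr_featurize(gt$decoys[[k]], profile, max_nodes = max_nodes,
                         label = list(lrmsd = gt$lrmsd[k], target_id = tid,
                                      group_id = grp))
      g$id <- gt$decoys[[k]]$id
      graphs[[length(graphs) + 1L]] <- g
    }
    rows[[t]] <- data.frame(
      id = vapply(gt$decoys, `[[`, character(1L), "id"),
      target_id = tid, group_id = grp, lrmsd = gt$lrmsd,
      lrmsd_norm = ipr_normalize_lrmsd(gt$lrmsd),
      is_correct = gt$lrmsd < 4.0, stringsAsFactors = FALSE)
    targets[[tid]] <- list(native = gt$native, msa = gt$msa, group_id = grp)
  }
  list(graphs = graphs, labels = do.call(rbind, rows), targets = targets)
}

# ---- plain-text writers ----------------------------------------------------

#' Write a complex to a PDB file
#'
#' Receptor chain(s) first, then the peptide chain, standard ATOM records,
#' TER separators and END.
#'
#' @param complex An [ipr_complex()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
ipr_write_pdb <- function(complex, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  write_res <- function(res) {
    for (a in seq_len(nrow(res$xyz))) {
      serial <<- serial + 1L
      nm <- rownames(res$xyz)[a]
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", formatC(nm, width = -3)), res$aa3, res$chain_id,
        res$res_seq, ifelse(nzchar(res$icode), res$icode, " "),
        res$xyz[a, 1L], res$xyz[a, 2L], res$xyz[a, 3L], 1, 0,
        substr(nm, 1L, 1L)), con)
    }
  }
  for (res in complex$receptor) write_res(res)
  writeLines("TER", con)
  for (res in complex$peptide) write_res(res)
  writeLines(c("TER", "END"), con)
  invisible(path)
}

#' Write sequences or an MSA to FASTA
#'
#' @param x An `ipr_msa` or a named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
ipr_write_fasta <- function(x, path) {
  if (inherits(x, "ipr_msa")) {
    nms <- x$names; seqs <- x$rows
  } else {
    nms <- names(x) %||% paste0("seq", seq_along(x)); seqs <- x
  }
  writeLines(as.vector(rbind(paste0(">", nms), seqs)), path)
  invisible(path)
}

#' Write a complete synthetic mini-benchmark directory
#'
#' One directory per target under `dir/targets/`, each holding
#' `native.pdb`, `msa.fasta` and `decoys/<id>.pdb`, plus a top-level
#' `targets.tsv` (target id, homology group, chain ids) and `labels.tsv`
#' with the true LRMSD of every decoy. The directory is a self-contained
#' input for the `featurize` command.
#'
#' @inheritParams ipr_make_planted_dataset
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
ipr_make_benchmark <- function(dir, n_targets = 4L, decoys_per_target = 16L,
                               seed = 1L, ...) {
  dir.create(file.path(dir, "targets"), recursive = TRUE, showWarnings = FALSE)
  tinfo <- list(); lab <- list()
  for (t in seq_len(n_targets)) {
    tid <- sprintf("t%02d", t)
    grp <- sprintf("g%02d", ceiling(t / 2))
    gt <- gen_planted_target(tid, seed = seed * 1000L + t,
                             decoys_per_target = decoys_per_target, ...)
    td <- file.path(dir, "targets", tid)
    dir.create(file.path(td, "decoys"), recursive = TRUE, showWarnings = FALSE)
    ipr_write_pdb(gt$native, file.path(td, "native.pdb"))
    ipr_write_fasta(gt$msa, file.path(td, "msa.fasta"))
    for (d in gt$decoys)
      ipr_write_pdb(d, file.path(td, "decoys", paste0(d$id, ".pdb")))
    tinfo[[t]] <- data.frame(target_id = tid, group_id = grp,
                             receptor_chain = "A", peptide_chain = "B",
                             stringsAsFactors = FALSE)
    lab[[t]] <- data.frame(
      decoy_id = vapply(gt$decoys, `[[`, character(1L), "id"),
      target_id = tid, lrmsd = gt$lrmsd, stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, tinfo), file.path(dir, "targets.tsv"))
  write_tsv(do.call(rbind, lab), file.path(dir, "labels.tsv"))
  invisible(dir)
}
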