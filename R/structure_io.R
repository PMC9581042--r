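# Structure input and decoy-vs-native model quality measures.

#' Construct a residue record
#'
#' Residues are the nodes of the decoy graph: a chain identifier, author
#' numbering (with optional insertion code), amino-acid identity, and the
#' coordinates of the heavy (non-hydrogen) atoms in Angstrom.
#'
#' @param chain_id Single-character chain identifier.
#' @param res_seq Integer author residue number.
#' @param aa3 Three-letter residue code; unknown codes map to one-letter "X".
#' @param xyz Numeric matrix (n_atoms x 3) of heavy-atom coordinates with
#'   atom names (e.g. "N", "CA", "C", "O") as row names.
#' @param icode Insertion code, default "".
#' @return An object of class `ipr_residue`.
#' @export
ipr_residue <- function(chain_id, res_seq, aa3, xyz, icode = "") {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) stopf("residue %s%d%s has no heavy atoms", chain_id, res_seq, icode)
  if (ncol(xyz) != 3L || !all(is.finite(xyz)))
    stopf("residue %s%d%s: coordinates must be a finite n x 3 matrix",
          chain_id, res_seq, icode)
  if (is.null(rownames(xyz))) stopf("atom coordinates need atom-name row names")
  aa1 <- unname(AA3_TO_1[toupper(aa3)])
  if (is.na(aa1)) aa1 <- "X"
  structure(
    list(chain_id = as.character(chain_id), res_seq = as.integer(res_seq),
         icode = as.character(icode), aa3 = toupper(aa3), aa1 = aa1, xyz = xyz),
    class = "ipr_residue"
  )
}

#' Construct a peptide-protein complex
#'
#' @param receptor,peptide Ordered lists of [ipr_residue()] records
#'   (file/chain order).
#' @param id Complex identifier.
#' @return An object of class `ipr_complex`.
#' @export
ipr_complex <- function(receptor, peptide, id = "complex") {
  if (length(peptide) < 1L) stopf("complex '%s': peptide has zero residues", id)
  if (length(receptor) < 1L) stopf("complex '%s': receptor has zero residues", id)
  if (length(peptide) > 25L)
    warnf("complex '%s': peptide has %d residues (> 25, outside the intended peptide regime)",
          id, length(peptide))
  if (length(receptor) < 50L)
    warnf("complex '%s': receptor has %d residues (< 50, outside the intended receptor regime)",
          id, length(receptor))
  structure(list(receptor = receptor, peptide = peptide, id = id),
            class = "ipr_complex")
}

#' @export
print.ipr_complex <- function(x, ...) {
  cat(sprintf("<ipr_complex '%s'> receptor %d res (%s), peptide %d res (%s)\n",
              x$id, length(x$receptor), x$receptor[[1L]]$chain_id,
              length(x$peptide), x$peptide[[1L]]$chain_id))
  invisible(x)
}

residue_key <- function(res) paste0(res$chain_id, res$res_seq, res$icode)

complex_sequence <- function(residues) {
  paste(vapply(residues, `[[`, character(1L), "aa1"), collapse = "")
}

# Stack the atoms of a residue list: coordinates plus residue/atom bookkeeping.
stack_atoms <- function(residues, atoms = NULL) {
  keep <- lapply(seq_along(residues), function(i) {
    xyz <- residues[[i]]$xyz
    if (!is.null(atoms)) xyz <- xyz[rownames(xyz) %in% atoms, , drop = FALSE]
    if (nrow(xyz) == 0L) return(NULL)
    cbind(res = i, xyz)
  })
  m <- do.call(rbind, keep)
  list(xyz = m[, 2:4, drop = FALSE], res = m[, 1L], name = rownames(m))
}

# Minimum heavy-atom distance between every residue of `a` and of `b`.
residue_min_dist <- function(a, b) {
  sa <- stack_atoms(a)
  sb <- stack_atoms(b)
  d2 <- outer(rowSums(sa$xyz^2), rep(1, nrow(sb$xyz))) +
        outer(rep(1, nrow(sa$xyz)), rowSums(sb$xyz^2)) -
        2 * sa$xyz %*% t(sb$xyz)
  d2[d2 < 0] <- 0
  fb <- factor(sb$res, levels = seq_along(b))
  out <- matrix(Inf, length(a), length(b))
  for (i in seq_along(a)) {
    rows <- sa$res == i
    cm <- if (sum(rows) == 1L) d2[rows, ] else apply(d2[rows, , drop = FALSE], 2L, min)
    out[i, ] <- as.numeric(tapply(cm, fb, min))
  }
  sqrt(out)
}

#' Read a peptide-protein complex from a PDB file
#'
#' Parses ATOM records via bio3d. Hydrogens and HETATM records are dropped;
#' for residues with alternate locations the highest-occupancy conformer is
#' kept; residues with non-standard codes get one-letter identity "X".
#'
#' @param path PDB file.
#' @param receptor_chains Character vector of receptor chain identifiers.
#' @param peptide_chain Single peptide chain identifier.
#' @param model Which MODEL block to read (1-based); files without MODEL
#'   blocks have a single model.
#' @param id Complex identifier; defaults to the file name.
#' @return An [ipr_complex()].
#' @seealso [ipr_read_pdb_models()] to read every MODEL block as a separate
#'   decoy.
#' @export
ipr_read_pdb <- function(path, receptor_chains, peptide_chain, model = 1L,
                         id = sub("\\.pdb$", "", basename(path))) {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model > n_models) stopf("%s has %d model(s); model %d requested", path, n_models, model)
  if (model > 1L) {
    co <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    at$x <- co[, 1L]; at$y <- co[, 2L]; at$z <- co[, 3L]
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  elesy <- toupper(trimws(at$elesy %||% ""))
  hyd <- elesy %in% c("H", "D") |
    (elesy == "" & grepl("^[0-9]*H", trimws(at$elety)))
  at <- at[!hyd, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  build_chain <- function(ch) {
    ca <- at[at$chain == ch, , drop = FALSE]
    if (nrow(ca) == 0L) stopf("%s: chain '%s' not found", path, ch)
    # alternate locations: keep the highest-occupancy conformer per atom
    ca <- ca[order(-ca$o), , drop = FALSE]
    akey <- paste(ca$resno, ca$insert, ca$elety, sep = "|")
    ca <- ca[!duplicated(akey), , drop = FALSE]
    ca <- ca[order(match(paste(ca$resno, ca$insert), unique(paste(at$resno, at$insert)[at$chain == ch]))), , drop = FALSE]
    rkey <- paste(ca$resno, ca$insert, sep = "|")
    lapply(unique(rkey), function(k) {
      ra <- ca[rkey == k, , drop = FALSE]
      xyz <- as.matrix(ra[, c("x", "y", "z")])
      rownames(xyz) <- trimws(ra$elety)
      ipr_residue(ch, ra$resno[1L], ra$resid[1L], xyz, icode = ra$insert[1L])
    })
  }

  receptor <- do.call(c, lapply(receptor_chains, build_chain))
  peptide <- build_chain(peptide_chain)
  ipr_complex(receptor, peptide, id = id)
}

#' Read every MODEL block of a PDB file as a separate decoy
#'
#' @inheritParams ipr_read_pdb
#' @return A list of [ipr_complex()] objects, ids suffixed `_m<k>` when the
#'   file holds more than one model.
#' @export
ipr_read_pdb_models <- function(path, receptor_chains, peptide_chain,
                                id = sub("\\.pdb$", "", basename(path))) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  lapply(seq_len(n_models), function(m) {
    mid <- if (n_models > 1L) sprintf("%s_m%d", id, m) else id
    ipr_read_pdb(path, receptor_chains, peptide_chain, model = m, id = mid)
  })
}

# ---- superposition ---------------------------------------------------------

# Optimal rotation (Kabsch, via SVD) mapping row-points P onto Q after
# centering; returns the 3x3 matrix U with Pc %*% U ~= Qc.
kabsch_rotation <- function(P, Q) {
  A <- t(P) %*% Q
  s <- svd(A)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Rigid transform fitted on (mob_fit -> ref_fit), applied to `coords`.
superpose_transform <- function(coords, mob_fit, ref_fit) {
  cm <- colMeans(mob_fit)
  cr <- colMeans(ref_fit)
  U <- kabsch_rotation(sweep(mob_fit, 2L, cm), sweep(ref_fit, 2L, cr))
  sweep(sweep(coords, 2L, cm) %*% U, 2L, cr, `+`)
}

rmsd_rows <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

check_matched <- function(decoy, native) {
  for (part in c("receptor", "peptide")) {
    d <- decoy[[part]]; n <- native[[part]]
    if (length(d) != length(n))
      stopf("%s length differs between decoy (%d) and native (%d)",
            part, length(d), length(n))
    for (i in seq_along(d)) {
      if (residue_key(d[[i]]) != residue_key(n[[i]]) || d[[i]]$aa3 != n[[i]]$aa3)
        stopf("decoy/native mismatch at %s residue %d: %s %s vs %s %s",
              part, i, residue_key(d[[i]]), d[[i]]$aa3,
              residue_key(n[[i]]), n[[i]]$aa3)
    }
  }
  invisible(TRUE)
}

# Backbone coordinates present in both structures, residue-matched.
paired_backbone <- function(d_res, n_res, what = "residue") {
  da <- list(); na_ <- list(); kept <- 0L; skipped <- 0L
  for (i in seq_along(d_res)) {
    dn <- intersect(BACKBONE_ATOMS, rownames(d_res[[i]]$xyz))
    dn <- intersect(dn, rownames(n_res[[i]]$xyz))
    if (length(dn) == 0L) { skipped <- skipped + 1L; next }
    if (length(dn) < length(BACKBONE_ATOMS)) skipped <- skipped + 0L
    da[[length(da) + 1L]] <- d_res[[i]]$xyz[dn, , drop = FALSE]
    na_[[length(na_) + 1L]] <- n_res[[i]]$xyz[dn, , drop = FALSE]
    kept <- kept + 1L
  }
  if (skipped > 0L)
    warnf("%d %s(s) skipped from the RMSD atom set (missing backbone atoms)",
          skipped, what)
  list(decoy = do.call(rbind, da), native = do.call(rbind, na_),
       kept = kept, skipped = skipped)
}

#' Ligand RMSD of a decoy against its native complex
#'
#' The decoy receptor backbone (N, CA, C, O) is least-squares superposed
#' onto the native receptor backbone; the RMSD is then computed over the
#' peptide backbone atoms without further fitting. A decoy is conventionally
#' "correct" when LRMSD < 4 Angstrom.
#'
#' @param decoy,native [ipr_complex()] objects with identical sequences and
#'   residue numbering.
#' @return LRMSD in Angstrom.
#' @export
ipr_lrmsd <- function(decoy, native) {
  check_matched(decoy, native)
  rec <- paired_backbone(decoy$receptor, native$receptor, "receptor residue")
  pep <- paired_backbone(decoy$peptide, native$peptide, "peptide residue")
  if (pep$kept < min(3L, length(decoy$peptide)))
    stopf("fewer than %d peptide residues carry backbone atoms; LRMSD undefined",
          min(3L, length(decoy$peptide)))
  fitted_pep <- superpose_transform(pep$decoy, rec$decoy, rec$native)
  rmsd_rows(fitted_pep, pep$native)
}

# Native interface residues: any heavy atom within `cutoff` of the other chain.
native_interface <- function(native, cutoff = 10) {
  d <- residue_min_dist(native$receptor, native$peptide)
  list(receptor = which(apply(d, 1L, min) <= cutoff),
       peptide = which(apply(d, 2L, min) <= cutoff))
}

#' Interface RMSD of a decoy against its native complex
#'
#' Interface residues are defined on the native: residues of either chain
#' with any heavy atom within `interface_cutoff` of the other chain. The
#' decoy is superposed on the backbone atoms of those residues and the RMSD
#' is computed over the same atoms.
#'
#' @inheritParams ipr_lrmsd
#' @param interface_cutoff Heavy-atom distance (Angstrom) defining the
#'   native interface; 10 by convention.
#' @return iRMSD in Angstrom.
#' @export
ipr_irmsd <- function(decoy, native, interface_cutoff = 10) {
  check_matched(decoy, native)
  iface <- native_interface(native, interface_cutoff)
  if (length(iface$receptor) + length(iface$peptide) == 0L)
    stopf("native has no interface contacts within %.1f Angstrom", interface_cutoff)
  d_res <- c(decoy$receptor[iface$receptor], decoy$peptide[iface$peptide])
  n_res <- c(native$receptor[iface$receptor], native$peptide[iface$peptide])
  bb <- paired_backbone(d_res, n_res, "interface residue")
  fitted <- superpose_transform(bb$decoy, bb$decoy, bb$native)
  rmsd_rows(fitted, bb$native)
}

contact_pairs <- function(cx, cutoff) {
  which(residue_min_dist(cx$receptor, cx$peptide) <= cutoff, arr.ind = TRUE)
}

#' Fraction of native contacts recalled by a decoy
#'
#' Residue-residue contacts are heavy-atom pairs within `contact_cutoff`
#' (5 Angstrom by convention); fnat is the fraction of the native contact
#' pairs also present in the decoy.
#'
#' @inheritParams ipr_lrmsd
#' @param contact_cutoff Heavy-atom contact distance in Angstrom.
#' @return fnat in \[0, 1\].
#' @export
ipr_fnat <- function(decoy, native, contact_cutoff = 5) {
  check_matched(decoy, native)
  nat <- contact_pairs(native, contact_cutoff)
  if (nrow(nat) == 0L)
    stopf("native has no residue-residue contacts within %.1f Angstrom (degenerate native)",
          contact_cutoff)
  dec <- contact_pairs(decoy, contact_cutoff)
  nk <- paste(nat[, 1L], nat[, 2L])
  dk <- paste(dec[, 1L], dec[, 2L])
  sum(nk %in% dk) / length(nk)
}

#' DockQ composite quality score
#'
#' Three-term average of fnat and scaled LRMSD / iRMSD terms,
#' `(fnat + 1/(1+(iRMSD/1.5)^2) + 1/(1+(LRMSD/8.5)^2)) / 3`; 1 for a
#' perfect model, tending to 0 for unrelated poses.
#'
#' @param lrmsd,irmsd RMSDs in Angstrom (non-negative).
#' @param fnat Fraction of native contacts in \[0, 1\].
#' @return DockQ score in \[0, 1\].
#' @export
ipr_dockq <- function(lrmsd, irmsd, fnat) {
  if (any(lrmsd < 0) || any(irmsd < 0) || any(fnat < 0) || any(fnat > 1))
    stopf("ipr_dockq: lrmsd/irmsd must be >= 0 and fnat in [0, 1]")
  (fnat + 1 / (1 + (irmsd / 1.5)^2) + 1 / (1 + (lrmsd / 8.5)^2)) / 3
}

#' CAPRI model-quality class
#'
#' High: LRMSD < 1 and iRMSD < 0.5 and fnat > 0.8; Medium: LRMSD < 2 and
#' iRMSD < 1 and fnat > 0.5; Acceptable: LRMSD < 5 and iRMSD < 2 and
#' fnat > 0.2; otherwise Incorrect. Higher classes imply the lower ones.
#'
#' @inheritParams ipr_dockq
#' @return Character vector over
#'   `c("Incorrect", "Acceptable", "Medium", "High")`.
#' @export
ipr_capri_class <- function(lrmsd, irmsd, fnat) {
  n <- max(length(lrmsd), length(irmsd), length(fnat))
  lrmsd <- rep_len(lrmsd, n); irmsd <- rep_len(irmsd, n); fnat <- rep_len(fnat, n)
  out <- rep("Incorrect", n)
  out[lrmsd < 5 & irmsd < 2 & fnat > 0.2] <- "Acceptable"
  out[lrmsd < 2 & irmsd < 1 & fnat > 0.5] <- "Medium"
  out[lrmsd < 1 & irmsd < 0.5 & fnat > 0.8] <- "High"
  out
}

#' Assess decoys against a native complex
#'
#' Computes LRMSD, iRMSD, fnat, DockQ, the CAPRI class and the correctness
#' flag (LRMSD < 4 Angstrom) for one or more decoys.
#'
#' @param decoys A single [ipr_complex()] or a list of them.
#' @param native The native [ipr_complex()].
#' @param interface_cutoff,contact_cutoff See [ipr_irmsd()], [ipr_fnat()].
#' @return A data.frame with one row per decoy: `id`, `lrmsd`, `irmsd`,
#'   `fnat`, `dockq`, `capri_class`, `is_correct`.
#' @export
ipr_assess <- function(decoys, native, interface_cutoff = 10, contact_cutoff = 5) {
  if (inherits(decoys, "ipr_complex")) decoys <- list(decoys)
  rows <- lapply(decoys, function(d) {
    l <- ipr_lrmsd(d, native)
    i <- ipr_irmsd(d, native, interface_cutoff)
    f <- ipr_fnat(d, native, contact_cutoff)
    data.frame(id = d$id, lrmsd = l, irmsd = i, fnat = f,
               dockq = ipr_dockq(l, i, f),
               capri_class = ipr_capri_class(l, i, f),
               is_correct = l < 4.0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
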