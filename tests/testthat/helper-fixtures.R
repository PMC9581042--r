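# Shared in-code fixtures: hand-placed residues and a tiny PDB text file.

# Single-atom residue (CA only) at a given position.
point_res <- function(chain, seq, x, y = 0, z = 0, aa3 = "GLY", atom = "CA") {
  xyz <- matrix(c(x, y, z), 1L, 3L, dimnames = list(atom, NULL))
  ipr_residue(chain, seq, aa3, xyz)
}

# Complex built from single-atom residues, warnings (tiny receptor) silenced.
point_complex <- function(receptor, peptide, id = "pc") {
  suppressWarnings(ipr_complex(receptor, peptide, id = id))
}

# A small hand-written PDB exercising altlocs, HETATM, hydrogens and an
# unknown residue code. Chain A: 4 residues (res 2 has two altlocs with
# occupancies 0.6/0.4; res 4 is non-standard "XYZ"); chain B: 2 residues.
write_tiny_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  H   ALA A   1       1.460   1.000   0.000  1.00  0.00           H",
    "ATOM      4  N  AGLY A   2       3.000   0.000   0.000  0.60  0.00           N",
    "ATOM      5  N  BGLY A   2       3.500   0.000   0.000  0.40  0.00           N",
    "ATOM      6  CA AGLY A   2       4.460   0.000   0.000  0.60  0.00           C",
    "ATOM      7  CA BGLY A   2       4.960   0.000   0.000  0.40  0.00           C",
    "ATOM      8  CA  SER A   3       8.000   0.000   0.000  1.00  0.00           C",
    "ATOM      9  CA  XYZ A   4      12.000   0.000   0.000  1.00  0.00           C",
    "HETATM   10  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    "TER",
    "ATOM     11  CA  LEU B   1       0.000   4.000   0.000  1.00  0.00           C",
    "ATOM     12  CA  VAL B   2       3.800   4.000   0.000  1.00  0.00           C",
    "TER",
    "END")
  writeLines(lines, path)
  path
}

# Small planted dataset shared by the slower tests (built once per run).
small_planted <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- ipr_make_planted_dataset(n_targets = 6, decoys_per_target = 24,
                                         seed = 101,
                                         receptor_len_range = c(40L, 52L),
                                         peptide_len_range = c(6L, 9L),
                                         msa_depth = 12)
    cache
  }
})

# Random rigid transform applied to a whole complex.
random_rigid <- function(cx, seed) {
  with_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(s); on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    force(code)
  }
  with_seed(seed, {
    ang <- runif(3L, -pi, pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]), 0, -sin(ang[1]), cos(ang[1])), 3L)
    Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0, sin(ang[2]), 0, cos(ang[2])), 3L)
    Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3L)
    R <- Rx %*% Ry %*% Rz
    t <- runif(3L, -20, 20)
    move <- function(res) { res$xyz <- sweep(res$xyz %*% R, 2L, t, `+`); res }
    cx$receptor <- lapply(cx$receptor, move)
    cx$peptide <- lapply(cx$peptide, move)
    cx
  })
}
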