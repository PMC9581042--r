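---
title: "Ranking peptide-protein docking decoys with edge-conditioned graph convolutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking peptide-protein docking decoys with edge-conditioned graph convolutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interpeprank)
```

## The problem

Fast-Fourier-transform rigid-body docking of a short peptide (up to 25
residues) onto a folded receptor samples the binding space exhaustively but
scores it poorly: the pool of tens of thousands of candidate poses
("decoys") per target contains near-native poses that the docking energy
cannot separate from junk. Refinement protocols that could fix a
near-native pose are far too expensive to run on every decoy, so the
practical bottleneck is *re-scoring*: ranking the decoy pool so that the
subset selected for refinement is enriched in poses that are actually
refinable. A decoy is conventionally called *correct* when its ligand RMSD
(LRMSD: RMSD over the peptide backbone after superposing the receptor onto
the native complex) is below 4 Å.

This package implements a graph-network scorer for that task, as a
standard R modelling interface: `interpeprank()` fits the network and
returns a classed object with `predict()`, `summary()`, `plot()`,
`residuals()` and friends; `ipr_ensemble()` averages several fits.

## Decoy representation

Each decoy becomes a residue-level graph:

* **Nodes** (up to `max_nodes = 100`): all peptide residues plus the
  receptor residues closest to the peptide by minimum heavy-atom distance
  (with a 25-residue peptide and a 170-residue receptor, the graph holds
  the 25 peptide residues and the 75 closest receptor residues). Smaller
  complexes are zero-padded; padding is masked out of every computation.
* **Node features** (64 columns): one-hot amino-acid identity over 20
  amino acids plus an unknown slot (21), a position-specific scoring
  matrix (21, including a gap column), self-entropy (21), and a
  peptide/receptor indicator (1). With column frequencies $p_i$ and
  background frequencies $p_{b}$,
  $$\mathrm{PSSM}_i = -\log\frac{p_i}{p_{b}}, \qquad
    S_i = -\,p_i \log\frac{p_i}{p_{b}},$$
  so $S_i = p_i\,\mathrm{PSSM}_i$ holds elementwise. Peptides are too
  short to yield a meaningful alignment, so peptide rows carry exactly
  zero PSSM and self-entropy and are marked by the indicator instead.
* **Edges** (4 one-hot channels): *self* edges on the diagonal, *sequence*
  edges between peptide-bonded chain neighbours, *proximity* edges between
  residues with any heavy-atom pair within 4.5 Å (inclusive), and an
  *identity* channel that is the union of the other three.

## Model

The one-hot block is first passed through a learned linear embedding
(default width 8) to cut the parameter count; the embedded identity is
concatenated with the remaining 43 features. A stack of edge-conditioned
graph convolutions follows: for node $i$ with neighbours $N(i)$ (any
nonzero edge channel),
$$h_i' = \mathrm{ReLU}\!\left(W_r h_i + \frac{1}{|N(i)|}
  \sum_{j \in N(i)} \Theta(e_{ij})\, h_j + b\right),$$
where the filter $\Theta(e_{ij})$ is generated from the 4-channel edge
vector by a single-hidden-layer network (ReLU, default width 16). The
outputs of all convolution layers are concatenated per node, globally
pooled over real nodes (mean by default, dividing by the real-node count,
never the padded size), and passed through two dense ReLU layers to a
softmax over quality bins.

The training target is the normalized LRMSD
$$\mathrm{LRMSD}_{norm} = \frac{1}{1 + (\mathrm{LRMSD}/4)^2},$$
binned into 2–4 evenly spaced, right-closed classes; with two bins the
class boundary coincides with the 4 Å correctness threshold (4.0 Å exactly
falls in the lower bin, matching the strict `< 4` definition). The
reported score is the probability-weighted mean of the bin centers
$x_i = (i + 0.5)/n$,
$$S = \sum_i x_i\, P(x_i),$$
so $S$ is bounded by the extreme bin centers and higher $S$ predicts lower
LRMSD. Ensembles average member scores.

Training uses cross-entropy, the ADAM optimizer at learning rate 0.001 for
up to 1000 epochs, and training-time *edge dropout*: each undirected edge
position (symmetric pairs together, so the identity channel stays
consistent) is zeroed across all channels with probability 0.1–0.25. When
a validation set is given, per-epoch loss, Spearman correlation of score
against normalized LRMSD, and precision/recall at score 0.5 are logged;
the selected weights are those of the epoch minimizing the rank-sum of
(validation loss, −Spearman, −F1). The forward and backward passes are
written directly in matrix form in base R; gradients are analytic and are
verified against finite differences in the test suite.

## Quality measures

`ipr_assess()` computes, per decoy against the native: LRMSD (superpose on
receptor backbone N, CA, C, O; RMSD over peptide backbone), iRMSD
(backbone RMSD over native interface residues, defined by a 10 Å
heavy-atom cutoff), fnat (fraction of native residue contacts at 5 Å
recalled), DockQ (three-term average with the standard 8.5 Å / 1.5 Å
scalings), and the CAPRI class:

| Class      | LRMSD   | iRMSD   | fnat   |
|------------|---------|---------|--------|
| High       | < 1.0 Å | < 0.5 Å | > 0.8  |
| Medium     | < 2.0 Å | < 1.0 Å | > 0.5  |
| Acceptable | < 5.0 Å | < 2.0 Å | > 0.2  |

## Design choices in detail

Several conventions are not forced by the method and were fixed once,
documented here:

* **LRMSD atom set.** Backbone N, CA, C, O for both the receptor fit and
  the peptide RMSD (the DockQ/CAPRI convention, consistent with the DockQ
  equivalents used in the class thresholds). Residues missing backbone
  atoms are skipped with a warning; the computation proceeds while at
  least three peptide residues remain. Decoy and native residues are
  matched by (chain, residue number, insertion code) — no realignment.
* **Background frequencies.** BLOSUM62 amino-acid backgrounds renormalized
  to 0.95, gap background 0.05; natural logarithm (a log2 flag exists).
  A pseudocount of total weight 1, distributed by background, keeps every
  frequency positive. Rows are weighted uniformly; redundancy filtering is
  assumed done by whatever produced the alignment.
* **Counting unknowns.** `X` and other non-alphabet symbols are excluded
  from column counts (the column denominator counts observed symbols
  only).
* **Edge conventions.** The 4.5 Å proximity comparison is inclusive
  (`<=`). Sequence edges require an actual peptide bond (C–N ≤ 2.0 Å), so
  chain breaks never create edges. Receptor node selection breaks distance
  ties toward the lower residue index. Node order is peptide first, then
  receptor, both in chain order — pooling makes the network insensitive to
  this, which the tests verify by permutation.
* **Edge dropout granularity.** Whole edge positions (all four channels,
  both directions) are dropped together, keeping the identity channel the
  union of the others.
* **Convolution internals.** Mean aggregation over neighbours, a root/self
  term, a bias, and a one-hidden-layer filter generator; Glorot-uniform,
  seeded initialization. Padded nodes are removed before computation,
  which realizes the masking contract exactly (the tests compare paddings
  of 100 vs 120 nodes).
* **Model selection.** "Best combination" of validation metrics is
  implemented as the minimum rank-sum of loss, −Spearman and −F1 over
  epochs; weight snapshots are kept only for epochs on the running Pareto
  front of these three metrics, which provably contains the rank-sum
  winner.
* **Dataset balancing.** Per target, the majority correctness class is
  down-sampled to the minority; then each homology group is capped at the
  median group total. The cap removes whole correct/incorrect pairs within
  a target, so the per-target class balance survives the cap (a uniform
  cap would not guarantee that); a group may land one decoy under the cap
  when the cap is odd. Both stages are seeded and uniform — no LRMSD
  stratification.
* **Validation Spearman** is pooled over the validation set (a per-target
  average would weight targets equally; pooled matches how the training
  loss is computed).
* **Selection cutoff.** `ipr_select(..., "cutoff", 0.47)` is inclusive at
  the boundary. The 0.47 operating point is the reference score threshold
  for choosing decoys worth refining.

## What the synthetic fixtures emulate — and what they do not

No structure or alignment is downloaded; every input is generated:

* `ipr_make_toy_complex()` builds an idealized backbone: the receptor is
  two parallel α-helical segments (CA radius 2.3 Å, rise 1.5 Å/residue,
  100°/residue) whose 13 Å axis gap forms a binding groove; the peptide is
  an extended strand in the groove. Atoms are placed along the curve at
  arc spacings N–CA 1.46, CA–C 1.52, C–N 1.33 Å, so consecutive residues
  are genuinely peptide-bonded and the native interface is non-empty at
  4.5 Å by construction.
* `ipr_make_decoy_set()` perturbs the peptide rigidly. Rotation about the
  peptide centroid and translation contribute orthogonally to the squared
  displacement, so the translation magnitude is solved analytically to hit
  a requested LRMSD exactly; every decoy is verified with `ipr_lrmsd()`
  and misses beyond 10 % are rejected.
* `ipr_make_toy_msa()` point-mutates the receptor sequence uniformly over
  the 20 amino acids. Under this model a fully mutated column tends to the
  uniform 1/20 distribution (not the BLOSUM background — the generator is
  deliberately simple), and a conserved column gives frequency 1.
* `ipr_make_planted_dataset()` builds class-separable training data:
  correct decoys (LRMSD drawn from 0.5–3.5 Å) stay in the groove and touch
  both receptor segments; incorrect decoys (LRMSD ≥ 8 Å, pure translation)
  sit on an outside face and touch one. The planted, target-transferable
  signal is therefore contact density — correct poses carry systematically
  more peptide–receptor proximity edges — which a small network can learn
  and generalize to held-out targets.

These fixtures exercise the full representation and training machinery,
but they are not real data: there are no side chains, no steric packing,
no sequence–structure correlation, and the planted signal is far cleaner
than the energetic differences that separate real near-native decoys.
Passing the learning tests shows the estimator can recover a geometric
signal it was promised, not that it reaches any particular accuracy on
real docking pools — reproducing published benchmark performance would
require the original multi-billion-decoy sets and full-scale training,
which is out of scope here.

## Problem sizes and numerics

The test-suite study conditions are chosen to be meaningful yet desk-sized:
the learning benchmark uses 20 synthetic targets × 100 decoys
(receptors 56–76 residues, peptides 8–12), a grouped 70/15/15 split by
homology group, and a two-member ensemble (3×32-channel and 2×24-channel
configurations) trained for 60 epochs at batch size 128 under a fixed
seed; held-out performance is required to reach ROC AUC ≥ 0.9 and
Spearman ρ ≥ 0.6. The overfit capacity check trains a 2×16-channel
network on 50 decoys of one target to ≥ 99 % training accuracy.
Degenerate inputs are handled explicitly: a native without interface
contacts errors (iRMSD/fnat undefined), ROC requires both classes,
single-class precision-recall reports `NA` recall, nodes isolated by edge
dropout fall back to their root term (degree is floored at one), and
softmax inputs are max-shifted for stability. All randomness — sequence
generation, decoy perturbations, alignments, initialization, shuffling,
dropout — flows from explicit seeds, and the RNG state of the caller is
restored afterwards.

## A worked run

```{r example, eval = FALSE}
pd <- ipr_make_planted_dataset(n_targets = 8, decoys_per_target = 40,
                               seed = 11)
sp <- ipr_grouped_split(unique(pd$labels[, c("target_id", "group_id")]),
                        c(train = 0.6, validation = 0.2, test = 0.2),
                        seed = 2)
fold <- sp$split[match(pd$labels$target_id, sp$target_id)]
fit <- interpeprank(pd$graphs[fold == "train"],
                    pd$graphs[fold == "validation"],
                    config = ipr_network_config(conv_channels = c(24L, 24L)),
                    max_epochs = 40, batch_size = 100, seed = 3)
scores <- predict(fit, pd$graphs[fold == "test"])
labels <- pd$labels[match(names(scores), pd$labels$id), ]
ipr_roc(scores, labels$is_correct)$auc
ipr_select(data.frame(decoy_id = names(scores), score = scores),
           "cutoff", 0.47)
```

The same workflow is available from a shell through the CLI wrapper
(`inst/scripts/interpeprank`): `make-fixtures`, `featurize`, `train`,
`score`, `select`, `evaluate`, each writing a YAML log of its resolved
options and seed.

## Known limitations

* The scorer is CPU-bound, pure R; it is sized for desk-scale experiments
  (thousands of decoys), not for scoring millions of poses.
* PDB input only (no mmCIF), protein chains only, one peptide chain.
* The synthetic generator produces backbone-only structures; side-chain
  dependent features could not be exercised even if added.
* Pretrained weights are not shipped; every use starts from training on
  user data or fixtures.
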