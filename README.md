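# interpeprank

Graph-network scoring and ranking of peptide–protein docking decoys in R.

## The problem

Rigid-body FFT docking of a short peptide (≤ 25 residues) onto a folded
receptor produces tens of thousands of candidate poses per target, of
which only a handful are near-native (ligand RMSD, LRMSD, below 4 Å).
Refinement can rescue near-native poses but is too expensive to run on
the whole pool, so docking pipelines live or die by the *re-scoring* step
that picks which decoys are worth refining. This package is for
structural-bioinformatics practitioners building or benchmarking such
pipelines: it provides the scorer, the quality metrics used to judge it,
and a fully synthetic benchmark generator so everything can be exercised
without downloading a single structure.

## The method

Each decoy is encoded as a residue graph: up to 100 nodes (the peptide
plus the receptor residues closest to it), 64 node features — one-hot
amino-acid identity (21), a position-specific scoring matrix and
self-entropy from a multiple sequence alignment (21 + 21, computed as
PSSM<sub>i</sub> = −log(p<sub>i</sub>/p<sub>b</sub>) and
S<sub>i</sub> = −p<sub>i</sub> log(p<sub>i</sub>/p<sub>b</sub>), zeroed
for the peptide) and a peptide indicator — and four one-hot edge channels
(self, peptide bond, heavy-atom proximity within 4.5 Å, and their union).

A stack of edge-conditioned graph convolutions (filters generated from
the edge features), an amino-acid embedding, global pooling over real
nodes and two dense layers predict the bin of the normalized LRMSD,
LRMSD<sub>norm</sub> = 1/(1 + (LRMSD/4)²), over 2–4 evenly spaced
classes. The decoy score is the probability-weighted mean of the bin
centers, S = Σ x<sub>i</sub> P(x<sub>i</sub>); higher S predicts lower
LRMSD, and scores from several trained networks are averaged into an
ensemble. Training uses ADAM (learning rate 0.001), cross-entropy,
edge dropout (0.1–0.25), and validation-based epoch selection. The
network, including analytic backpropagation, is implemented in base R
and verified against finite differences in the test suite.

Ground-truth quality of a decoy against its native is computed with the
standard battery: LRMSD, interface RMSD, fraction of native contacts,
DockQ, and the CAPRI class (Incorrect / Acceptable / Medium / High).

## A worked example

Generate a synthetic benchmark with a planted geometric signal, fit a
scorer, and rank held-out decoys:

```r
library(interpeprank)

pd <- ipr_make_planted_dataset(n_targets = 8, decoys_per_target = 40, seed = 11)
sp <- ipr_grouped_split(unique(pd$labels[, c("target_id", "group_id")]),
                        c(train = 0.6, validation = 0.2, test = 0.2), seed = 2)
fold <- sp$split[match(pd$labels$target_id, sp$target_id)]

fit <- interpeprank(pd$graphs[fold == "train"], pd$graphs[fold == "validation"],
                    config = ipr_network_config(conv_channels = c(24L, 24L)),
                    max_epochs = 40, batch_size = 100, seed = 3)
fit
#> Edge-conditioned graph network decoy scorer
#>   2 bins, embedding 8, conv [24, 24], dense [64, 32], mean pooling
#>   trained on 160 decoys (80 validation), 40 epochs, selected epoch 39

scores <- predict(fit, pd$graphs[fold == "test"])
labels <- pd$labels[match(names(scores), pd$labels$id), ]
ipr_roc(scores, labels$is_correct)$auc
#> [1] 1
ipr_spearman(scores, labels$lrmsd_norm)
#> [1] 0.7847444
```

A held-out AUC of 1 means every correct decoy of the unseen targets
outranked every incorrect one; the Spearman value says the continuous
score also tracks the graded quality within the pool. Selection for
refinement uses either a top-N rule or the reference score cutoff 0.47:

```r
head(ipr_select(data.frame(decoy_id = names(scores), score = scores),
                "cutoff", 0.47), 3)
#>   decoy_id     score rank
#> 1 t08_d018 0.7499881    1
#> 2 t07_d008 0.7499838    2
#> 3 t08_d016 0.7499750    3
```

The same workflow runs from a shell via the wrapper in
`inst/scripts/interpeprank`:

```sh
interpeprank make-fixtures --out bench --targets 4 --decoys 16 --seed 7
interpeprank featurize --dir bench --out graphs.rds
interpeprank train --graphs graphs.rds --out model.rds --members 2 --epochs 40 --seed 7
interpeprank score --graphs graphs.rds --model model.rds --out scores.tsv
interpeprank select --scores scores.tsv --cutoff 0.47 --out selected.tsv
interpeprank evaluate --scores scores.tsv --dir bench --out eval/
```

`ipr_assess(decoys, native)` produces the quality table (LRMSD, iRMSD,
fnat, DockQ, CAPRI class, correctness flag) for any decoy set read from
PDB files with `ipr_read_pdb()`.

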