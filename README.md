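# mosppi

Sequence-only protein–protein interaction (PPI) prediction built around the
**matrix-of-sequence (MOS)** descriptor.

Experimental PPI detection is slow and costly, so a large body of work
predicts interactions from amino-acid sequence alone: encode each protein as
a fixed-length vector, concatenate the two vectors of a candidate pair, and
classify. Popular encoders (conjoint triad, auto covariance, local
descriptors) look only at local windows or bounded lags. The MOS descriptor
instead summarises the order relationship of the *entire* sequence, and is
small enough (29 values per protein) to make training fast.

## The descriptor

Residues are first reduced to seven groups by dipole moment and side-chain
volume:

| group | residues |
|---|---|
| 1 | A G V |
| 2 | I L F P |
| 3 | Y M T S |
| 4 | H N Q W |
| 5 | R K |
| 6 | D E |
| 7 | C |

For the reduced sequence g₁…g_L, the sequence matrix counts every ordered
position pair:

    m_ij = #{ (p, q) : 1 ≤ p ≤ q ≤ L, g_p = i, g_q = j }

accumulated in O(L) by a single reverse scan over the running suffix counts
(the "vector of sequence"). The matrix obeys Σ m_ij = L(L+1)/2,
m_ii = C_i(C_i+1)/2 and m_ij + m_ji = C_i·C_j, where C_i is the group-i
count. Normalizing by L(L+1)/2 and flattening the diagonal-and-above
entries (28 values) plus a 1/L length tag gives the 29-dimensional protein
vector; a pair is the 58-value concatenation. Pairs are classified with a
feed-forward ReLU network (default: 3 hidden layers × 512 units, Adam,
learning rate 0.01, batch 128, dropout 0) trained on binary cross-entropy,
or with decision-tree / k-NN / random-forest baselines. CT (343), AC (210)
and LD (630) encoders are included for comparison at matched conditions.

## Worked example

Encoding the 14-residue example sequence:

```r
library(mosppi)
v <- encode_mos("AGCRQTSPLGVKSE")
paste(map_to_groups("AGCRQTSPLGVKSE"), collapse = "")
#> [1] "11754332211536"
round(v[c("m11", "m12", "m13", "invlen")], 4)
#>    m11    m12    m13 invlen
#> 0.0952 0.0381 0.0762 0.0714
```

The reduced sequence is `11754332211536`; `m11 = 10/105 ≈ 0.0952` because
the four group-1 residues form 4·5/2 = 10 ordered pairs out of
14·15/2 = 105 total, and the tag is 1/14 ≈ 0.0714.

A full pipeline on synthetic data with a planted composition signal
(proteins drawn from latent composition archetypes; interacting pairs share
an archetype):

```r
cfg <- list(seed = 23L, encoder = "MOS",
            synthetic = list(n_proteins = 120L, n_pos = 150L, n_neg = 150L,
                             effect = 0.8),
            model = list(width = 32L, depth = 2L, n_steps = 250L),
            split = list(n_train_pos = 110L, n_train_neg = 110L))
res <- run_pipeline(cfg, out_dir = tempfile())
#> simulate: 120 proteins, 300 pairs
#> filter: 300 -> 300 pairs
#> encode: 300 rows x 58 features (MOS)
#> evaluate: accuracy 0.9500 recall 0.9750 auc 0.9962 loss 0.0920
```

The holdout AUC of 0.9962 shows the classifier recovering the planted
archetype signal from MOS features; at `effect = 0` the same pipeline
scores chance-level AUC. A command-line front end with `simulate`,
`encode` and `run` subcommands is installed at `inst/cli/mosppi`.

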