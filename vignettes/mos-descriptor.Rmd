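---
title: "The matrix-of-sequence descriptor: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The matrix-of-sequence descriptor: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosppi)
```

## The descriptor

Sequence-only PPI prediction needs a fixed-length numeric representation of
a variable-length protein. `mosppi`'s central representation reduces the 20
amino acids to seven groups defined by dipole moment and side-chain volume
({A,G,V}, {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W}, {R,K}, {D,E}, {C}) and then
counts, for every ordered position pair $p \le q$ of the reduced sequence,
the group pair $(g_p, g_q)$. The resulting $7 \times 7$ matrix of sequence
(MOS) $m_{ij}$ summarises the order relationship of the *entire* sequence,
not just local windows. Three identities pin the construction down and are
enforced as tests on every computed matrix:

* $\sum_{ij} m_{ij} = L(L+1)/2$ — one count per position pair;
* $m_{ii} = C_i(C_i+1)/2$ where $C_i$ is the group-$i$ residue count;
* $m_{ij} + m_{ji} = C_i C_j$ for $i \ne j$.

The matrix is accumulated by a single reverse scan: walking from position
$L$ down to 1, the suffix group-count vector (VOS) is updated and added to
the row of the current position's group. This is $O(L \cdot 7)$ time;
`compute_mos_bruteforce()` re-derives the same matrix by explicit pair
enumeration and exists purely as an independent cross-check.

Normalization divides by the total mass $L(L+1)/2$, so entries lie in
$[0,1]$ and sum to 1. The feature vector takes the diagonal and
above-diagonal entries — 28 values for 7 groups — plus the reciprocal
length $1/L$ as a 29th "sequence tag". The tag matters because the
normalized matrix is scale-free: equal-composition proteins of different
lengths would otherwise be hard to tell apart. Two proteins of different
length, or of equal length but different group counts, always receive
different vectors (the tag or a diagonal entry differs); the converse is
false — distinct sequences of equal length and composition can share a
matrix (the test suite exhibits a collision found by exhaustive search over
short sequences), so the descriptor is deliberately lossy.

### Flattening order

No canonical order exists for the 28 upper-triangle entries; any fixed
order is equivalent for learning. The package freezes row-major order
including the diagonal — $(1,1), (1,2), \dots, (1,7), (2,2), \dots, (7,7)$
— with the $1/L$ tag appended last, and names the columns `m11 … m77,
invlen`. Matrices are kept as exact integer counts (stored in doubles,
exact up to $L \approx 9 \cdot 10^7$) until normalization.

## Comparison encoders

Three standard encoders are provided so the descriptor can be compared at
matched pipeline conditions. They are defined by their original
literature, since each is named but not re-derived here:

* **CT (conjoint triad)**, 343 per protein: counts of all $7^3$ consecutive
  group triads over sliding windows, rescaled per protein as
  $d = (f - \min f)/\max f$.
* **AC (auto covariance)**, 210 per protein: for seven z-standardized
  physicochemical scales (hydrophobicity, hydrophilicity, side-chain
  volume, polarity, polarizability, solvent-accessible surface area, net
  charge index) and lags $1..30$, the mean-centered lagged covariance
  $\frac{1}{L-d}\sum_i (x_{i} - \bar x)(x_{i+d} - \bar x)$. Sequences must
  exceed the maximum lag.
* **LD (local descriptor)**, 630 per protein: composition, transition and
  distribution features of the reduced sequence over ten overlapping
  regions (four quarters, two halves, central 50%, first/last 75%, central
  75%; 63 features each). Region endpoints use floor on 0-based half-open
  slices — a frozen tie-break, documented rather than canonical.

Per-pair vectors concatenate the two protein vectors in the pair's listed
(a, b) order, giving 58 / 686 / 420 / 1260 values; no swap-augmentation or
symmetrization is applied by default (a config-level choice left off
because listed pair order is the convention of the interaction files).

## Dataset assembly

`read_pairs()` reads the two-column id lists that interaction supplements
ship as; `filter_records()` applies the usual benchmark hygiene in a fixed,
counted order: drop pairs with missing sequences, self-interactions,
unordered duplicate pairs, then pairs containing a protein with unusual
residues (B, J, O, U, X, Z or any non-standard character) or shorter than
50 residues. Duplicates are deduplicated as *unordered* pairs — (a, b) and
(b, a) describe one physical interaction. The optional `collision_filter`
removes pairs whose proteins share length and group composition (such
proteins are indistinguishable to MOS); it defaults off because it is a
caveat of the descriptor, not a step of the standard benchmark recipe, and
turning it on is a measurable choice the exclusion report records.

## The classifier

The classifier is a fully-connected network: `depth` hidden ReLU layers of
`width` units and one sigmoid output, minimizing mean binary cross-entropy
with Adam. The default operating point is learning rate 0.01, width 512,
depth 3, batch size 128, dropout 0; `baseline_model_config()` (learning
rate 0.001, width 256) is the preset conventionally used with the wider
CT/AC/LD inputs. "Iterations" are minibatch steps, not epochs. Choices the
operating point leaves open are frozen as: Adam $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$; fan-in-scaled uniform weight
initialization $U(-s, s)$, $s = \sqrt{6/\text{fan-in}}$, zero biases; a
0.5 decision threshold for the confusion counts; probability clipping at
$10^{-12}$ so the cross-entropy stays finite. Everything is seeded, so
training is bit-reproducible. Decision-tree, k-NN and random-forest
baselines are thin wrappers over rpart, class and randomForest at
documented defaults (k = 5, 200 trees), exposed through the same
predict/evaluate contract.

AUC is computed by the midrank (Mann–Whitney) statistic, which equals the
trapezoidal area under the ROC curve with ties counted one half; the test
suite checks it against an exhaustive pairwise-rank oracle.
`holdout_repeat()` reports each metric as mean ± sample standard deviation
over independent stratified split/train/evaluate cycles (a single repeat
reports sd 0 by convention); metrics are computed on the held-out rows,
never on training rows.

## What the synthetic generator emulates — and what it does not

Real PPI benchmarks cannot be redistributed with a package, so the test
surface is a generator that emulates their *shape*: a proteome of
random-composition sequences (length 50–200, standard alphabet, so every
protein passes the filters untouched) and labeled pair lists with a planted
signal. The signal lives at the level of seven-group composition: proteins
belong to one of `n_archetypes` (default 4) latent composition archetypes,
and `effect` $\in [0,1]$ interpolates each archetype's residue-frequency
center between a shared baseline (effect 0) and a distinct random
composition (effect 1); per-protein frequencies are drawn from a Dirichlet
around that center (concentration 100) and residues i.i.d. from them.
Interacting pairs join same-archetype proteins, non-interacting pairs
different archetypes. Placing the signal in group composition guarantees
every encoder can in principle see it — the MOS diagonal is a deterministic
function of composition. At effect 0 all centers coincide, so the labels
are provably uninformative and a correct pipeline must score chance-level
AUC; recovered AUC grows monotonically with effect.

One point of the generator's contract was genuinely contradictory as
specified informally: a proteome cannot be simultaneously independent of
the class-separation strength and carry a composition-level planted signal.
The package resolves this by letting `effect` shape the proteome (archetype
separation) and keeping the pairing rule fixed; the invariant that matters
— effect 0 implies no recoverable signal — holds exactly.

The generator does **not** emulate protein evolution, domain structure,
binding interfaces, length/composition biases of real interactomes, or
sequence redundancy. Passing the planted-signal benchmark therefore shows
the pipeline is *correct* (encoders expose composition, the network learns
pair similarity, the metrics are honest), not that any encoder will reach
published accuracies on curated human data — that depends on external
sequence databases outside this package's scope.

## Problem sizes and numerical choices in the shipped checks

The packaged checks run at desk scale, chosen once as the smallest sizes
that make the statistics stable: the oracle-equivalence property uses 500
random group sequences of lengths 1–300; the planted-signal benchmark uses
600 proteins, 2000 + 2000 pairs, a 1500/1500 training split and 1000 Adam
steps at the default 512×3 network (holdout AUC comfortably above 0.99 at
effect 0.8); the null check uses three seeds at effect 0 with 1000 + 1000
pairs and a width-64 network — at chance, the mean AUC over three holdouts
of 500 pairs has a standard error of about 0.015, so the ±0.05 band is a
sharp but reliable test. The monotonicity property is checked at effects
0 / 0.4 / 0.8 with three seeds each at a smaller scale (250 + 250 pairs,
width 32).

## Known limitations

* The descriptor is non-injective by construction; same-length,
  same-composition proteins collide. The optional collision filter exists
  for exactly this case.
* AC depends on published property scales; alternative scale sets would
  change its values (not its dimension).
* k-NN stores its training table; on large tables prediction, not
  training, is the expensive step.
* The network trains on CPU BLAS; at the default width, a few thousand
  steps per minute. Large benchmarks would want smaller widths or fewer
  steps first.
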