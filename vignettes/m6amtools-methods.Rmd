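---
title: "m6amtools: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{m6amtools: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6amtools)
```

## The prediction problem

m6Am (N6,2′-O-dimethyladenosine) sits on the first transcribed adenosine
of capped mRNAs. The classification task addressed here takes a 41-nt RNA
window whose central base (position 21) is a candidate adenosine and
predicts a binary modification status. The package assumes inputs are
*pre-windowed*: extracting windows from transcripts, and redundancy
filtering of near-identical windows (typically done upstream with CD-HIT),
are outside its scope. Windows are validated strictly — exact length,
alphabet {A, C, G, U} after mapping T to U, central A (toggleable) — and
ambiguity codes are rejected rather than imputed, because none of the
encoders defines a value for an ambiguous base.

## The feature space

Each window is encoded by nine schemes into one named numeric vector.
Dimensional contracts (length-L window):

* **PseEIIP** (L + 64): positional electron–ion interaction potentials
  (A 0.1260, C 0.1340, G 0.0806, U 0.1335) followed by
  `EIIP_xyz * f_xyz` for the 64 trinucleotides, with
  `f_xyz = N_xyz / (L - 2)`.
* **Hash** (L − 1 at k = 2): each sliding dinucleotide read as a two-digit
  base-4 number under the scheme's own digit order A0, G1, C2, U3.
* **DBE** (4(L − 1)): two bits per base, A = (0,0), C = (1,0), G = (1,1),
  U = (0,1). The A and G codes are fixed by the scheme's published
  examples (AA→0000, GG→1111); the C and U codes are the unique completion
  consistent with AC→(0,0,1,0) and AT→(0,0,0,1).
* **NCP** (3L): ring/amino/H-bond triples, A = (1,1,1), C = (0,1,0),
  G = (1,0,0), U = (0,0,1).
* **PseKNC** (4^k + λ): normalized k-tuple frequencies plus λ correlation
  tiers; tier j is the mean squared property distance between
  dinucleotides j apart, `θ_j = mean_i Φ(d_i, d_{i+j})` over
  i = 1..(L − j − 1), weighted by ω. All components share one
  denominator, so the block always sums to exactly 1 — a useful invariant
  that holds regardless of which property table is used.
* **DNM** (48): per dinucleotide, the occurrence count n, mean occurrence
  position u, and normalized positional variance
  `D² = Σ(i − u)² f(t_i) / (n (L − 1))`; an absent dinucleotide is emitted
  as (0, 0, 0) to avoid 0/0 (the scheme's defining formulas do not cover
  this case).
* **K-mer** (Σ 4^k, k = 2, 3, 4): raw sliding counts, not frequencies.
* **SCPseTNC** (64 + λΛ): trinucleotide frequencies plus
  series-correlation factors `θ = mean_i P_ξ(tri_i) P_ξ(tri_{i+m})` over
  i = 1..(L − m − 3), one factor per (property ξ, lag m) pair, ordered by
  lag then property.
* **Ksnpf** (16 · max_gap): frequencies `S / (L − k − 1)` of ordered base
  pairs with exactly k intervening positions, k = 1..5.

All k-mer-indexed blocks use strict lexicographic order A < C < G < U;
internally a k-mer is a base-4 integer, so lexicographic and numeric order
coincide and a fixed, reproducible column order is guaranteed — models
refuse input whose columns differ in name *or order* from the ones they
were trained on.

### The total dimensionality question

The scheme-by-scheme contracts on a 41-nt window give 892 features for
the seven schemes with no free parameters, plus 64 for SCPseTNC at its
default λ = 0, plus 4^k + λ for PseKNC. A commonly quoted total of 1120
for this nine-scheme space cannot be reconstructed from those contracts:
it would require PseKNC to contribute 164 dimensions, which 4^k + λ
cannot reach for k = 2 with the admissible λ < 40. The package therefore
treats the total as configuration-dependent. The default PseKNC setting
is k = 2 (the frequency part covers the 16 dinucleotides), ω = 0.1 and
λ = 8 — a modest lag depth typical of pseudo-composition encoders, small
relative to the 40 dinucleotide positions of a 41-nt window — giving 980
features in total.

### Physicochemical property tables

PseKNC and SCPseTNC weight their correlation terms by per-dinucleotide
and per-trinucleotide property vectors (Λ = 6 and 12 at the defaults).
Published property compilations exist for both, but no single canonical
choice is pinned down for this task, so the package ships *synthetic*
built-in tables: deterministic sequence-derived indices (EIIP sum, GC /
purine / amino / keto content, a nearest-neighbour stacking proxy,
nucleotide-monophosphate mass, base-transition count, terminal EIIPs) for
each oligomer. They satisfy everything the encoders require — fixed,
distinct, standardizable numeric vectors per oligomer — and are
standardized to zero mean and unit variance across oligomers before use,
as pseudo-composition methods prescribe. Users with a preferred published
compilation can pass it via `encoder_config(psekn_properties = ...,
scptnc_properties = ...)`; a property that is constant across oligomers
is rejected at standardization. Note that at the defaults
(`scptnc_lambda = 0`) SCPseTNC reduces to pure trinucleotide frequencies
and uses no properties at all.

## Feature selection

Importance comes from an extremely-randomized-trees ensemble (100 trees
by default, impurity importance, fixed seed, single-threaded for
bit-reproducibility). Ties in importance are broken alphabetically by
feature name so a ranking is a deterministic function of (data, seed).
When several sub-training datasets are available, each is ranked
separately and the normalized scores averaged (`average_rankings()`),
which is also what `run_pipeline()` does.

The equidistant search evaluates nested prefixes of the ranking at sizes
step, 2·step, …, appending the full feature count when it is not a
multiple of the step (1120 features at step 50 → 23 evaluations). The
best size maximizes mean cross-validated AUC; ties go to the *smaller*
subset, which matters in the saturated regime where several prefixes
reach identical AUC.

## Modeling

The classifier is a gradient-boosted decision-tree ensemble (xgboost
backend: histogram trees, second-order "Newton" leaf estimates, binary
log-loss). The default configuration — 2000 iterations, depth 9, learning
rate 0.03 — is the tuned operating point for this task; the tuning grids
(iterations {100, 250, 500, 1000, 1500, 2000}, depth 1–10, learning rate
{0.001, 0.01, 0.03, 0.1, 0.2, 0.3}) span 360 candidate configurations,
searched exhaustively by mean CV AUC with ties preferring fewer
iterations, then shallower trees, then smaller learning rates — the
cheapest of equally good models. A `loss_function = "MultiClass"`
compatibility mode fits a two-class softmax instead; for 0/1 labels the
two objectives induce the same ranking behavior, and a test asserts their
AUCs agree.

The hard-label threshold is fixed at 0.5 throughout; none of the reported
metrics motivates a tuned threshold, and AUC is threshold-free.

## Evaluation protocol

Metrics are the standard six: Sn = TP/(TP+FN), Sp = TN/(TN+FP), ACC, F1,
MCC and AUC. MCC's denominator is computed in double precision (the
four-factor product overflows 32-bit integers already at a few hundred
samples per cell) and set to 0 when any marginal vanishes. AUC is the
rank (Mann–Whitney) statistic, identical to the trapezoid area under the
returned ROC — a consistency the tests assert to 1e−9; ties receive half
credit. The PR curve sets precision to 1 at recall 0 by convention.

Cross-validation uses stratified folds: each class is permuted under the
seed and dealt round-robin, so fold class ratios match the dataset up to
rounding. The choice of stratification is deliberate — the balanced
sub-training datasets make it nearly equivalent to plain partitioning,
but it prevents degenerate single-class folds on small data, and a fold
that still ends up single-class is a hard error rather than a silent NaN.
The independent test refuses any window id that also occurs in the
model's training ids.

Aggregation across sub-training datasets reports mean ± SD *over the
per-dataset means* (not over all folds pooled), using the sample (n − 1)
SD.

## The synthetic generator

`generator_spec()` emulates the *shape* of the published m6Am benchmark:
41-nt A-centered windows, 3700 positives vs 37,000 negatives by default
(the 1:10 imbalance that motivates negative splitting), uniform
background composition. Class signal is planted in two ways, both scaled
by `effect_size`: a 6-nt motif (consensus GGACUC) immediately downstream
of the central A, detectable by positional encoders (NCP, DBE, Hash,
positional EIIP), and a mild GC-ward composition shift at the remaining
positions (at most 15 percentage points of probability mass at
`effect_size = 1`), detectable by compositional encoders (k-mer, PseEIIP
products). At `effect_size = 0` the two classes are identically
distributed by construction.

What passing synthetic tests does and does not show: the generator
produces i.i.d. positions with a single deterministic motif site, so it
validates the *mechanics* of the pipeline — encoders, selection, model,
metrics, splits — and its ability to recover a planted signal at a known
scale. Real m6Am windows have TSS-adjacent context, correlated positions
and subtler motifs; performance numbers obtained on synthetic data say
nothing about accuracy on real transcriptomes.

## Problem sizes used by the shipped checks

The test suite runs the planted-signal experiment at one full
sub-training scale (3700 + 3700 windows, 10-fold CV, 100 boosting rounds
at depth 6 — boosting-round counts reduced from the tuned 2000 since the
planted signal saturates far earlier) and the null experiment at
1000 + 1000; oracle-equivalence checks use 200 random windows of length
8–15; the selection and grid checks run on small planted-feature
matrices. All seeds are fixed in the tests; every randomized quantity is
reproducible.

## Known limitations

* No transcriptome scanning: the package classifies given windows only.
* No redundancy filtering; supply CD-HIT-reduced data if that matters.
* The default property tables are synthetic built-ins (above), not a
  published compilation; override them for property-sensitive work.
* Boosting determinism is guaranteed single-threaded; multi-threaded
  training may differ at floating-point level across platforms.
* The independent-test guard is id-based; it cannot detect two different
  ids carrying identical sequences.
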