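# m6amtools

Feature encoding, feature selection and gradient-boosted classification of
N6,2′-O-dimethyladenosine (m6Am) sites in RNA.

m6Am is a reversible mRNA modification of the first transcribed adenosine
next to the 5′ cap, implicated in transcript stability and cancer
progression. Experimental mapping of m6Am sites is slow and expensive, so
sequence-based classifiers are used to triage candidate sites: given a
41-nt window centered on a candidate adenosine, predict whether it is
modified. `m6amtools` implements that pipeline end to end for R users —
from FASTA windows to cross-validated performance reports — together with
a synthetic window generator so every stage can be exercised and tested
without access to benchmark data.

## What it computes

1. **Nine sequence encodings** turn each window into a named numeric
   vector (980 features at the defaults for a 41-nt window):

   | scheme | idea | dims (L = 41) |
   |---|---|---|
   | PseEIIP | per-position electron–ion interaction potential (EIIP) values plus EIIP·frequency products over the 64 trinucleotides, `EIIP_xyz = EIIP_x + EIIP_y + EIIP_z`, `f_xyz = N_xyz/(L−2)` | 105 |
   | Hash | sliding dinucleotides as two-digit base-4 numbers (A0, G1, C2, U3) | 40 |
   | DBE | 4-bit positional code per overlapping dinucleotide | 160 |
   | NCP | (ring, amino/keto, H-bond) chemical-property triples per base | 123 |
   | PseKNC | k-tuple frequencies + lag-λ property-distance correlation factors | 16 + λ |
   | DNM | count, mean position and positional variance per dinucleotide | 48 |
   | K-mer | occurrence counts for k = 2, 3, 4 | 336 |
   | SCPseTNC | trinucleotide frequencies + series-correlation terms | 64 |
   | Ksnpf | ordered base-pair frequencies at gaps 1–5 | 80 |

2. **Feature selection**: impurity importances from an
   extremely-randomized-trees ensemble rank all features; an *equidistant
   search* evaluates nested top-k prefixes (k = 50, 100, …) by
   cross-validated AUC and keeps the smallest best subset.
3. **Modeling**: a gradient-boosted decision-tree classifier (tuned
   operating point: 2000 iterations, depth 9, learning rate 0.03) with
   exhaustive grid-search tuning.
4. **Evaluation**: ACC, AUC, Sn, Sp, F1 and MCC
   (`MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`), stratified
   10-fold cross-validation, ROC/PR curves, and a leakage-guarded
   independent test.
5. **Imbalance handling**: a 1:10 positive:negative benchmark is split
   into 10 balanced sub-training datasets (all positives + one of 10
   disjoint negative shards); metrics are reported as mean ± SD across
   them.

## Worked example

```r
library(m6amtools)

# a synthetic benchmark: 400 positives, 4000 negatives, planted signal
ds <- generate_windows(generator_spec(n_pos = 400, n_neg = 4000,
                                      effect_size = 0.8, seed = 1))
ds
#> m6am_dataset: 4400 windows (400 positive, 4000 negative), length 41 nt

# balanced sub-training splits, then encode the first one
splits <- make_subtraining_splits(ds, n_splits = 10, seed = 1)
X <- encode_matrix(splits[[1]])          # 800 x 980

# importance ranking: positional features at the planted motif dominate
head(rank_features(X, splits[[1]]$label, seed = 1), 3)
#>   rank       feature     score
#> 1    1    DBE.p23.b1 10.801833
#> 2    2 PseEIIP.pos22 10.681431
#> 3    3 PseEIIP.pos23  9.915462

# 10-fold cross-validation of a boosted-tree model
cfg <- model_config(iterations = 100, depth = 6, learning_rate = 0.3, seed = 1)
cross_validate(X, splits[[1]]$label, k = 10, seed = 1, config = cfg)
#> 10-fold cross-validation
#>   ACC  0.938 +/- 0.022
#>   AUC  0.991 +/- 0.006
#>   Sn   0.943 +/- 0.054
#>   Sp   0.932 +/- 0.041
#>   F1   0.937 +/- 0.023
#>   MCC  0.878 +/- 0.042
```

The ranking picks out positions 22–27 — exactly where the generator plants
its motif downstream of the central A — and the cross-validated AUC of
0.991 reflects the strong planted signal (at `effect_size = 0` the same
pipeline returns chance-level AUC ≈ 0.5).

`run_pipeline(run_config(...))` chains all stages
(simulate → split → encode → rank → select → tune → train → evaluate) into
one reproducible run directory with a `MANIFEST.json`; the same stages are
available from a shell via `exec/m6amtools
simulate|encode|rank|train|cv|predict|pipeline`.

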