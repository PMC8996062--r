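# essMiR

Predicting **essential microRNAs** from pre-miRNA sequence and secondary
structure with gradient-boosted classification trees.

Some miRNA genes are essential: knocking them out produces lethal or
infertile phenotypes. Determining essentiality experimentally is slow and
expensive, so sequence-based classifiers that rank candidate pre-miRNAs
by their probability of being essential are a practical screening tool.
`essMiR` is a complete, tested implementation of such a pipeline for
bioinformaticians who want to train, calibrate, evaluate and apply this
kind of predictor — on their own labeled pre-miRNA sets or on fully
synthetic data generated by the package itself.

## What it computes

A pre-miRNA `R = r1 r2 ... rl` (`ri ∈ {A,C,G,U}`) and, where needed, its
MFE dot-bracket structure `S = s1 s2 ... sl` are turned into one of five
feature vectors:

| scheme | dimension | definition |
|---|---|---|
| `kmer` | 4^k | frequency of each contiguous k-mer among the `l−k+1` windows |
| `mismatch` | 4^k | per k-mer type, the count of windows within Hamming distance m (`Σ_{j≤m} c_{i,j}`) |
| `subsequence` | 4^k | per type, `Σ δ^{len(a)}` over gapped index tuples; a contiguous match counts `δ⁰ = 1`, a gapped match `δ^{span}` |
| `triplet` | 32 | frequency of (paired/unpaired pattern of `s_{i−1} s_i s_{i+1}`, bracket direction collapsed) × center nucleotide |
| `psedsspc` | 10 + 100d + λ | status frequencies over the 10 structural statuses (A, C, G, U, A-U, U-A, G-C, C-G, G-U, U-G), distance-indexed ordered status-pair frequencies, and energy correlation tiers `g_k = (1/(l−k)) Σ (e(t_i) − e(t_{i+k}))²`, jointly weight-`w` normalized to unit sum |

Classification is by CART-style trees split on the Gini index
`G(D) = 1 − Σ p_i²` with branch purity `I(D,α) = Σ (|D_j|/|D|) G(D_j)`,
boosted into an ensemble with a logistic-loss gradient-boosting stage
(shrinkage `R`, per-tree depth `D`, L2 penalty `λ`, `T` rounds).
Evaluation reports Acc, Pre, Rec, F1 and AUROC from pooled leave-one-out
or repeated stratified 5-fold cross-validation, and hyper-parameters are
calibrated by a sequential (coordinate-wise) grid search that scans each
parameter in order while later ones sit at their defaults.

## Worked example

```r
library(essMiR)

## a labeled synthetic benchmark: 30 essential sequences carry a planted
## GGGCCC motif, 30 non-essential ones are guaranteed motif-free
ds <- plantedMotifDataset(nPos = 30, nNeg = 30, motif = "GGGCCC",
                          insertionRate = 1, seed = 42)
ds
#> LabeledRnaSet: 60 sequences (30 essential, 30 non-essential)

fm <- batchEncode(ds, encoderParams("kmer", k = 3))
fm
#> FeatureMatrix: 60 sequences x 64 features (kmer)
round(featureValues(fm)[1, c("GGG", "GGC", "GCC", "CCC")], 4)
#>    GGG    GGC    GCC    CCC
#> 0.0135 0.0135 0.0135 0.0541

report <- loocv(ds, encoderParams("kmer", k = 3), modelSpec("boosted"),
                seed = 1)
report
#> MetricsReport (loocv): Acc=0.767 Pre=0.750 Rec=0.800 F1=0.774 AUROC=0.787
#>   counts: TP=24 TN=22 FP=8 FN=6
```

Every held-out sequence was scored by a 100-tree boosted model trained on
the other 59; the pooled scores give the confusion counts at the 0.5
cutoff and an AUROC of 0.787 — the planted 6-mer is recoverable from
3-mer composition, and the signal strengthens with sample size (it
exceeds 0.90 AUROC at 100 + 100 sequences).

Structure-aware schemes fold on the fly (or take a dot-bracket file):

```r
db <- foldRna(rnaSequences(ds)[1])     # ViennaRNA RNAfold, version recorded
tr <- assignStatus(as.character(rnaSequences(ds)[[1]]), db[[1]])
v  <- encodePseDSSPC(tr, d = 5, lambda = 5, w = 0.5)   # 515 dimensions
```

The same workflows are scriptable from a shell through the bundled CLI
(`system.file("cli", "essmir.R", package = "essMiR")`), with commands
`make-fixtures`, `encode`, `train`, `evaluate`, `predict` and
`calibrate`; every command writes its resolved configuration beside its
output and is byte-reproducible under a fixed `--seed`.

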