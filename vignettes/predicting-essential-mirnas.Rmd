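---
title: "Predicting essential miRNAs from sequence and structure features"
author: "essMiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting essential miRNAs from sequence and structure features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essMiR)
```

## The problem and the model

A small number of miRNA genes are essential: silencing them is lethal or
causes infertility. `essMiR` frames essentiality prediction as binary
classification of the pre-miRNA hairpin (label 1 = essential, the
positive class everywhere in the package: in metrics, ROC direction and
output files). The classifier sees only the primary sequence and,
optionally, the minimum-free-energy secondary structure, encoded by one
of five feature schemes, and is either a single Gini-criterion
classification tree or a gradient-boosted ensemble of such trees with a
logistic objective.

The model makes the usual assumptions of this family: sequence
composition carries the signal (no alignment, no conservation, no
expression data); the MFE structure is an adequate structural summary
(no base-pair probabilities or suboptimal ensembles); and the canonical
probability output is thresholded at 0.5 for hard labels, since nothing
in the problem dictates an asymmetric cutoff.

## The five encoders

Throughout, k-mer types are ordered lexicographically with
`A < C < G < U`; this fixes the identity of every feature dimension
across the package, since no external convention exists.

**k-mer frequencies** (dimension `4^k`, `k` in 1..6): counts of the
`l − k + 1` windows, divided by the window count, so the vector sums
to 1.

**Mismatch counts** (dimension `4^k`, `k` in 1..6, `m` in 0..k−1): for
each type, the number of windows within Hamming distance `m` — the sum
of the exact-`j`-mismatch occurrence counts for `j = 0..m`. These are
raw counts: the defining sums are accumulations, not frequencies, and
tree learners are invariant to monotone per-feature scaling, so we keep
the literal form and record the convention in the provenance. At
`m = 0` the encoder is exactly the k-mer count vector — an identity the
tests assert bit-exactly.

**Gap-weighted subsequence sums** (dimension `4^k`, `k` in 2..4, decay
`δ` in [0, 1]): for each type, the sum over all ordered index tuples
`p1 < … < pk` spelling that type of a decay weight. We read the length
function of the matched subsequence as its span (`pk − p1 + 1`), with
the contiguous case weighted `δ⁰ = 1` exactly — so `δ = 0` collapses to
contiguous k-mer counts (with `0⁰ := 1`), the second exact degeneracy
identity. The production path is a prefix dynamic program: for a growing
prefix word, `M[p]` accumulates `Σ δ^(p − p1)` over matching tuples
ending at `p`, extended through the linear recurrence
`S[p] = δ (S[p−1] + M[p−1])`. It is exact, not an approximation; an
exhaustive tuple-enumeration twin backs it in the tests over the full
parameter grids.

**Structural triplets** (dimension 32): for each interior position, the
paired/unpaired pattern of the three surrounding structure symbols
(bracket direction collapsed, 8 patterns) crossed with the center
nucleotide, normalized by the `l − 2` windows. We compute the
composition over the full pre-miRNA rather than extracting a hairpin
segment first; the encoding is well defined for any structure, and
full-sequence application keeps the operation a pure function of
(sequence, structure). Users following the segment-extraction convention
of some earlier triplet work can simply pass the truncated sequence and
structure.

**PseDSSPC** (dimension `10 + 100·d + λ`): each residue gets one of ten
structural statuses — its own nucleotide when unpaired, or the ordered
pair type `X-Y` (six canonical/wobble categories) when paired. Block 1
holds the ten status frequencies; block 2, for each distance `1..d`, the
100 ordered status-pair frequencies normalized by the `l − d'` available
pairs (the ordered reading is what makes the printed 100-per-distance
count come out); block 3, for each lag `k = 1..λ`, the mean squared
difference of per-status pseudo energies,
`g_k = (1/(l−k)) Σ (e(t_i) − e(t_{i+k}))²`. With
`Z = Σ(blocks 1–2) + w Σ(block 3)`, blocks 1–2 are divided by `Z` and
block 3 multiplied by `w/Z`. Because block 1 sums to 1 and each distance
slice of block 2 sums to 1, `Z = 1 + d + w Σ g`, and the emitted vector
always sums to exactly 1 — a property the tests assert.

### The energy table

No published table fixes `e(t)` for the ten statuses, and only squared
*differences* of `e` enter the features, so any fixed lookup yields a
well-defined, reproducible encoder. The shipped default sets the four
unpaired statuses to 0 and grades the paired ones by hydrogen-bond
count: `G-C/C-G = −3`, `A-U/U-A = −2`, `G-U/U-G = −1` (pseudo-energy
units). Every consuming function accepts a replacement named vector, so
a recovered original table can be dropped in without code changes.

## Structures

Folding delegates to ViennaRNA's `RNAfold` at its default settings
(temperature, dangles); the engine name and version are attached to
every folded result, since MFE structures can change across engine
versions. We deliberately do not reimplement MFE folding. Structures can
equally be supplied as Vienna-style dot-bracket files; both paths run
the same validator (plain three-symbol alphabet — pseudoknot dialects
are rejected — balanced brackets, length agreement), and file-supplied
structures additionally face the canonical-pair check: a predicted
`A-C` pair is a hard error naming the positions, because no MFE engine
emits one and silent coercion would corrupt the status track. Positions
are 1-based everywhere, in storage and messages.

## Classifiers

The Gini index and the size-weighted branch purity are standalone,
tested operations, and the in-package CART trainer splits on exactly
that criterion. The trainer is grown in-package because the calibration
grid demands two things mature R tree learners do not expose together: a
`"random"` splitter (one uniform threshold per candidate feature) and a
fresh uniform subsample of `maxFeatures` candidate features at every
split. Splits stop at the depth cap, at pure nodes, or when no candidate
reduces impurity; ties break toward the first candidate encountered, so
training is a pure function of (features, labels, parameters, seed). On
plain separable data its predictions coincide with `rpart` configured
for the Gini criterion — an independent cross-check in the test suite,
not a code path.

The boosted stage wraps xgboost (`binary:logistic`, single-threaded)
with the grid's four knobs: rounds `T`, shrinkage `R`, per-tree depth
`D` and L2 penalty `λ`. When a parameter is not under scan it sits at
the conventional defaults of the underlying learners — `T = 100`,
`R = 0.3`, `D = 6`, `λ = 1`; trees: best splitter, depth 6, all
features — which we document as our own defaults rather than claim as
anyone else's. Models persist as a single-file bundle embedding the
fitted state, hyper-parameters, encoder provenance, seed and a schema
version; loading refuses unknown schemas, and prediction refuses feature
matrices whose encoder provenance does not match the model's.

## Evaluation protocols

`computeMetrics()` derives TP/TN/FP/FN at the cutoff and reports
accuracy, precision, recall, F1 and AUROC; AUROC is the rank statistic
(ties contribute 1/2), cross-checked in tests against exhaustive
positive–negative pair counting and against pROC. Metrics with a zero
denominator are reported as 0 with an explicit flag — never NA — so
aggregation across repetitions cannot fail.

LOOCV pools all `n` held-out scores into a single ROC; a per-fold ROC is
undefined for singleton folds, making pooling the only well-defined
reading. Repeated k-fold CV is stratified by class — with about 150
sequences and 5 folds, unstratified folds risk a class-empty fold, which
would make the protocol ill-defined — and repetition `r` derives its
shuffle and training seed from `seed + r`; the five statistics are
averaged arithmetically across repetitions.

`sequentialGridSearch()` implements coordinate-wise calibration: scan
parameter 1 with the rest at defaults, fix its argmax, move on. Ties
break toward the first-listed value; with value lists ordered
simple-first this biases toward simpler models, and it makes the scan
deterministic. The full (cell → objective) trace is returned and
serializable for audit. Preset grids reproduce the standard scan ranges
(k = 1..6; m = 0..k−1 adaptively after k is fixed; k = 2..4 with
δ = 0.1..0.9; d = 1..10, λ = 1..20, w = 0.1..0.9; splitter/depth/max
features; T = 50..500 step 10, R = 0.1..0.5 step 0.02, D = 3..10,
λ = 0..2 step 0.1). The boosting grid targets AUROC; the feature and
tree grids target accuracy, reflecting which statistic each scan is
meant to optimize, and the objective is a field of the grid so either
choice is one argument away.

## Synthetic data, and what passing tests do and do not show

The generator emulates only the *shape* of a curated essentiality
dataset: two balanced classes of a few hundred hairpin-sized RNAs
(default 100 + 100 sequences of 60–90 nt, matching the order-10² scale
and ~60–110 nt lengths of curated pre-miRNA essentiality sets), with a
deterministic seed. The discriminative signal is a planted 6-mer
(`GGGCCC` by default) inserted into every positive and rejection-sampled
out of every negative. Hairpin fixtures carry their own ground-truth
dot-bracket, so every structural encoder is testable without a folding
engine. None of this models miRNA biology — no biogenesis signals, no
conservation, no class imbalance (real genomes are heavily imbalanced,
so genome-wide application of any such classifier will produce false
positives). A pipeline that recovers the planted motif demonstrates that
encoding, training and cross-validation are wired correctly and leak
nothing; it does not certify performance on real pre-miRNAs.

Problem sizes used by the shipped checks: oracle-equivalence sweeps run
hundreds of random sequences of length ≤ 12 (exhaustive enumeration
stays exact and fast there); the end-to-end benchmark runs pooled LOOCV
at n = 200, where the boosted 3-mer model exceeds 0.90 AUROC; chance
behavior is verified as the mean AUROC over 20 label permutations at
n = 60, which sits within 0.5 ± 0.1. The permutation mean lands slightly
below 0.5 (≈ 0.47–0.49): under label permutation the held-out sample's
class is underrepresented in its own training fold, a known pessimistic
bias of pooled LOOCV that shrinks as n grows.

## Numerical and degenerate-input choices

Sequences are canonicalized on input (uppercase, `T → U`); any other
residue is a hard error naming the record and character, because every
encoder's denominator assumes a clean four-letter alphabet. Boundary
lengths are legal one-window inputs (`l = k` for the string kernels,
`l = 3` for triplets, `l = max(d, λ) + 1` for PseDSSPC); shorter
sequences error naming the id and both lengths. The subsequence DP uses
a forward recurrence rather than the algebraically equivalent
`δ^p · cumsum(δ^{−q})` form, which would lose precision for small `δ`
and long sequences. Class-proportion validation in `giniIndex()`
tolerates 1e−9 of slack on the unit sum. Functions that consume a seed
restore the ambient RNG state on exit, so seeded calls never perturb a
caller's random stream.

## Example

```{r example, eval = FALSE}
ds <- plantedMotifDataset(nPos = 30, nNeg = 30, seed = 42)
report <- loocv(ds, encoderParams("kmer", k = 3), modelSpec("boosted"),
                seed = 1)
perfMetrics(report)

## calibrate k on a grid, then inspect the scan trace
obj <- loocvObjective(ds, "kmer", kind = "boosted", metric = "auroc")
scan <- sequentialGridSearch(presetGrid("kmer"), obj)
scan$best; scan$trace
```

## Known limitations

Trained on balanced data, the classifier's scores are not calibrated
probabilities under genome-scale class imbalance. The triplet encoder's
full-sequence convention may differ from segment-extracting
implementations, and whether upstream feature servers rescaled mismatch
or subsequence outputs before training is unknowable from their
descriptions — both conventions are recorded in the provenance so
results remain comparable within this package. The PseDSSPC energy
table is a documented default, not a recovered original. Single-tree
training is quadratic in candidate cut points per split and intended
for the few-hundred-sample regime this problem lives in.
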