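---
title: "Predicting polystyrene surface-binding peptides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting polystyrene surface-binding peptides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phage display panning against targets immobilized in polystyrene plates
routinely recovers peptides that bind the plastic rather than the target.
These polystyrene surface-binding peptides (PSBPs) are a common class of
target-unrelated peptide (TUP): left unrecognized they contaminate panning
results, while deliberately selected they make useful affinity tags for
ELISA-style assays. `psbp` classifies a short peptide as PSBP or non-PSBP
from sequence alone, so that biopanning hit lists can be screened cheaply in
either direction.

## The model

A peptide over the 20-letter alphabet is encoded by its amino-acid
composition (AAC) and dipeptide composition (DPC):

$$\mathrm{AAC}_i = \frac{x_i}{\sum_{i=1}^{20} x_i}, \qquad
  \mathrm{DPC}_j = \frac{y_j}{\sum_{j=1}^{400} y_j},$$

where $x_i$ counts residues of type $i$ and $y_j$ counts overlapping
dipeptides of type $j$ (windows $(1,2),\dots,(L-1,L)$, so
$\sum_j y_j = L-1$). The 420-dimensional concatenation uses a fixed layout —
indices 1–20 are the AAC in alphabetical residue order, 21–420 the DPC in
row-major alphabetical order — because feature subsets and persisted models
index into it.

Features are ranked by the F-score,

$$F(i) = \frac{(\bar{x}^{+}_i - \bar{x}_i)^2 + (\bar{x}^{-}_i - \bar{x}_i)^2}
  {\tfrac{1}{n^{+}-1}\sum_k (x^{+}_{k,i}-\bar{x}^{+}_i)^2 +
   \tfrac{1}{n^{-}-1}\sum_k (x^{-}_{k,i}-\bar{x}^{-}_i)^2},$$

the ratio of between-class separation to pooled within-class variance, as in
LIBSVM's feature-selection tooling. Forward selection then adds features to
an initially empty set in descending F-score order; after each addition the
stratified fivefold cross-validated accuracy of an RBF-kernel SVM on the
current set is measured, and the prefix with the maximum accuracy (smallest
prefix on ties) is the optimal subset. The final classifier is a C-SVM with
radial kernel and Platt probability output (LIBSVM via **e1071**), with
$(c, \gamma)$ chosen by exhaustive search over the canonical log-spaced
grids $c \in \{2^{-5}, 2^{-3}, \dots, 2^{15}\}$,
$\gamma \in \{2^{-15}, 2^{-13}, \dots, 2^{3}\}$. A peptide is called PSBP
iff its calibrated PSBP probability is at least 0.5 (a neutral, configurable
cutoff).

## Curation rules

Training sets are assembled by, in order: deletion of the flanking cysteines
of circular peptides (applied once, only when a sequence of length ≥ 3 both
starts and ends with C); exclusion of sequences containing ambiguous
residues (B, J, O, U, X, Z) or non-alphabetic characters; removal of exact
duplicates (within each class, and negatives identical to a positive); and a
Generalized Jaccard similarity filter that keeps only negatives strictly
below 0.90 similarity to every positive. Similarity is computed on
residue-count multisets, $\sum_i \min(x_i,y_i) / \sum_i \max(x_i,y_i)$, the
standard multiset generalization of Jaccard; a dipeptide-count
representation is available as an option since the token set is in principle
open. Positives are never filtered against negatives. "Below 90%" is read
as strict inequality. Every drop is logged with a stage and reason.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` (curation) | 0.90 | Generalized Jaccard cutoff, fraction in (0, 1] |
| `k` | 5 | cross-validation folds |
| `seed` | 1 | fold assignment and Platt-calibration RNG |
| `cost_grid`, `gamma_grid` | $2^{-5..15}$, $2^{-15..3}$ (step $2^2$) | grid-search candidates |
| decision `threshold` | 0.5 | PSBP probability cutoff |
| `retune` | `FALSE` | re-run the grid search at every prefix size during selection |
| `block` | `"dpc"` | feature block: `aac`, `dpc`, or `both` |

`retune = FALSE` performs one grid search on the full feature block and
holds that $(c,\gamma)$ fixed during the forward sweep; this keeps a
400-step sweep at 208 samples in the tens of seconds while changing the
selected prefix little in our experience. Per-step re-tuning is available
when fidelity to the exhaustive protocol matters more than time. The
accuracy-vs-prefix-size curve is retained either way and persisted next to
the selected subset.

## Numerical and design choices

* **Stratified folds.** Folds are stratified by class, sizes within a class
  differing by at most one, with leftover samples rotated across folds
  between classes so overall fold sizes are as equal as possible (104+104
  samples split 42/42/42/41/41). Stratification stabilizes sensitivity and
  specificity at this sample size. Headline Sn/Sp/Acc/MCC are fold averages;
  the AUC is computed on the pooled held-out probabilities because a
  five-point averaged ROC is ill-defined at n ≈ 200. Both the pooled
  confusion matrix and per-fold metrics are reported.
* **Grid-search ties.** Many $(c,\gamma)$ pairs often tie at the maximum
  cross-validated class-prediction accuracy, and the smallest-cost corner of
  the grid can be a degenerate model whose class predictions look fine while
  its Platt probability output is unusable (even inverted) — decision values
  there are vanishingly small. Tied configurations are therefore re-scored
  through the probability pathway (PSBP probability thresholded at 0.5, the
  same mode in which final models are trained), and remaining ties fall to
  smaller cost, then smaller gamma, preferring smoother models.
* **MCC convention.** When any factor of the MCC denominator is zero the
  coefficient is reported as 0 and flagged `mcc_undefined`.
* **No extra feature scaling.** Composition features already lie in [0, 1]
  and are used as defined; no additional [-1, 1] rescaling is applied
  (`scale = FALSE` throughout), keeping the encoding exactly the stated
  normalization.
* **Ranking criterion.** Features enter the forward sweep in descending
  F-score order; accuracy is what is measured at each step. Tie scores are
  broken by ascending feature index, so duplicated columns select
  deterministically.
* **Degenerate inputs.** Length-1 peptides are rejected for any model that
  uses dipeptide features (DPC is undefined there); single-class training
  input is an error; prediction tolerates invalid rows, annotating them
  while scoring the rest.
* **Reproducibility.** All randomness (fold splits, Platt calibration,
  synthetic generation) flows from explicit seeds recorded in reports and
  model metadata; the train-to-predict path is bit-reproducible for a fixed
  seed.

## The synthetic data generator

The package includes a generator for balanced labeled peptide datasets that
emulates the statistical structure reported for PSBPs: positives are
enriched in the aromatic residues W, Y and F (default multiplier 3 on the
background frequency, renormalized) and a configurable fraction of them
(default 0.7) carries one planted PS-binding motif drawn from
{`WXXW`, `FHXXW`, `WXXWXXXW`} at a uniform random offset. Motif wildcard
positions (`X`) are drawn from the *background* distribution, not the
enriched one, so the motif-order signal and the composition signal can be
switched independently — this is what lets tests verify that dipeptide
features capture more than composition. Negatives are i.i.d. draws from the
background distribution (uniform over the 20 residues by default; a
natural-abundance option exists). Default lengths are 7 and 12, mirroring
common phage-display library designs. Motifs longer than a drawn length are
excluded from the motif draw for that peptide. Generated sets pass through
the same curation pipeline as real data, with bounded resampling so exactly
`n_per_class` peptides per class survive.

The default `n_per_class = 104` matches the shape of the published training
corpus for this problem. The corpus shipped at
`inst/extdata/synthetic_training_{pos,neg}.fasta` is exactly
`generate_dataset(synthetic_spec(seed = 42))` — a **synthetic stand-in**,
not the published supplementary data. Results computed on it (and quoted in
the README) are therefore statistical reproductions of the published
modeling protocol under emulated conditions, not re-computations on the
original corpus.

What the generator does *not* emulate: real phage-display propagation and
codon biases, library-specific flanking linkers, the long tail of
PSBPs lacking canonical motifs, and — importantly — negatives drawn from
panning against other targets *in the same libraries*, which are closer in
composition to positives than uniform-background peptides are. One visible
consequence: on synthetic data the AAC-only baseline performs far better
(≈ 0.87 CV accuracy) than the ≈ 0.73 reported for composition-matched real
negatives, because here raw aromatic composition alone separates the
classes. Passing end-to-end tests on synthetic data demonstrates that the
pipeline recovers planted signal of realistic strength; it does not certify
real-data performance levels for the composition-only model.

## Problem sizes used in tests and reports

The shipped corpus is 104+104 peptides; pipeline evaluations replicate the
full protocol (ranking, forward selection, grid search, fivefold CV) over
ten seeds and average. A full DPC-block run takes roughly half a minute on
one core; the AAC block a few seconds. Unit and property tests run on
datasets of 20–50 peptides per class and complete in seconds.

## Worked example

```{r, eval = FALSE}
library(psbp)

ds <- generate_dataset(synthetic_spec(seed = 42))
fit <- run_pipeline(ds, block = "dpc", seed = 1)
fit$metrics
predict_peptides(fit$model, "VHWDFRQWWQPS")
```

## Known limitations

* The exact Generalized Jaccard representation used to curate the original
  corpus is not documented; residue-count multisets are the default here,
  and reproductions of a differently-curated negative set may differ.
* The original model's $(c, \gamma)$ and its exact CV fold assignments are
  unknown; reproduction of published performance is statistical (over
  seeds), not bitwise.
* Linear peptides that genuinely begin and end with cysteine are
  indistinguishable from circular-library peptides by sequence alone;
  trimming is therefore an explicit curation step, applied by
  `build-dataset` but never silently at prediction time.
* Probability calibration at very small sample sizes (tens of peptides) is
  noisy; decision labels are more stable than the probabilities themselves.
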