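---
title: "Predicting cohesin-mediated chromatin loops from 1D chromatin features"
author: "loopForge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cohesin-mediated chromatin loops from 1D chromatin features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopForge)
```

## The modelling problem

Chromatin loops bring two distal genomic loci — the loop *anchors* — into
physical proximity. Cohesin (its RAD21 subunit) and CTCF mark the anchors of
a large fraction of these contacts, and loops called from RAD21 ChIA-PET
experiments can be predicted surprisingly well from ordinary one-dimensional
sequencing tracks (ChIP-seq of architectural proteins and transcription
factors, DNase-seq, RNA-seq, histone marks). loopForge implements that
modelling framework end to end:

1. **Loop universe.** Positive loops are replicated interaction calls: loops
   present in both ChIA-PET replicates, where two loops are the same when
   *both* anchors match within a maximum edge-to-edge gap of 2 kb (the bound
   is inclusive; the gap is measured between interval edges in 0-based
   half-open coordinates). Negative loops are built by randomly pairing
   ChIP-seq peaks on the same chromosome, discarding any candidate that
   matches a positive loop, and then matching the genomic-distance
   distribution of the positives.
2. **Features.** For a loop of length `L` (outer span, left-anchor start to
   right-anchor end), the region extended by `L` on each side — total
   length `3L` — is cut into 1500 near-equal bins, and every track is
   scored per bin. A matrix over the default 23-track schema has
   23 × 1500 = 34,500 columns. Bins 1–500 are the left flank, 501–1000 the
   loop itself, 1001–1500 the right flank; the anchors sit exactly at the
   window boundaries (bins 500/501 and 1000/1001).
3. **Classification.** Six supervised learners are trained on an 80/20
   stratified split and compared by accuracy, precision, recall and F1.
4. **Interpretation.** The tree-based learners expose per-feature
   importances, which the package re-assembles into position-resolved
   per-track profiles and an *anchor concentration* summary (the fraction of
   importance inside the 100-bin windows centred on each anchor boundary).
5. **Transfer.** A model trained on one dataset can be applied to another
   with an identical feature schema; a fingerprint check refuses silently
   misaligned matrices.

## Scoring: conventions and rationale

A read is assigned to the bin containing its midpoint
(`floor((start + end) / 2)`, 0-based). Midpoint assignment makes per-bin
counts *exactly* conserve the number of reads whose midpoint falls in the
region, which gives the test suite a brute-force oracle with exact equality
rather than a tolerance. Scores are normalized by both bin genomic length
and library size as reads per kb per million mapped reads (RPKM-style):

```
score = count / (bin_length_kb × library_size_millions)
```

The absolute scale is irrelevant to the tree-based learners (their splits
are monotone-invariant, a property the tests assert); it matters for the
RBF-kernel SVM and the neural models, which is why those learners
standardize inputs (fit on the training split, applied to test data) — the
transformation is stored inside the trained model.

Bin boundaries are `b_i = start + round(i × length / 1500)`; widths may
differ by 1 bp and tile the region exactly (asserted bp-exactly in the
tests). Loops whose `3L` region would cross a chromosome edge are clamped
with a warning, and the grid is built on the clamped region.

## Negative-set construction

Random peak pairs have a length distribution very different from real
loops, and genomic distance strongly influences contact probability, so raw
pairs would let a classifier cheat on distance alone. The package matches
distributions by density-ratio importance resampling on log10 loop length:
kernel density estimates (Gaussian kernel, bandwidth by the normal
reference rule) for positives and candidates give each candidate the weight
`positive density / candidate density`, capped at the 0.99 quantile to
bound variance and set to zero outside the positives' support. Candidates
are then drawn without replacement with inclusion probabilities
proportional to the weights using systematic PPS sampling along
length-sorted candidates — the stratification makes the selected empirical
CDF track the target closely. The selection is accepted when the
two-sample KS statistic against the positives is ≤ 0.1 (the default
tolerance); otherwise it is redrawn a bounded number of times and the best
set is returned with a warning and the achieved KS value attached.

Matching is on the outer span `L`; candidate pools are capped at the
maximum positive length by default so every positive length quantile is
actually reachable. Only candidates matching a positive on *both* anchors
are filtered out — reusing a single anchor of a real loop is allowed, as in
the peak-pairing construction.

## Classifiers and their configuration

| algorithm | backend | defaults |
|---|---|---|
| `decision_tree` | rpart | depth ≤ 10, entropy criterion (`criterion` switch allows Gini) |
| `random_forest` | ranger | 250 trees, depth ≤ 8 |
| `xgboost` | xgboost | 100 estimators, learning rate 0.1, depth 3 |
| `svm_rbf` | e1071 | RBF kernel, C = 100, standardized inputs |
| `mlp` | in-package dense net | L2 alpha 0.001, adaptive learning rate |
| `deep_ann` | in-package dense net | 120–30–10 relu with dropout 0.2 after the first two layers, sigmoid output |

Two configuration notes. First, no installed R forest implementation
exposes an entropy split criterion, so the random forest splits on Gini —
the two impurity measures are close relatives, and the single tree (whose
backend supports both) keeps the choice available as a config switch.
Second, R has no maintained multi-hidden-layer perceptron package, so the
package ships a compact dense-network trainer (relu hidden layers, sigmoid
output, binary cross-entropy with L2, inverted dropout, Adam, and a
learning-rate schedule that halves the rate when the epoch loss stops
improving) used by both `mlp` and `deep_ann`. The `mlp` hidden layout is
genuinely ambiguous in the source configuration ("40 layers with 10
neurons on the first layer"), so two named presets are shipped —
`mlpHiddenPreset("two-layer")` (hidden sizes 40, 10; the default) and
`mlpHiddenPreset("stacked")` (forty 10-unit layers). The stacked reading
does not train under plain backpropagation (vanishing gradients without
skip connections), which is why the two-layer reading is the default.

Metrics use the standard confusion-matrix definitions with
zero-denominator conventions (precision/recall/F1 are 0 when undefined).
Headline numbers use class-support-weighted averaging over the two classes
— on balanced sets this keeps precision/recall/F1 tracking accuracy, which
matches how the published comparison tables behave; the averaging mode is
recorded in every report and `positive_class`/`macro` are available.

## Feature subsets

`selectSubset()` carves the column families used in the feature-ablation
analyses: `Architectural` (CTCF + RAD21, all bins), `TF` (the nine
transcription factors), `Transcription` (everything except the
architectural tracks), and the `-anchors` variants restricted to 100 bins
centred on each anchor boundary (bins 451–550 and 951–1050 at defaults;
2 × 100 = 200 bins per track). The anchor windows straddle the
flank/interior boundaries symmetrically — 50 bins on each side — because
the anchors themselves begin and end exactly at those boundaries.

## What the synthetic generator emulates

The generator produces, per simulated "cell line": true loops with
log-uniform lengths in 10–500 kb (the one-to-hundreds-of-kb scale of
cohesin loops) and 2 kb anchors; two replicate interaction calls derived
from the truth by independent 10% dropout and rounded Gaussian anchor
jitter (sd 200 bp, clamped at chromosome bounds, ordering-preserving); a
peak set containing every distinct true anchor plus uniformly placed decoy
peaks kept > 5 kb from any anchor (so decoys can never match a true anchor
under the 2 kb rule — negative-set purity is controllable in tests); and
per-assay read tracks: homogeneous Poisson background at 2 × 10⁻³ reads/bp
— the per-bp order of magnitude of a typical 10–30 M-read ChIP-seq library
on a mammalian genome — plus surplus reads inside anchors
(architectural/TF/accessibility-like tracks) or inside the loop span
(gene-body/repressive-mark-like tracks) raising the local rate to
`enrichmentFactor ×` background (default 10). Reads have a fixed 50 bp
length, which keeps the midpoint-counting oracle exact. Two cell lines are
emulated by marking TF profiles as cell-specific on disjoint subsets:
architectural signal is shared (transferable), TF signal is line-private
(non-transferable).

What it does *not* emulate: fragment-level ChIA-PET structure
(self-ligation, PET redundancy), sequence content, copy-number or
mappability artifacts, correlated inter-track biology, and genome-scale
loop densities. Passing tests therefore demonstrate that the machinery —
set construction, binning, learning, importance, transfer — behaves
correctly under known signal, not that real-data accuracies are
reproduced; the published cell-line accuracies depend on the external
ENCODE datasets and are explicitly out of scope.

Simulation scale in the shipped tests and acceptance script: 500–1000
loops on 80–100 Mb two-chromosome genomes with 5–6 tracks, sizes at which
every planted effect is comfortably detectable while a full run stays in
the minutes range.

## Numerical and design choices

- **Coordinates.** All files are 0-based half-open (BED/BEDPE);
  in-memory anchors are `GRanges`. Loop length is the outer span
  `right.end − left.start`; the inner anchor distance is also exposed.
- **Replicate intersection** keeps the first replicate's coordinates and
  order (the choice is arbitrary and documented; the second replicate only
  votes).
- **Degenerate inputs.** A zero-rate track has no reads; its recorded
  library size is floored at 1 so it remains a valid normalizer. A model
  trained on a single class, unknown hyperparameter keys, fingerprint
  mismatches, unknown categories and odd anchor windows all fail fast with
  named errors.
- **Ties in importance rankings** are broken by schema track order, then
  ascending bin — rankings are fully deterministic.
- **Seeds.** Every stochastic stage takes a seed; the pipeline derives
  per-stage seeds from one global seed via a fixed integer recurrence, so
  stages are individually reproducible and a rerun is byte-identical
  (manifest checksums and matrix files are compared in the tests).

## Known limitations

- The distance matcher cannot fabricate candidates where none exist; with
  too few short-span peak pairs the KS tolerance may be unattainable, in
  which case the best-achieved set is returned with a warning and the KS
  value attached for inspection.
- `rpart`'s variable importance includes surrogate-split credit, so the
  single tree's profile is not exactly sklearn-style impurity decrease;
  forest (impurity) and boosting (gain) importances are conventional.
- The in-package dense-net trainer is deliberately small: full-batch
  matrices in base R, no GPU, no early-stopping on a validation split. It
  is adequate for the matrix sizes used here, and `deep_ann` remains
  excluded from importance analyses by construction.
- Inter-chromosomal loops and more than two replicates are out of scope.
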