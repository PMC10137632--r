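---
title: "Ensembling bounding-box detectors: fusion, strategies, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensembling bounding-box detectors: fusion, strategies, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boxfusion)
```

## The problem

Detecting anatomical structures (brain tissue, eyes, optic nerves,
ventricles) and pathology (tumor) on MRI slices is usually done with deep
object detectors trained under k-fold cross-validation, which leaves the
analyst with a grid of prediction sets: several architectures times several
folds, each emitting axis-aligned boxes with confidence scores. Individual
detectors disagree most on small, low-contrast structures — exactly the
clinically interesting ones. `boxfusion` implements the post-hoc remedy:
merge the grid's predictions into a consensus set by weighted boxes fusion,
under one of four selection strategies, and quantify the effect with the
standard detection metrics.

The package deliberately starts *after* model training: its inputs are
boxes, labels and scores (COCO-dialect JSON on disk, plain data frames in
memory), never images or network weights.

## Weighted boxes fusion

All strategies share one computational core. Detections are pooled across
sources class-wise and image-wise, visited in descending confidence, and
clustered: a box joins the existing fused box of its class with which it
overlaps most, provided that IoU exceeds the clustering threshold (default
0.6); otherwise it opens a new cluster. A cluster with members
$(X_{1,2}^i, Y_{1,2}^i)$ and confidences $C_i$ is summarized by

$$C = \frac{1}{T}\sum_{i=1}^{T} C_i, \qquad
  X_{1,2} = \frac{\sum_i C_i X_{1,2}^i}{\sum_i C_i}, \qquad
  Y_{1,2} = \frac{\sum_i C_i Y_{1,2}^i}{\sum_i C_i},$$

so the consensus corners are confidence-weighted means (confident members
pull the fused box toward themselves) and the consensus confidence is the
plain mean over the $T$ members. Unlike non-maximum suppression, which
discards all but one box, fusion uses every source's localization evidence.

Design choices a reader should know about, since the formulas alone do not
pin down an algorithm:

* **Membership test.** A candidate is compared against the *current fused
  box* of each cluster, not against individual members. This keeps the
  greedy pass order-stable under the descending-score sort and is how the
  weighted-fusion method is conventionally implemented.
* **Incremental updates.** Fused coordinates are recomputed from the full
  member list after every addition; by associativity of weighted means this
  equals a single batch computation at the end, and a test asserts exactly
  that equivalence against an independent replay.
* **Skip threshold.** Boxes whose (weighted) score falls below the skip-box
  threshold (default 0.16) are removed *before* clustering; they neither
  seed nor join clusters.
* **Weights.** Per-source weights are normalized to mean 1 before use, so
  scaling all weights by a positive constant is exactly a no-op — without
  normalization the fused confidences would silently scale. Defaults are
  equal weights.
* **Ties.** Equal scores sort by source index, then input order, making
  output deterministic for any input.

Standalone non-maximum suppression is provided with the conventional
defaults used upstream of fusion (0.6 IoU, 0.1 score threshold): class-wise
and image-wise, the highest-scored box suppresses any overlapping same-class
box above the IoU cap.

## The four ensemble strategies

Given a `detection_bundle` (models x folds) the package offers:

1. **All folds of one model** — fuse the k cross-validation variants of a
   single architecture, no selection.
2. **Above-mean folds** — fuse only the folds whose selection-split mAP lies
   strictly above the mean over that model's folds. If all folds tie, all
   are used (an empty fusion input would be meaningless).
3. **All models per fold** — hold the fold fixed and fuse across
   architectures; applied to every fold this yields one consensus per fold.
4. **Best model per fold** — per fold, pick the architecture with the top
   selection mAP (ties to the first model in the bundle's declared order)
   and fuse the winners into a single result.

Selection scores live in a `selection_table` carrying a `split_tag`. The
scores should come from a validation split, never from the split being
reported: `compute_selection_table()` restricts each prediction set to the
selection split's images before scoring, and the tag records the provenance.
Strategy results carry the fused boxes plus a provenance table naming every
(model, fold) that entered the fusion.

## Evaluation metrics

Matching is Pascal-VOC-style greedy: predictions in descending score order;
a prediction is a true positive iff it attains IoU at or above the threshold
with a not-yet-matched same-class ground-truth box on its image (the
highest-IoU candidate, earliest annotation index on exact ties). IoU uses
continuous corner coordinates with area $(x_2-x_1)(y_2-y_1)$ and no +1 pixel
correction, which keeps the geometry consistent with the fusion formulas.

**AP and mAP.** Per class, precision $P = TP/(TP+FP)$ and recall
$R = TP/(TP+FN)$ are traced over all score cutoffs and AP is the all-points
summary $\sum_k (R_k - R_{k+1}) P_k$ with the boundary convention $R_n = 0$,
$P_n = 1$, evaluated on the monotone (interpolated) precision envelope. The
summation form alone is ambiguous about interpolation; the envelope reading
is the community standard and — importantly — is checkable against a
brute-force oracle that re-matches every cutoff and integrates the envelope
explicitly, which the test suite does on hundreds of random instances.
mAP averages AP with equal weight over the classes present in the ground
truth. A class with ground truth but no predictions scores 0; a class
predicted but absent from the ground truth cannot have an AP, is excluded
from the mean, and is reported in `ignored_classes` (its predictions still
count as false positives in FROC pooling).

**FROC and FAUC.** Sweeping the confidence threshold from 0 to 1 (step 0.02
by default) yields, per threshold, the pooled true positive rate and the
false positives per image $FPPI = FP / \text{n images}$ — images with zero
annotations count in the denominator, which is why `ground_truth` carries an
explicit image set. The curve is pooled over classes by default (a class
filter gives per-class curves). Because greedy matching is prefix-stable in
score order, the whole sweep is computed from one matching pass; a test
asserts equality with literal re-matching at every threshold. FAUC is the
trapezoidal area under TPR-vs-FPPI normalized by an FPPI upper bound. No
universal bound exists for FROC analysis, so the package defaults to the
largest FPPI observed on the curve, records it in the object, and lets the
caller impose a shared bound — FAUCs are only comparable under a shared
normalization, so cross-method comparisons here always use the maximum over
the curves being compared. A curve that never produces a false positive is
assigned its best TPR (a perfect detector scores exactly 1); when the lowest
observed FPPI is positive the curve is anchored at the origin rather than
extrapolated flat, a conservative choice that never credits unobserved
operating points.

## The synthetic simulator

Real detector grids need GPUs and restricted imaging data, so the package
ships a seeded simulator that reproduces the *statistical shape* of the
problem instead. `brain_class_spec()` defines six classes on a 512 x 512
frame whose per-slice presence probabilities and counts approximate
expert-annotated axial brain MRI collections: the brain region on every
slice; eyes and lateral ventricles as paired structures (two-plus objects
when present, anterior and central placement respectively); a rare, small
optic nerve and third ventricle; a tumor on about a quarter of slices.

`detector_profile()` describes a detector by corner jitter (Gaussian,
proportional to box side), a miss rate, a Poisson false-positive rate per
image, and a confidence model: a true detection's score is its realized IoU
with the source box plus Gaussian noise, clipped to $[0,1]$, while spurious
boxes draw low scores (uniform on $[0, 0.5]$ by default). Making confidence
informative about localization is a deliberate choice — it is the regime in
which confidence-weighted fusion should help, and the regime trained
detectors approximate. All noise parameters are artifact choices, not
estimates from any dataset: real detectors have no published error model.

Seeding is hierarchical: one master seed expands into independent
per-(model, fold) streams (`detector_grid()`), so a whole bundle is bitwise
reproducible while its detectors remain statistically independent. All
generators use scoped RNG and leave the caller's random state untouched.

What the simulator does *not* emulate, and what passing tests therefore do
not show: correlated errors between detectors (real architectures trained on
the same data fail together far more than independent simulators do, so
real-world ensemble gains will be smaller than simulated ones), slice-to-
slice anatomical continuity, class-dependent detector biases, and any image
content whatsoever. The ensemble-improvement property verified in the test
suite — fusing five moderately noisy detectors beats their mean mAP in at
least 18 of 20 seeded runs — is a qualitative statement about the method
under independence, not a reproduction of any dataset-specific number.

## Numerical conventions and degenerate inputs

* Boxes must have strictly positive area; zero-area boxes are rejected, and
  the simulator enforces a 1-pixel minimum side after frame clipping.
* Scores outside $[0,1]$ are rejected at construction and at JSON ingestion
  (naming the offending record).
* AP of a class with no ground truth raises a typed condition
  (`boxfusion_undefined_ap`) rather than returning a silent 0.
* Empty prediction sets are legal everywhere and propagate as zero recall /
  empty output rather than errors; an empty confidence sweep or an image
  set of size zero is an error.
* All tie-breaks (score sorting, cluster choice, argmax selection) are
  documented above and deterministic, so repeated runs are bitwise equal —
  the command-line pipeline test asserts this end to end via file
  checksums.

## Problem sizes

The bundled checks run on deliberately small instances chosen to exercise
every code path with comfortable margins: random metric instances use at
most 8 boxes (where brute-force oracles are exact and cheap), property
sweeps use 100-1000 replicates, and the simulation benchmark in
`scripts/acceptance.R` uses 40 images per split with a 4-model x 5-fold
grid of graded quality plus 20-seed replication for the improvement
property. These sizes are statistical choices: large enough for stable
means, small enough that the whole suite re-runs in a couple of minutes on
a laptop core.

## Limitations

Axis-aligned 2D boxes only — no rotated boxes, no 3D volumes, no
segmentation-mask metrics (Dice and friends are a different toolchain). No
learned fusion weights or stacking; fusion is closed-form. And the
simulator's independence assumption, noted above, makes simulated ensemble
gains an upper bound on what correlated real detectors deliver.
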