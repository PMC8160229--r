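---
title: "Two-phase gradient-based classification of brain MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase gradient-based classification of brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the method

Gliomas produce space-occupying and infiltrative changes that alter local
intensity gradients in structural MRI long before a human reader can
delineate them reliably.  `fuzzyhog` implements a whole-brain, segmentation-
free classifier for two binary tasks on spatially aligned T2-FLAIR-like
volumes: *detection* (lesioned vs. healthy brain) and *grading* (high- vs.
low-grade lesion texture).  The pipeline is deliberately shallow and
interpretable:

1. **Intensity standardization.** Each volume is z-scored over all voxels
   (population SD), clipped at z = ±4 and rescaled linearly to [0, 1].
2. **Local gradient descriptors.** Every slice along the acquisition axis is
   partitioned into a dense origin-anchored grid of non-overlapping square
   cells of side *c* (default 10 voxels).  For each cell an
   orientation histogram over *N* = 8 signed channels (0–360°, channel *k*
   centered at *k*·45°) is accumulated: every pixel votes with its gradient
   magnitude, either entirely into the nearest channel center ("hard") or
   split between the two nearest centers in proportion to angular distance
   ("bilinear", the default).  Gradients use centered differences
   (f(t+1) − f(t−1))/2 with one-sided differences at borders, the standard
   derivative estimate on a unit grid.
3. **Phase 1 — per-position fuzzy clustering.** Because the cohort is
   aligned, the descriptor of cell position *p* is comparable across
   subjects.  For each of the *P* = m·R·Q positions, fuzzy C-means with
   *K* = 2 clusters (fuzzifier 2) is fitted across the training subjects'
   descriptors at that position.  The membership probability of the
   designated first cluster becomes one scalar feature, so the subject
   representation shrinks from *P·N* numbers to *P* — an *N*-fold reduction
   that directly attacks small-*n*/large-*P* overfitting.
4. **Phase 2 — linear SVM.** A support vector machine (balanced class
   weights, C = 1) is trained on the membership vectors.  The linear
   kernel's primal weight vector assigns one weight per brain position;
   back-projecting |w| onto each cell's voxel footprint yields a
   discriminant map that localizes the class-separating regions.

A *baseline* mode concatenates the raw cell histograms (length *P·N*)
instead, which is the conventional dense-HOG representation; the
cross-validation harness can run both for a controlled comparison.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cell_size` | 10 voxels | side of the square R-HOG cell; the sweep 10–20 is the conventional range for these matrix sizes |
| `n_bins` | 8 | signed orientation channels over 0–360° |
| `normalize` | `"l2"` | per-cell contrast normalization (`"none"`, `"l2hys"` available) |
| `vote_interp` | `"bilinear"` | magnitude voting; `"hard"` is the literal nearest-channel rule |
| `K` | 2 | clusters per position (lesion-associated vs. normal tissue) |
| `fuzzifier` | 2.0 | softness of the memberships; the universal FCM default |
| `tol`, `max_iter`, `n_init` | 1e-5, 300, 3 | FCM stopping rule and seeded restarts |
| `C`, `class_weight` | 1.0, balanced | SVM regularization; balancing matches imbalanced cohorts |

### Choices that were genuinely open

* **Per-position vs. pooled clustering.** Clustering descriptors *per
  position* across subjects (the default) exploits the alignment and lets
  every brain location develop its own lesion/normal dichotomy; a
  `scope = "global"` mode pools all positions into one clustering instead.
  Both are implemented because the method description admits either
  reading; per-position is the default since position-wise comparability is
  the stated motivation for registering to a common template.
* **Cluster identity.** Fuzzy clustering does not know which cluster is
  "lesion-related".  Clusters are ordered per position by descending
  centroid norm — any deterministic, train/predict-stable convention works,
  because the phase-2 SVM learns a sign per position.
* **Test-time assignment.** Training features are continuous memberships,
  so new subjects are scored by default with the same soft membership
  formula against the frozen centroids (`"soft"`); the literal
  nearest-centroid rule (`"hard"`, 0/1 with ties to the first cluster) is
  available but distribution-shifts the SVM inputs.
* **Degenerate positions.** A position whose descriptors are identical in
  every training subject (typically background cells), or whose fitted
  centroids coincide, carries no information; it is flagged and emits the
  constant 0.5 so vector length and position indexing never vary.
* **Contrast normalization per task.** Per-cell L2 normalization makes
  descriptors robust to intensity scaling, which suits *detection* (the
  signal is the orientation structure of lesion edges).  For *grading* the
  discriminating signal is the *magnitude* of the internal texture
  gradients; L2 normalization maps strong isotropic texture and weak
  isotropic noise to nearly identical unit-norm histograms and erases the
  task.  The grading analyses therefore run with `normalize = "none"`.
  This is the package's own resolution of a point the method description
  leaves open ("may be contrast-normalized").

## The synthetic phantom

No clinical data ship with the package; a generator produces aligned
cohorts that emulate the two tasks.  Each phantom is a thick-slab axial
acquisition through the middle of a brain: in-plane, the brain is an
ellipse covering 90% of the field of view; through-plane, the ellipsoid's
semi-axis equals the slab thickness, so all slices sample the brain near
its equator.  (This mirrors thick-slice clinical protocols — a dozen 6 mm
slices never cover the polar caps — and is what lets a realistically sized
spherical lesion satisfy the "lesion inside the brain" constraint despite
the thin slab.)  Tissue intensity is 100 (arbitrary units) on a zero
background with additive Gaussian noise (SD 5).

Lesions are bright spheres (+40 above tissue, default radius 8 voxels ≈ 13%
of the brain width).  `smooth_bright` is a constant plateau: only its rim
produces gradients, emulating a homogeneous low-grade lesion.
`rough_bright` multiplies the plateau by 1 + a·U(−1, 1) voxel-wise
(amplitude a = 0.3 by default): strong heterogeneous internal gradients,
the high-grade analogue.  Across subjects the lesion center jitters by up
to ±10% of each dimension and the radius by ±20%, so boundary cell
positions see both lesioned and normal descriptors — the regime the fuzzy
(soft) assignment is designed for.  All randomness derives from one cohort
seed via an integer hash, so cohorts are bit-reproducible.

What the phantom does *not* model: anatomy (no tissue classes, skull or
ventricles), bias fields, registration error, multi-modality contrast, or
partial-volume effects.  Passing the package's tests therefore demonstrates
that the machinery extracts and localizes gradient-structure differences
under aligned, standardized conditions — not clinical performance.

## Numerical conventions

* Population (divide-by-N) SD in the z-scoring, for bit-reproducibility.
* Gradient magnitude of a pure unit ramp is exactly 1 everywhere (centered
  differences are halved; borders are one-sided).
* Angular ties in hard voting go to the lower channel index (at the 360/0°
  wrap the lower index is channel 0); zero-gradient pixels have direction 0
  by convention and contribute no vote mass.
* FCM memberships are initialized from a seeded uniform matrix normalized
  row-wise; iteration stops when no membership moves by `tol` or more.
  Among `n_init` restarts the lowest objective J = Σ u^m d² wins.  A point
  coinciding with a centroid gets full membership there (split equally on
  multiple coincidences).  All per-position runs execute in one batched
  engine that freezes each position at its own convergence point and is
  exactly equivalent to independent single-position fits.
* Decision scores are oriented so positive favors class 1; a score of
  exactly 0 predicts class 1.
* AUC is computed per CV run from the pooled out-of-fold decision scores
  (stabler than per-fold ROC at these cohort sizes; per-fold values can be
  recovered from the stored records).  The aggregate confusion matrix is
  the element-wise median across runs of the fold-summed counts, rounded;
  since positives and negatives are constant per run, the aggregate still
  sums to the subject count.
* Every nested seed (fold shuffles, FCM restarts, SVM) is derived from one
  master seed with a deterministic integer hash kept below 2^31.

## Problem sizes used in the shipped analyses

The package's own test suite and the `scripts/acceptance.R` summary run at
desk scale, chosen to exercise the small-*n*, large-*P* regime the method
targets: detection with 20 + 20 subjects on 60×60×12 grids (cell size 10,
P = 432, three runs of stratified 10-fold CV), grading with 15 + 15, a
high-dimensional comparison with 15 + 15 subjects and P = 1024 cells
(64×64×16, cell size 8) over five cohort seeds, and a matched lesion-free
null cohort that must stay at chance AUC.

## Limitations

* Binary tasks only; one modality/channel per volume.
* The package consumes *already aligned* NIfTI volumes; registration, bias
  correction and skull handling belong to upstream tools.
* K > 2 is supported mechanically but the cluster-ordering convention and
  the one-number-per-position feature are designed around K = 2.
* No nested hyperparameter search and no significance testing between
  methods; the harness reports descriptive means and SDs across runs.
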