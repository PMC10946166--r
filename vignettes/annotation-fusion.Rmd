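---
title: "Fusing multi-observer bounding-box annotations and evaluating detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing multi-observer bounding-box annotations and evaluating detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boxfuse)
library(dplyr)
```

## The problem

When several clinicians independently draw bounding boxes around lesions on
the same radiograph, no single annotation set can serve as ground truth:
raters disagree on lesion extent, miss lesions, occasionally mark artifacts,
and grade severity differently. Training an object detector needs one
consistent set of boxes per image. `boxfuse` builds that consensus with a
probabilistic fusion rule, and then evaluates detectors — or the raters
themselves — against consensus ground truth with the standard
object-detection metrics.

The package grew out of dental radiography, where proximal caries are graded
by radiolucency depth (grades 1–2 in the enamel, 3–5 reaching the dentine,
plus secondary lesions near restorations and an `unknown` grade), but
nothing in the machinery is specific to teeth: any axis-aligned-box
annotation task with a severity-ordered label set fits.

## The fusion model

Fusion runs image by image, in four steps.

**1. Grouping.** All boxes drawn on one image (by any rater) are grouped by
overlap: two boxes join the same group when their intersection-over-union
(IoU) reaches `group_iou`, and groups are the connected components of this
relation (single linkage). Single linkage is the permissive choice: it never
splits a clique of mutually overlapping boxes, and a chain of
pairwise-overlapping boxes is treated as one object. The default
`group_iou = 0.3` matches the IoU threshold used for evaluation, so "same
object" means the same thing during fusion and scoring. Boxes from the same
rater may legitimately share a group (a rater can draw two boxes over one
lesion); they are all kept as components.

**2. Per-axis Gaussian representation.** Each box in a group is summarised,
separately along x and y, by a Gaussian whose mean is the box centre and
whose standard deviation is the half-extent divided by the coverage factor
`k`:

$$\mu_x = \tfrac{x_{min}+x_{max}}{2}, \qquad
  \sigma_x = \tfrac{x_{max}-x_{min}}{2k}.$$

With the default `k = 2` the box edges sit at two standard deviations. The
group's boxes then define, per axis, an equal-weight Gaussian mixture
density (every rater counts the same — there is no reliability weighting):

$$f(x) = \frac{1}{N}\sum_{i=1}^{N} \varphi(x;\, \mu_i, \sigma_i).$$

**3. Level-set extraction.** The consensus extent along each axis is the
connected component, containing the global maximizer, of the *relative*
level set

$$\{\,x : f(x) \ge p \cdot \max_x f(x)\,\}.$$

Two properties motivated reading the threshold `p` as a fraction of the
mixture's own maximum rather than an absolute density:

* *scale invariance* — pixel units cancel, so the same `p` behaves
  identically on thumbnails and full-resolution radiographs;
* *identity* — for a single box the level set is exactly
  $\mu \pm \sigma\sqrt{-2\ln p}$, so with the paired defaults
  `p = exp(-k²/2)` (≈ 0.1353 at `k = 2`) a singleton group reproduces its
  box to numerical precision, and N duplicates of one box behave like one.
  A fusion rule that moved uncontested boxes would be hard to defend.

When raters disagree, mass concentrates where boxes agree and the level set
tightens around the shared core; an outlier box flattens its own
contribution without dragging the interval far. If the mixture is multimodal
and the level set splits into several intervals, the component under the
highest mode is used — taking the hull of all components could produce a
consensus box larger than every member box, which we rejected.

**4. Label vote.** The consensus label is the modal label among the group's
boxes; ties go to the most severe label. Severity is a configurable total
order, by default `unknown < enamel < dentine < secondary`. Only
enamel-below-dentine is clinically fixed (a dentine lesion is deeper, and
for a tie the cautious call is the more severe one); where secondary lesions
rank was a genuinely open choice — we place them top because they indicate
pathology near existing restorations and under-calling them is the costlier
error, and the order is a single argument to change. Voting operates on the
merged groups (enamel / dentine / secondary) because that is the vocabulary
the fused ground truth is consumed in; `vote_on = "grade"` votes on raw
grades first instead. Annotations with `unknown` grade are excluded from
fusion by default (mirroring their exclusion from model training);
`keep_unknown = TRUE` retains them.

## Numerical details

The level-set crossings are found by scanning a grid of step
`grid_resolution` (default 0.1 px) over
$[\min_i \mu_i - 6\max_i \sigma_i,\; \max_i \mu_i + 6\max_i \sigma_i]$,
refining the maximizer with `stats::optimize()`, and refining the two
crossings by bisection (`stats::uniroot()`) at tolerance
`min(grid_resolution/100, 1e-9)`. The grid only brackets; accuracy comes
from the bisection, which is why the identity property holds to 1e-6 and
why scaling the scene (with the grid scaled along) is equivariant. The
6-sigma margin guarantees the density falls below any practical relative
level before the scan limits. Degenerate inputs are rejected early: boxes
must have strictly positive width and height, `p` must lie strictly inside
(0, 1).

## The evaluation protocol

`evaluate_detections()` implements the PASCAL VOC protocol at a configurable
IoU threshold (default 0.3 — in caries screening missing a lesion is worse
than a loose box, so a permissive threshold is the accepted operating
point):

* **Matching** is greedy per image and class, in descending confidence;
  each detection claims the unmatched ground-truth box with the highest
  IoU at or above the threshold. Equal confidences keep stable input
  order — relevant for annotators-as-detectors, whose boxes all carry
  confidence 1.0 (`annotator_as_detector()`); this degeneracy is exactly
  why order-sensitive NMS-style fusion was avoided for building ground
  truth in the first place.
* **AP** uses all-point interpolation (the precision envelope integrated
  over recall), not the 11-point variant: it uses every operating point of
  the curve and is the better-behaved estimate.
* **F1 and FNR** are computed at the all-detections operating point (no
  confidence cut), the only operating point a scoreless annotator has;
  `F1 = 2TP/(2TP+FP+FN)`, `FNR = FN/(FN+TP)`. Matches are pooled over the
  test set per class before computing FNR (pooling, not per-image
  averaging: per-image FNR is undefined on images without lesions of a
  class, and pooling weighs every lesion equally).
* **Class means** (mAP, mF1, mFNR) are unweighted over
  enamel/dentine/secondary; a class with no ground truth anywhere is
  excluded from the means, with a message. Degenerate conventions: no
  detections and no ground truth gives F1 = 0 with a warning; FNR is `NA`
  without ground truth.

## Bootstrap confidence intervals

`evaluate_with_ci()` attaches bias-corrected and accelerated (BCa)
bootstrap intervals (default 1000 resamples, 95%). The resampling unit is
the **image**: a detection and the ground truth it was matched against must
travel together, and the image is the only unit that preserves that
structure. Matching is computed once; each resample merely re-aggregates
per-image match results, which keeps 1000 iterations at seconds. Details:
`z0` is the normal quantile of the fraction of bootstrap values below the
point estimate, counting ties half and continuity-correcting by `0.5/B` at
the extremes; the acceleration comes from jackknife skewness, with `a = 0`
when the jackknife sum of squares vanishes; resamples on which a metric is
undefined (a class absent from every resampled image) are redrawn and
counted, warning above 10%; metric intervals are clipped to [0, 1].
Significance between two systems is declared by interval disjointness
(`compare_by_overlap()`) — conservative, but assumption-free and the
convention this evaluation protocol uses.

## What the synthetic generator emulates — and what it does not

`generate_ground_truth()` + `simulate_annotators()` /`simulate_detector()`
stand in for a multi-rater annotation campaign: images of fixed size
(default 1000 × 800 px) holding 1–6 boxes of 20–80 px, class frequencies
with secondary lesions most frequent (0.45/0.30/0.25 for
secondary/enamel/dentine), and raters who jitter each box **edge**
independently (Gaussian, default sigma 2 px), miss boxes (default 10%),
add Poisson spurious boxes (default 0.2 per image, placed to overlap no
true box above IoU 0.1), and confuse labels via a row-stochastic matrix.
Detectors additionally draw confidences from Beta(8, 2) for
truth-derived boxes and Beta(2, 5) for spurious ones.

Edge-wise jitter is deliberate: the fusion model assumes a Gaussian per
axis around the box *centre*, and edge noise does not match that assumption
exactly, so passing tests demonstrate robustness to a misspecified noise
model rather than self-confirmation. What the generator does **not**
emulate: correlated errors between raters (real clinicians share training
and bias), image-difficulty effects (blur, overlapping teeth), rater drift
over a campaign, and of course pixels — only geometry and labels are
generated. Results on synthetic scenes therefore show the machinery is
correct and well-behaved, not that any particular clinical performance
number transfers.

The test and acceptance workloads use deliberately modest problem sizes —
120-image scenes, 200-replicate recovery studies, 1000 × 1000 bootstrap
coverage simulations — chosen so the full suite runs on a laptop core in
a couple of minutes while keeping Monte-Carlo error well inside the
asserted margins.

## Splits

`kfold_split()` partitions images into K folds (default 5) by random
sampling without replacement, sizes differing by at most one;
`three_way_splits()` enumerates the rotation in which each fold serves once
as test set, the cyclically next as validation, and the rest as training.
Image-level splitting can leak when several images come from one patient;
passing `groups =` switches to grouped assignment in which a group is never
split across folds (sizes then balance greedily and may differ by more than
one). Fold indices are 1..K, following R convention.

## A worked example

```{r example}
cfg <- scene_config(n_images = 12)
gt <- generate_ground_truth(cfg, seed = 1)
panel <- replicate(6, rater_profile(), simplify = FALSE)
ann <- simulate_annotators(gt, panel, seed = 2)
consensus <- fuse_annotations(ann)
consensus

det <- simulate_detector(gt, detector_profile(), seed = 3)
ev <- evaluate_detections(det, consensus)
tidy(ev)
glance(ev)
```

```{r plots, fig.width = 6, fig.height = 4}
plot_consensus(ann, consensus)
autoplot(ev)
```

## Known limitations

* The fusion rule has no notion of rater reliability; a consistently poor
  rater counts as much as an expert. Equal weighting is a modelling choice,
  not a limitation of the code structure, but STAPLE-style weighting is
  out of scope.
* Grouping is single-linkage: two distinct adjacent lesions bridged by one
  sloppy box merge into one group. A stricter linkage or a per-rater
  assignment rule would need information the annotations do not carry.
* AP for uniform-confidence detectors depends on the documented stable-order
  tie policy; F1 and FNR do not, which is why the annotator comparison
  leans on them.
* CI-overlap significance is conservative relative to a paired test on the
  bootstrap replicates; it was chosen for comparability, not power.
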