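---
title: "Angle-closure biometry from labeled UBM images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angle-closure biometry from labeled UBM images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(UBMbiometry)
```

# The measurement problem

A single-angle ultrasound-biomicroscopy (UBM) image shows one side of the
anterior chamber angle: the corneoscleral wall, the iris, and — uniquely
among anterior-segment modalities — the ciliary body behind the iris.
Angle closure can arise from pupillary block (PB, the iris bows forward
under posterior-chamber pressure), from a thick peripheral iris (TPI), or
from an anteriorly located ciliary body (ALCB) pushing the iris root
forward; combinations ("multiple mechanisms", MM) are common. The
package takes a *tissue-label raster* (background / iris / sclera /
ciliary body) as input — any segmentation method may stand in front of
it — and produces per-mechanism biometry, binary mechanism calls, and the
four-way integrated assessment.

# Physical coordinates

Both acquisition geometries image a fixed physical field: 9.75 mm x
6.00 mm (half-frame) or 15.50 mm x 9.50 mm (panorama). Pixel pitches are
the field divided by the actual raster dimensions — for the canonical
1024 x 655 raster, 9.52 x 9.16 µm/px and 15.14 x 14.50 µm/px. The two
axes are deliberately never collapsed into one scalar pitch: every
physical distance is computed per-axis (`physicalDistance()`). Coordinates
are 0-based `(row, col)` with subpixel values allowed everywhere; the
convention matches the output of the marching-squares iso-contours used
for all boundaries (`regionBoundary()`, built on
`grDevices::contourLines()` at the 0.5 level of a tissue indicator).

Masks are validated, not repaired: each tissue must form a single
connected component once speckle under 50 px is disregarded, and the iris
must touch the ciliary body (its anatomical insertion). Orientation is
normalized so the angle recess — found as the iris region closest to the
sclera — lies on the left; the `flipped` flag preserves provenance and the
operation is an involution.

# Spur-anchored biometry

The scleral spur is the fixed landmark of angle biometry. There is no
standard recipe for locating it on a label mask, so the package uses an
anatomically-motivated deterministic heuristic: candidate points are
sclera-boundary points within 2 px of the ciliary body (the sclerociliary
interface, sampled from a distance transform by bilinear interpolation so
that mirrored rasters give mirrored candidates), and the spur is the
candidate nearest the iris, ties broken by row then column. The method tag
on `SpurPoint` records the heuristic so alternatives can be swapped in; a
quality score decays linearly with the candidate-to-iris distance over
500 µm.

**Iris thickness on a circle.** A circle of radius *r* µm around a centre
is intersected with the iris contour (crossings by linear interpolation of
the radial residual along contour segments, after subdividing segments to
sub-pixel length so that no double crossing is missed). Consecutive
crossings split the circle into arcs; arcs whose midpoint lies inside the
iris are thickness candidates, and the chord between the endpoints of the
selected arc is the reported thickness. When several arcs qualify, the one
nearest a reference point is chosen: a "nearest the spur" rule would be
degenerate for circles centred *on* the spur, so the reference is the iris
root for spur-centred circles and the spur for root-centred ones — both
select the peripheral measurement site. Near the insertion these chords
are oblique to the band (the spur sits at the level of the posterior
surface, not the band midline), which is why all recovery checks compare
against ground truth computed with the *same* chord construction.

**Iris curvature.** The posterior iris surface is taken as the per-column
lower envelope of the iris component — equivalent to the posterior side of
the contour in a single-angle image but immune to end-cap corners tilting
the chord. The curvature is the extremal-magnitude signed perpendicular
distance from that surface to its root-to-pupil chord, positive toward the
cornea. The signed *extremum* (not the signed maximum) is used so that
posterior bowing is reported as a negative sagitta rather than clipped
to zero.

**Ciliary contact.** The anterior ciliary surface is the maximal connected
boundary arc whose points have the iris within 500 µm as their nearest
non-ciliary tissue (or face the anterior chamber directly), with the
direction test "the segment to the nearest iris point must not re-enter
the ciliary body" screening out the far-side boundary. Contact is the arc
within 2 px of the iris — sub-resolution apposition cannot be resolved, so
2 px (about 19 µm at half-frame pitch) is the operational definition of
touching. Isolated single-vertex classification flickers along the arc are
bridged (gap tolerance 8 vertices, 4 for contact) before lengths are
measured on the physically scaled polyline.

# Classifiers and integration

Feature rows (three thicknesses, curvature, root insertion, contact
length, anterior length, contact ratio) feed a bank of five binary
classifiers per mechanism: random forest, classical gradient boosting,
regularized extreme gradient boosting, an RBF support-vector machine, and
logistic regression. Hyperparameters are the library defaults, pinned in
`inst/config/hyperparameters.yaml`; the two boosting entries differ in the
classical (depth 3, learning rate 0.1, no penalty) versus regularized
(depth 6, rate 0.3, L2 penalty 1) configuration. The pipeline is median
imputation of undefined measurements, then per-feature standardization —
both fitted on training rows only — then the classifier. SVM probabilities
come from a Platt calibration (logistic fit of the labels on the decision
values) fitted deterministically on the training set, because the
library's built-in probability estimate uses internally randomized
cross-validation. The decision threshold is 0.5 with the `>=` convention
and is recorded on the model for adjustability.

Datasets are split by *patient*, never by image, at a 3:1 ratio (met up to
one patient's worth of images); model selection ranks candidates by MCC,
then F1, then accuracy, then sensitivity, then a fixed algorithm order —
the listed criteria made total and deterministic. The integrated class is
a fixed truth table over the three booleans: PB alone is pure PB, TPI or
ALCB without PB is pure non-PB, PB with company is MM, nothing is others.

Evaluation statistics are implemented from their definitions (confusion
counts, accuracy/sensitivity/specificity/PPV/NPV/F1/MCC, rank-based AUC
with midrank tie handling, Cohen's kappa, Pearson chi-square on 2x2
correct/incorrect tables) and cross-checked in the tests against
brute-force oracles and independent implementations. Confidence intervals
use the Wilson score method, which behaves well at the near-1 accuracies
typical of this application; the method name is recorded in every report
so the choice stays auditable. The chi-square test defaults
to no continuity correction, switchable by argument. Metrics with zero
denominators are flagged undefined rather than coerced to zero, so a
degenerate candidate can never win model selection by accident.

# The synthetic anterior segment

No clinical images can ship with the package, so the synthetic renderer
is a first-class module. The scene is built from continuous curves in
physical micrometres and only then rasterized: a sclera band whose inner
boundary dips gently temporal to the spur and climbs steeply (the
corneoscleral wall) nasal to it; an iris whose posterior surface is a
circular arc of prescribed sagitta over the root-to-pupil chord, with a
linear thickness profile, a short taper into the insertion and a 20 µm
thickness floor so the insertion survives rasterization; and a ciliary
wedge whose anterior edge tracks the posterior iris over a 1.5 mm extent,
in apposition over `contact_fraction` of it.

Three rasterization-aware choices keep the phantom's ground truth exact:

- *Apposition versus adjacency.* Contact is rendered as a gap of about
  1.2 px — within the extractor's 2 px contact tolerance but beyond
  8-connectivity — and in apposition columns the ciliary top is pinned
  exactly two pixel rows below the iris bottom row, so sloped surfaces can
  never become diagonally adjacent. This matters because the iris *root*
  is defined by adjacency: only the true insertion (where the root end
  overlaps the wedge, balanced by a short stub temporal to the root so the
  adjacency centroid sits on the root point) may touch.
- *Non-contact standoff.* The drop-away portion of the anterior edge sits
  at `max(40 µm, 3.5 px)` — beyond the contact tolerance at either
  acquisition pitch, within the 500 µm iris-facing reach, and shallow
  enough not to inflate the anterior arc length.
- *Analytic ground truth.* Spur and root locations, the sagitta and the
  contact fraction are parameters; the three circle thicknesses are
  computed by running the chord construction on the continuous curves at
  1 µm sampling, independent of any raster. Boundary jitter (smoothed
  Gaussian noise, default 0.3 px, shared between apposed surfaces so the
  gap is preserved) is added to the curves before rasterization, so the
  ground truth stays analytic.

Cohorts draw anatomy from class-conditional ranges with deliberate margins
around the generator's label thresholds — PB if sagitta > 200 µm, TPI if
the analytic 750 µm spur-circle thickness > 500 µm, ALCB if the contact
fraction > 0.4. These thresholds are *generator conventions chosen to make
the four classes controllably separable*; they are explicitly not claims
about clinical cut-offs, for which no accepted quantitative criteria
exist. Up to four images share a synthetic patient id, mirroring the
clinical one-image-per-quadrant convention, so patient-grouped splitting
is exercised for real.

What passing the synthetic benchmark shows — and what it does not: the
end-to-end run (400 images, equal mixture, patient-grouped 3:1 split)
demonstrates that measurement, learning, selection and integration are
internally consistent and recover controllably separable classes with
held-out binary accuracy at or above 0.95 and integrated accuracy at or
above 0.90. Real UBM anatomy is harder: segmentations are imperfect,
mechanisms overlap continuously rather than by construction, and the
phantom renders neither speckle, nor acquisition artifacts, nor plateau
iris. Accuracies on the phantom are upper bounds in kind, not predictions
for clinical data.

# Numerical choices and degenerate inputs

- Measurement circles that miss the iris yield `NA` markers, not errors;
  rows are still emitted and imputed at training time. Only validation
  failures abort a feature row.
- Thickness-arc selection and spur candidate ordering round distances to
  1e-9 before comparison so floating-point noise cannot flip a tie; the
  remaining tie-breaks (smaller angle; smaller row, then column) are
  total.
- The problem sizes used throughout the tests — a 100-mask recovery grid
  and a 400-image benchmark cohort, both at the canonical 1024 x 655
  raster — were chosen as the smallest sizes at which the grid spans the
  full anatomy ranges and every class contributes about 25 patients to
  the held-out set.
- `parameterRecoveryGrid()` and `syntheticBenchmark()` expose the two
  validation studies as ordinary functions; `scripts/acceptance.R` is a
  thin driver around them.

# Known limitations

Single-image scope (no per-patient aggregation across quadrants), no
plateau-iris category, no raw-image enhancement or segmentation (any
image-to-mask front end satisfying `validateMask()` can be plugged in),
and the synthetic-to-clinical caveats above. The spur heuristic is a
documented surrogate for the unavailable original localization procedure;
its method tag keeps it replaceable without touching downstream code.
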