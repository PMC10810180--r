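---
title: "Auditing decision-region composition: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing decision-region composition: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(decreg)
```

## The problem and the model

A classifier deployed on medical images will sooner or later meet patients
unlike any it was developed on. Two failure regimes matter. Under a
*population shift* the patient's class for the task at hand was represented
during development, but other attributes were not; the model can still be
right, but its error profile may tilt. Under *cross-reactivity* the
patient's true class for the task is not even among the model's output
classes — a 70-year-old scored by an age model whose only outputs are
"40 to 49" and "60 to 69" — so the model is wrong by construction and the
only question is *where* it sends such patients.

Per-class accuracy on a finite test set is often uninformative about either
regime. This package instead probes the structure of the decision space near
the data manifold. Deep classifiers organize their decision boundaries
around the training manifold; test images lie on that manifold, so convex
combinations of a few test images stay near it. For a triplet of images
$x_0, x_1, x_2$ drawn from one patient subgroup we synthesize virtual images

$$p(a,b,c) = a\,x_0 + b\,x_1 + c\,x_2,\qquad a,b,c \ge 0,\ a+b+c=1,$$

on an even barycentric lattice, classify each one, and summarize the
*decision-region composition*: the fraction of lattice points assigned to
each class. Because the lattice is uniform over the triangle, that fraction
is an unbiased proxy for the area of the decision region intersecting the
triplet's plane. Virtual images have no ground-truth label, which is why all
three members come from a single subgroup: the subgroup's own class is the
natural reference, and the `same_class` fraction measures how much of the
surrounding space the model concedes to it.

Aggregating compositions (mean and sample standard deviation over a
subgroup's triplets, then equal-weight means over subgroups) yields the
assigned share of each class. The *preferred class* of a task is the argmax
of assigned share; the *preference gap* is its margin over the runner-up.
The report also carries the per-class same-class summary (the mean
same-class fraction over subgroups whose own value is that class), which is
the descriptive view from which a preference can be read off directly. We
operationalize the preference as the assigned-share argmax because it
remains well defined even for cross-reactive subgroups, whose same-class
fraction is identically zero.

## Parameters that matter

* **Lattice resolution `R` (default 25)** — $(R+1)(R+2)/2 = 351$ virtual
  images per triplet. For an affine score the lattice count differs from the
  exact clipped-triangle area by at most about $3/R$ (the boundary line
  crosses $O(R)$ of the $R^2$ lattice cells), so $R = 25$ bounds the
  per-triplet discretization error by roughly 0.12 while keeping a full
  800-triplet audit at desk scale; the acceptance checks run the comparison
  at $R = 50$ against the exact oracle.
* **Triplets per subgroup (default 50)** — the sensitivity stage
  (`triplet_count_sensitivity()`) shows the composition estimate is flat in
  the triplet count while its standard deviation follows the
  finite-population $1/\sqrt{T}$ law; beyond ~50 triplets additional draws
  change little.
* **Partition fractions (default 0.5/0.1/0.2/0.2)** — training, validation1
  (threshold calibration), validation2 (region generation and shift
  evaluation), test. Five evaluation repeats re-draw the
  development/validation2/test split; five training repeats re-split only
  the development pool, giving 25 training/validation1 assignments for
  sensitivity to both data levels.
* **Decision thresholds** — one per task, applied as `score >= t` is
  positive (ties go to the positive class; documented convention).

## Threshold calibration and the operating-point choice

`calibrate_threshold()` selects the equal-error operating point: candidates
are the midpoints of adjacent sorted unique scores plus 0 and 1,
$|FPR - FNR|$ is minimized exactly over that finite set, and ties are broken
by the median candidate (lower median for even counts) so the result is
deterministic. Calibrating at the equal-error point ensures a composition
imbalance is not a trivial artifact of a threshold favoring one class.

Working with analytic scorers exposed a property worth stating plainly: for
a scorer whose defect is a *uniform* score bias, equal-error re-calibration
on validation1 absorbs the bias completely (the calibrated threshold moves
to the shifted midpoint), and the composition imbalance vanishes with it.
A uniform-bias defect is only visible when the model is audited at the
operating point it actually ships with. `run_pipeline()` therefore accepts
either mode: re-calibration per repeat pair (`fixed_thresholds = NULL`) or a
fixed operating point (`nominal_thresholds()`), and the synthetic
demonstration defaults to the fixed nominal point 0.5 — the unbiased
construction's exact equal-error score — so that an injected bias plays the
role of a deployed miscalibration. Real networks are not affine, and their
region imbalances generally survive re-calibration; the affine case is the
worst case for detectability, not the typical one.

## Partitioning: determinism and rounding

Partitions are stratified per subgroup. Counts use largest-remainder
apportionment (remainder ties broken by partition order), which keeps every
subgroup within one patient of its target in every partition. Every shuffle
seeds R's RNG with a stable 31-bit hash of (master seed, repeat indices,
subgroup), so adding a subgroup or repeat never perturbs the other splits,
and plans are bit-identical across platforms for a given seed. Whether the
evaluation-level split should be re-drawn independently per repeat or
rotated is genuinely open; we re-draw independently, which makes repeats
exchangeable at the cost of partial overlap between their validation2 sets.
A subgroup whose validation2 share would fall below three patients aborts
partitioning, because three same-subgroup patients are the minimum for one
triplet.

Image preprocessing follows the standard recipe (bilinear resize so the
shortest side is 320, then a 320×320 center crop). Two conventions the
recipe leaves open are fixed and documented: the non-short dimension rounds
half away from zero, and odd crop remainders bias the window to the
top/left (`floor((dim - crop)/2)`).

## Numerical guarantees

* Composition fractions are rational counts over the lattice size; each
  task's fractions sum to one exactly, and subgroup means sum to one within
  1e-12.
* Virtual-image synthesis accumulates the weighted sum with the triplet
  members sorted by sample id. Since the lattice is closed under permutation
  of the barycentric roles, relabeling the members permutes the weights but
  reproduces bit-identical virtual images — compositions are exactly
  permutation-invariant, not merely up to rounding.
* Virtual pixels lie in the convex hull of the member pixels (no clipping
  inside the triangle). The extended rectangular plane chart, which exists
  for visualization and exploratory tallies (`plane_chart()`,
  `chart_composition(triangle_only = FALSE)`), does leave the hull and is
  clipped to [0, 1]; it is excluded from subgroup aggregates.
* Degenerate inputs are handled explicitly: single-triplet aggregates report
  a standard deviation of zero with a `degenerate` flag; collinear triplets
  are rejected when charting a plane (Gram–Schmidt residual below
  $10^{-8}\,\lVert x_2-x_0\rVert$); agreement verdicts with margins under
  one percentage point are returned as indeterminate rather than asserted.

## The synthetic study conditions

The generator emulates a multi-attribute cohort in which each attribute
modulates its own disjoint 4×4 pixel template on a flat 0.5 background of a
64×64 image, with i.i.d. Gaussian pixel noise and clipping to [0, 1]:

* binary attributes (sex F/M, covid negative/positive, race black/white)
  map to template coefficients ∓1 scaled by the effect size δ = 0.1;
* race carries three additional *unrepresented* values with intermediate
  coefficients (−0.25, 0, +0.25), exercising cross-reactivity;
* age is a continuous latent drawn uniformly in its group's bin
  (<40, 40s, 50s, 60s, 70+ over 25–85 years) with coefficient
  (latent − 55)/10, so the represented 40s/60s groups center at ∓1 and the
  unrepresented bins sit outside or between them;
* pixel noise σ = 0.2 puts the matched-filter raw-score noise at
  σ/(δ·4) = 0.5 against class centers ±1 — the regime where decision
  boundaries genuinely cross triplet planes, which is what makes
  composition analysis non-trivial. Cohorts default to 50 patients per
  represented subgroup, mirroring a minimum-subgroup-size inclusion rule
  (validation2 then holds 10 patients per subgroup).

The matched-filter linear scorer is exactly affine in the pixels, with
weights scaled so noise-free classes score ∓1 raw and the logistic squashing
placing the unbiased equal-error point at score 0.5. Because affine scores
restricted to a triplet plane are affine in the barycentric coordinates, the
exact composition is the area of the reference triangle clipped by one
half-plane, computed by Sutherland–Hodgman clipping and the shoelace formula
(`oracle_composition()`). This is the yardstick the lattice estimator is
verified against.

Template disjointness is a deliberate idealization: real radiographic
attributes are entangled in the pixels, real models are non-affine, and real
score noise is neither Gaussian nor independent of the image. Passing the
synthetic checks therefore demonstrates the *estimator* (lattice vs exact
area, conservation, symmetry, detection of a known injected preference), not
that any particular clinical model generalizes.

## Problem sizes

The shipped test suite and acceptance script run, per seed: 200 random
triplet/threshold draws against the exact oracle at R = 50; a full audit of
8–16 subgroups × 50 triplets at R = 25 (400–800 triplets, ~140,000–280,000
virtual images); preferred-class detection across 20 master seeds; and
sensitivity resampling with 200 resamples per triplet count on pools of up
to 400 compositions. These sizes were chosen so the complete validation runs
on one CPU in a few minutes while keeping every statistical check
well-powered.

## Known limitations

* Binary decisions per task; multi-class tasks would need a different
  threshold model.
* Composition is a *relative* area proxy within each triplet plane; it says
  nothing about absolute distances to decision boundaries, and no
  boundary-distance measurement is attempted.
* The audit's resolution is bounded by the diversity of the test set:
  virtual images recombine only what the real images contain.
* One image per patient is assumed (the patient is the partitioning unit);
  manifests with repeated patients must opt in explicitly.
* DICOM ingestion, windowing and acquisition-mode filtering are upstream of
  this package; it consumes 8-bit grayscale PNG/JPEG or in-memory matrices.
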