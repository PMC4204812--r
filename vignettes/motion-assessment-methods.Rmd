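---
title: "Assessing head motion in fMRI from complete and reduced rigid-body parameter sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing head motion in fMRI from complete and reduced rigid-body parameter sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionQC)
```

## The problem

Rigid-body realignment of an fMRI time series yields six parameters per
volume: three translations $t = (t_x, t_y, t_z)$ in mm and three rotations
$r = (r_x, r_y, r_z)$ in radians. Only the six parameters jointly describe
the detected motion trajectory, yet motion quality control is often based
on translations alone. Because rotations displace tissue proportionally to
its distance from the rotation origin, ignoring them (or ignoring
translations) systematically misstates how much the head actually moved,
which in turn distorts motion scrubbing, motion-induced signal-change
estimates, and the variance attributed to motion in nuisance regression.
This package quantifies those effects end to end, on synthetic data with
known ground truth.

## Total displacement and the average cortical distance

A rotation angle is converted to millimeters at a reference distance: the
average cortical distance $d_{avg}$, the mean Euclidean distance from the
image origin to the voxels on the outer cortical surface of a gray-matter
mask. `averageCorticalDistance()` computes it by (optionally) reslicing
the mask to 1 mm isotropic resolution, extracting the exterior surface by
a background flood fill, and averaging $\lVert v \rVert_2$ over surface
voxel centers $v$. The package default is the conventional representative
value of 65 mm; `davgSensitivitySweep()` quantifies how little the choice
matters over 50–80 mm.

The default scalar summary of one volume's motion is

$$ TD = \lVert\, t + d_{avg} \cdot r \,\rVert_2 , $$

pairing each rotation's arc length at $d_{avg}$ with the same-axis
translation before taking the Euclidean norm. Two alternatives are
shipped because the pairing is a modelling choice, not an identity:
`sphere_mean` (the geometrically exact mean displacement of points on the
sphere of radius $d_{avg}$ under the full rigid transform) and
`reference_point` (displacement of a single point at distance $d_{avg}$).
For a pure rotation by $\varphi$ about one axis the sphere mean has the
closed form $(\pi/4)\, 2 d \sin(\varphi/2)$, which the test suite uses as
an oracle. *Absolute* motion references the first volume, *relative*
motion the previous volume; relative motion is computed by parameter
differencing by default (transform composition is available via
`relativeMethod = "compose"`), which keeps the reduced-set zeroing
well defined.

Transforms are composed as $M = T\,R_x\,R_y\,R_z$ — the composition order
of SPM-style parameter files — with standard right-handed rotation
matrices, centralized in one function so the convention is changed in a
single place. Reduced parameter sets (`translation_only`,
`rotation_only`) zero the complementary three columns exactly
(`reduceParams()`).

## Scrubbing

`censorSeries()` discards volumes whose displacement strictly exceeds the
admissible-motion cutoff ("exceeding" is read strictly; ties are kept),
and never censors volume 1, whose displacement is zero by convention.
`scrubTable()` crosses the three parameter sets with both modes and the
conventional cutoffs 0.5–3 mm and reports each reduced-set count as a
percentage of the complete-set count; undefined cells (complete count 0)
are NA, written as "–" in the text table. For cohorts, datapoints are
pooled before percentages by default (`aggregate = "pooled"`); a
per-subject median is available because published totals can be formed
either way.

## Phantom replay

`buildPhantom()` isolates the purely geometric signal change a motion
trajectory would cause: the first volume is replicated and each volume's
correcting transform is re-applied, i.e. the output intensity at world
position $x$ is the first volume's intensity at $M_t x$. The forward
simulator `simulateFmri()` uses the same pull-back convention, so the
simulate-then-replay round trip is a near-identity bounded only by
interpolation error — a property the tests assert. Interactions of the
moving head with the static field (motion × B0) are *not* modelled; the
replay is geometry only, which should be kept in mind when comparing
scores against estimates from tools that model susceptibility effects.

Signal change is summarized from 9 automatically derived regions of
interest: 8 at the brain/non-brain interface near the volume corners
(found by walking each corner-to-centroid ray to the first mask voxel,
then intersecting a small sphere with a two-voxel shell straddling the
exterior boundary) and one at the brain center. The exact ROI geometry is
a design decision of this package — the size, shape, and "near the
corner" distance are not uniquely determined by the construction's verbal
description — as is the score baseline: each ROI trace is converted to
its absolute deviation from its first-volume value and averaged over ROIs
and volumes 2..T (a mean baseline is available via a flag).
`fingerprintTraces()` turns the ROI traces into motion-fingerprint
nuisance regressors; the 3-trace variant is defined here as the first
three principal-component scores of the 9 centered traces, an
approximation recorded as such rather than a claim of fidelity to any
particular reference implementation.

## Variance explained

`buildDesign()` assembles the regressor sets: the 6 raw parameters
(complete or reduced) and the 24-parameter Volterra expansion
$[\,p,\ p_{t-1},\ p^2,\ p_{t-1}^2\,]$, with "shifted back in time"
implemented as the standard lagged-regressor construction (row $t$ holds
the value from $t-1$, first row zero-padded). Columns are mean-centered;
the intercept is appended at fit time. `fitGlm()` runs ordinary least
squares per voxel and reports $R^2$ and the omnibus
$F = (R^2/K)\,/\,((1-R^2)/(T-K-1))$ with $K$ the effective number of
regressors after pivoted rank reduction (reduced sets carry three
structurally zero columns, so their effective $K$ is 3). No drift or
high-pass regressors are added by default and no adjusted-$R^2$
correction is applied: more regressors explain more variance by
construction, and the package mirrors the convention of reporting each
set relative to the Volterra reference (`percentOfReference()`, mean
$R^2$ over the analysis mask by default, median via a flag) rather than
correcting for model size.

## What the synthetic data emulates

The generators are first-class, tested code and define the study
conditions used throughout the tests and the acceptance script.

* `simulateMotion()` produces random-walk drift (default innovation SD
  0.05 mm per volume) plus sparse persistent steps ("spikes", default
  probability 0.02 per volume, amplitude 0.5–3 mm) — a step, rather than
  a one-volume excursion, is used so that each spike trips scan-to-scan
  censoring exactly once, matching how the spike log is used as ground
  truth. Rotation drift magnitudes follow their own random walk scaled by
  $1/65$ mm$^{-1}$ so both parameter families contribute commensurately.
  The translation/rotation *sign* coupling is applied per volume: the
  drift rotation carries the same-axis translation's sign with
  probability $(1+c)/2$. This makes the per-volume sign-product process
  independent across volumes — a statistical emulation chosen so that
  discordance counts are exactly binomial at $c = 0$ and fully
  (dis)concordant at $c = \pm 1$ — not a biomechanical model; one
  consequence is that rotation drift contributes relatively strongly to
  scan-to-scan displacement.
* `syntheticBrain()` builds ellipsoidal phantoms with a smooth internal
  intensity gradient (so motion produces edge signal), a binary brain
  mask, and a gray-matter shell; a sphere of radius $R$ closes the loop
  with the distance estimator ($d_{avg} \approx R$).
* `simulateCohort()` draws ages uniformly over 4–18 years and sets each
  subject's shell radius to $61.58 + 0.18\,(\text{age} - 11)$ mm plus
  Gaussian noise (defaults chosen to match a pediatric cohort's d_avg
  level and growth rate), for slope-recovery testing.

None of this emulates real anatomy, physiological noise, susceptibility
artefacts, or task activation. Passing tests therefore demonstrate that
the estimators recover known geometric and statistical ground truth, not
that any particular empirical cohort value is reproduced.

## Numerical choices

Resampling uses separable B-spline interpolation of order 0–7 (default 7)
with the standard causal/anti-causal IIR prefilter, so interpolation is
exact at lattice points; coefficients use whole-sample-symmetric (mirror)
boundaries, while sample points strictly outside the input lattice return
0 (phantoms are embedded in zero background by construction). Masks are
re-binarized at 0.5 after interpolation; gray-matter probability maps are
thresholded at 0.5 before surface extraction. The "outer cortical
surface" is the exterior 6-connected boundary found by flood-filling the
background from the volume border, which excludes interior cavities; a
naive boundary mode is available for comparison. The sphere-mean
displacement uses a deterministic Fibonacci lattice (500 points by
default), validated against dense Monte-Carlo sampling in the tests.
Degenerate inputs fail loudly: non-positive $d_{avg}$ or cutoffs, empty
masks, rank-0 designs and dimension mismatches are errors, while an
origin outside the field of view or a fully zeroed design column set
only warns.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale, chosen as the smallest sizes at which every property
is meaningfully exercised: replay phantoms of about $29 \times 25 \times
23$ voxels at 2 mm, cohorts of 12 trajectories of 120 volumes for
displacement/scrubbing summaries, a 60-subject cohort at 1 mm for slope
recovery, and a 0.5 mm ellipsoid for the surface-distance oracle. All
generators are seed-deterministic, and every reported number is
recomputed at run time from those generators.

## Known limitations

* The component-wise pairing in the default displacement formula is the
  most literal reading of the usual arrow construction; it is not
  asserted to be bit-identical to any published implementation, and the
  geometrically exact `sphere_mean` is provided alongside it.
* Replay scores exclude motion × B0 and spin-history effects, so absolute
  scores are lower bounds on real motion-induced signal change.
* $d_{avg}$ from voxel centers underestimates the true surface distance
  by a fraction of the voxel size; at 1 mm this bias is below 1% of a
  typical adult value.
* Cohort-level inferential statistics (rank tests, skipped correlations)
  are delegated to standard routines and not re-derived here.
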