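---
title: "CT-based condylar morphometry: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT-based condylar morphometry: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condylomorph)
```

## The measurement protocol

The package implements a CT-based protocol for quantifying bone modeling of
the mandibular condyle in studies of temporomandibular joint (TMJ) disc
displacement.  The inputs per patient and timepoint are a watertight surface
mesh of the (hemi)mandible in millimetres and a file of named cranial
landmarks.  The protocol has four stages.

**Osteotomy plane.**  The Frankfort horizontal (FH) plane is fitted through
the bilateral porions and the orbitale.  The osteotomy plane C is the plane
parallel to FH through *s*, the lowest point of the mandibular sigmoid
notch.  Because parallelism fixes a plane's orientation only up to sign, the
caller declares a superior reference point (the pipeline uses the crista
galli); the normal is flipped so that reference lies on the positive side.

**Condylar block and volume.**  The mandible mesh is clipped to the
half-space above C, the cut is capped by constrained triangulation of the
cut polygons in plane coordinates, and the volume is the divergence-theorem
signed volume of the capped block.  Vertices within $10^{-6}$ mm of C are
snapped onto it first, which avoids sliver triangles at the rim.  When the
cut leaves several components above C (the coronoid process can protrude
above a low notch), the component whose centroid is most posterior along the
anteroposterior axis is kept: plane C through the sigmoid notch separates
the condyle (posterior) from the coronoid (anterior).

**Seven landmarks.**  On the block, *i* and *o* are the medial and lateral
extreme vertices (cap excluded) along the mediolateral axis; ties are broken
by greater height, then vertex index, so the search is deterministic.  Plane
M is perpendicular to C through *i* and *o*; IO is the projection of the
segment *i*–*o* onto C; plane N is perpendicular to IO and C through the IO
midpoint, and N1/N2 are rotated $\pm 45^\circ$ about the C normal.  *up* is
the highest contour point of the block section on M.  *a* and *p* are the
"lowest edge" points of the anterior and posterior slopes on N, and the two
posterior-slope points on N1/N2 are assigned to *pi* and *po* by proximity
to *i* and *o*.  Every landmark's *height* is its signed distance to C.

**Cephalometrics.**  ANB is the angle at nasion between the rays to the A
and B points after projecting all three onto the midsagittal plane (the
plane through the crista galli whose normal is the in-FH component of the
zygomatico-frontal vector).  It is signed positive when A is anterior to B.
PN is the distance from pogonion to the vertical line through nasion
perpendicular to FH; ME is the distance from menton to the midsagittal
plane.  ME and PN are reported unsigned by default (the direction of
deviation was not part of the published convention); a signed ME is
available behind a flag.

## Operationalizing the "lowest edge of the slope"

The protocol's verbal definition — the point where a section plane meets the
"lowest edge" of the anterior or posterior slope — has no literal
computational reading: the literal lowest point of any slope is on the cut
plane itself, at height zero always, which would make slope-height change
identically zero and cannot be what a clinical operator marks.  The package
operationalizes the lowest edge as the **head–neck concave inflection**: on
the section contour, walking from the apex down a branch, the first local
maximum of concave curvature, with curvature estimated on a contour
resampled at 0.1 mm and smoothed over an arc-length window of three mean
mesh edge lengths.  Three guards make this robust:

* points within `cap_exclusion` (default 0.5 mm) of C are excluded, so cut
  rim artifacts never win;
* only points *below the crest level* (the lower of the *i*/*o* heights)
  are eligible, since the slope's lowest edge is by definition below the
  crest — this also de-sensitizes the search to curvature features high on
  the head;
* if no concave inflection exceeds the minimum concavity (0.01 mm$^{-1}$),
  the lowest non-excluded branch point is returned with a warning.

The branch lying on the negative anteroposterior side of the apex is the
posterior slope.  Because contour resampling quantizes the pick to 0.1 mm
and the smoothing window scales with mesh resolution, slope-point heights
carry a discretization uncertainty of roughly one mesh edge length; the
crest extremes, apex and all plane constructions are exact to floating
point, and all heights are rigid-motion invariant to $10^{-6}$ mm or
better.

## The synthetic condyle and what it does and does not emulate

No patient data accompany the protocol, so the package ships a generator
whose outputs exercise every pipeline stage.  A condyle is a surface with
elliptical cross-sections and a radial profile $\rho(z)$: an ellipsoidal
head (default semi-axes 7 × 5.5 × 6.5 mm) joined $C^1$ to a
$\cosh$-shaped neck whose waist — the analytic head–neck inflection — is
placed at a stated height (default 6 mm) above the cut plane, plus a
flaring stub below the plane so that block cutting is non-trivial.  The
waist radius, join height and $\cosh$ scale are solved numerically from the
requested neck radius.  Defaults were chosen once so that a bilateral pair
lands in the 2100–3400 mm³ range typical of summed adolescent condylar
volumes; the analytic block volume $\int_0^{z_{top}} \pi a b \rho(z)^2 dz$
is ledgered for every generated mesh and serves as an independent
quadrature oracle (mesh volumes agree within 0.3% at the default
resolution, 1% at the coarse test resolution).

Remodeling is phenomenological: per-region amplitudes (superior, eight
45°-azimuth bins around the head centroid) are blended into a smooth
per-vertex field and applied as a displacement.  Two direction conventions
are supported.  Pure outward-normal displacement (`growth = 0`) is the
classical offset surface — useful for volume calibration (a uniform
$\delta$ on a sphere changes volume by $4\pi r^2\delta$ to first order) —
but an offset surface provably keeps the height of the head–neck inflection
fixed, so it cannot move slope landmarks.  `growth = Inf` displaces along
the superior axis, emulating apposition at the superior condylar cartilage;
under it a landmark's height change equals its local field amplitude, which
is the behavior cohort simulations need.  The field is tapered to zero over
1.5 mm above plane C so the osteotomy geometry itself never moves.

The generator emulates: watertight single-condyle geometry with a head,
neck inflection and sub-notch stub; paired baseline/follow-up meshes with
region-weighted apposition; cohort tables with skewed change distributions
(a two-piece split normal whose half-scales are matched to the requested
median and quartiles, so the prescribed median and IQR are reproduced
exactly, the mean differs from the median under asymmetry, and both tails
stay Gaussian — a heavy-tailed family at the same quartile asymmetry
produces unphysical volume changes), bilateral per-side splits that sum
exactly to the ledgered per-patient draws, and a direction-dependent
posteromedial height deficit.  It does **not** emulate segmentation error,
osteophytes or erosive surface irregularity, bilateral shape asymmetry
beyond a smooth low-order perturbation, or any biomechanical remodeling
law.  A green test suite therefore demonstrates that the pipeline measures
what it defines, at the stated discretization accuracy, on clean geometry —
not that the landmark definitions coincide with a human operator's picks on
pathological bone.

## Statistical conventions

* Quartiles use the weighted-average percentile rule at $h = (n+1)p$,
  matching the convention of the commercial statistics environments used in
  clinical reports; mean/SD use the $n-1$ denominator.
* The Mann–Whitney U test enumerates all label assignments exactly for
  combined $n \le 12$ (ties handled by counting); otherwise a tie-corrected
  normal approximation with continuity correction (flag to disable, which
  reproduces the uncorrected asymptotic column some packages print).  The
  continuity-corrected variant was chosen because it tracks the exact test
  within 0.02 at $n = 8+8$, while the uncorrected one does not.
* The two-sample t test defaults to the pooled-variance Student form, with
  Welch available by flag; summary-statistics input follows exactly the
  same formulas as raw input.  Published group summaries of the
  posteromedial/posterolateral height difference (23 vs 18 joints, means
  −0.151 vs −1.068, SDs 1.197/1.333) give $t = 2.32$, $p \approx 0.026$, by
  either variant; the package reports what the formulas give.
* ICC is the two-way random-effects, absolute-agreement, single-measure
  form ICC(A,1) with the F-based confidence interval; the published
  protocol names no variant, and this is the standard choice for two
  interchangeable raters measuring the same subjects.
* The sample-size routine scans equal group sizes upward, computing power
  from the noncentral-t distribution with Satterthwaite degrees of freedom,
  then inflates per group by $1/(1-\text{dropout})$ with ceiling rounding
  and forces the total even (1:1 allocation).  With the published design
  inputs (0.94 vs 166.50 mm³, SDs 153.7/201.5, $\alpha = 0.05$, power 0.90,
  10% dropout) it requires 26 per group, 58 enrolled — consistent with the
  60 the trial used.
* No multiple-testing correction is applied anywhere: every table reports
  marginal two-sided tests, mirroring the analysis style it reproduces.
  Interpret families of p-values accordingly.

## Numerical choices and degenerate inputs

Exact algebra (planes, frames, projections) is validated to $10^{-9}$ mm;
mesh-dependent quantities carry discretization tolerances that scale with
edge length and are always compared against analytic or brute-force oracles
in the tests.  Collinear Frankfort landmarks, a superior reference on the
cut plane, coincident porions, *i*/*o* projecting to one point, empty
blocks and non-watertight inputs all raise typed errors naming the problem;
a cut entirely below the mesh returns the whole mesh as the block; a mesh
with negative signed volume is flipped with a message.  All simulation
entry points take explicit seeds and are pure functions of (parameters,
seed).

## Problem sizes used in the shipped tests

The default test suite runs meshes at azimuthal resolutions 16–128
(subdivision 1–4), cohort calibrations at 100–400 replicates, the null
size checks at 2000 replicates, regression coverage at 500 seeds, and the
end-to-end mesh-level power check at 8 replicate cohorts of 20 + 20
single-condyle patients at subdivision 3.  These sizes keep the full suite
in the tens of minutes on one CPU while leaving every Monte-Carlo bound at
least three standard errors wide of its pass threshold, except where a
published calibration band (type-I error $0.05 \pm 0.01$ at 2000
replicates) is asserted as-is.

## Known limitations

* The crest is operationalized as the whole above-C surface for the *i*/*o*
  extreme search; on extreme dysmorphic condyles the mediolateral extremes
  could leave the anatomical crest.
* Slope landmarks inherit a one-edge-length discretization uncertainty;
  paired designs (T1 − T0 on the same mesh topology) cancel most of it.
* The per-side measurement assumes one condyle per mesh side above plane C;
  fused or duplicated geometry above the notch is resolved only by the
  most-posterior-component rule.
* Mesh-level cohort simulation emits one condyle per synthetic patient for
  runtime; the bilateral summation path is exercised by the
  measurement-level mode instead.
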