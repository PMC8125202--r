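---
title: "Measuring the TMJ joint space on CBCT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the TMJ joint space on CBCT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement model implemented in `tmjgap`,
the assumptions behind each stage, the tunable parameters, what the
synthetic phantom does and does not emulate, and the numerical choices
made where the design was genuinely open.

## The measurement model

The temporomandibular joint is characterized by the width of its
radiological gap — the bone-bounded space between the mandibular
condyle (TMJ head) and the temporal bone's glenoid fossa — at three
standardized sites. All three are read off one vertical cross-section,
the *reference slice*, chosen so that it is reproducible: the vertical
plane through the midpoint of the condyle's longest axial-projection
section, perpendicular to that section. On this slice:

* `r_C` is the vertical distance from the condyle's highest point
  `P_TMJh` to the first fossa bone straight above it, `P_TMJa`. For a
  scan acquired in Natural Head Position this direction is
  perpendicular to the Frankfurt plane.
* `r_D` (dorsal) and `r_F` (frontal) are measured where half-lines from
  `P_TMJa` become tangent to the condyle outline on either side of the
  vertical; each width is the distance from the tangent contact point
  to the fossa along the perpendicular to the tangent.

The only manual input is a cuboid volume of interest (VOI) around one
joint, plus the joint's laterality. The VOI's uppermost axial slice
must lie above the acetabular roof (so the condyle is absent from it),
and the x/y extents should contain the whole condyle with a small
margin.

### Assumptions

* Pseudo-HU values from CBCT are not quantitatively calibrated; the
  method only relies on contrast between air, soft tissue and bone, and
  applies the DICOM rescale linearly with no device-specific
  correction.
* Near the joint, bone values barely exceed ~200 pseudo-HU and the
  histogram is dominated by an air peak — this motivates mixture-model
  classification over fixed thresholding.
* The condyle's shape is approximately convex in each axial
  cross-section (its convex hull is used to close internal voids).
* All non-condylar bone within the VOI (temporal bone, fossa walls)
  reaches the VOI border on every axial slice where it appears — this
  is what the border-component removal step exploits, and it holds for
  any clinically sensible VOI.
* The head is in Natural Head Position; no Frankfurt-plane correction
  is applied.

## Pipeline stages and parameters

### Curvature-flow denoising

Mean-curvature motion of the iso-intensity level sets,
`I_t = kappa |grad I|`, discretized explicitly on the voxel grid with
replicate boundaries; derivatives are taken in voxel units, so the time
step is dimensionless. Defaults: `denoise.timeStep = 0.01`,
`denoise.iterations = 10`. Flat regions (noise) are averaged while
extended edges, whose level sets are nearly flat, barely move; the test
suite verifies both the monotone variance decrease and the
edge-preservation advantage over an equal-variance Gaussian. Denoising
is applied after cropping to the VOI: outside a one-voxel stencil of
the border this is identical to denoising first, and far cheaper.

### Per-slice Gaussian-mixture segmentation

Each axial slice's pseudo-HU values are modelled as a univariate
mixture of `segmentation.components = 3` Gaussians (air, soft tissue,
bone), fitted by EM to convergence (`segmentation.tol = 1e-4` change in
mean log-likelihood, variance floor 1 pseudo-HU²). A pixel is bone iff
its maximum-posterior component is the highest-mean component.

The fit is deterministic: three fixed starts (means at low/median/high
quantiles; at quantiles with the top component anchored at the 99th
percentile; and spread evenly over the value range), each refined by
three hard-assignment iterations before EM. Two details matter in
practice and are deliberate design choices:

* The *upper-tail start* is essential on slices where bone is a small
  fraction of the pixels (below the condyle's equator): a 90th
  percentile that falls inside soft tissue makes EM merge the soft and
  bone classes.
* Among the converged fits, the one whose top component is *compact and
  separated* (top mean at least 4 top-sd above its neighbour; top sd at
  most 3 times the smallest component sd) is preferred over the raw
  maximum-likelihood fit. Partial-volume pixels on tissue boundaries
  otherwise reward a degenerate solution in which one wide
  duplicate-mean component acts as an outlier catch-all — a better
  likelihood but a useless bone classifier. If no fit qualifies, the
  best-likelihood fit is used.

Postprocessing per slice: remove 8-connected components touching the
ROI border, fill each remaining component's convex hull (idempotent);
then keep the largest 26-connected 3D component across the stack (ties
broken by the smallest (slice, row, column) index). 3D labelling is
used rather than per-slice labelling so that different bones cannot be
selected on different slices.

### Reference plane and slice

Per head-bearing slice, the minimum-area enclosing rectangle of the
mask's pixel centres is found by rotating calipers over the convex
hull; the mask pixels within `geometry.contactTolVoxels = 0.75` voxel
diagonals of each *shorter* side's line are averaged and projected onto
it, giving two candidate endpoints per slice. The longest section is
the global maximum of the pairwise distances over all collected
candidates (cross-slice pairs allowed — the section's endpoints may
come from different slices). Degenerate (collinear) slices fall back to
the endpoints of the pixel set's diameter; square rectangles use the
side pair whose contacts are farther apart.

The reference plane is the perpendicular bisector of this section,
azimuth normalized to (−90°, 90°]. Rather than sampling the oblique
plane directly, the whole volume is rotated about the vertical axis
through the anchor (bilinear in-plane, exact in z) so the plane becomes
a grid plane; the slice through the anchor is extracted and
re-segmented with the mixture classifier — without hole filling and
without largest-component restriction, so the fossa survives.

In-plane coordinates: `u` horizontal (spacing `dy`), `v` vertical
(spacing `dz`), v increasing downward. With the azimuth normalized, the
+u direction points dorsally (posteriorly); the laterality input is
carried as metadata resolving presentation, not the dorsal direction,
which is fixed by the geometry.

### Landmarks and gap widths

`P_TMJh`: on the uppermost head-bearing slice, the plane's in-slice
projection line is intersected with the mask; the longest run's
midpoint gives u, and v is taken half a slice above the slice plane —
the head apex lies between this slice and the empty one above it.
`P_TMJa`: marching up the vertical line through `P_TMJh` in the
reference-slice bone mask, skipping the head's own run and at least one
gap sample, the first bone pixel is the fossa roof; its v is reported
at the half-sample boundary toward the gap. These half-sample
corrections matter: voxel-centre landmarks each sit half a voxel inside
their bone, biasing `r_C` by a full voxel on average; with the
correction the error is bounded by one voxel and unbiased.

Profiles are sampled bilinearly at `profile.stepFactor = 0.5` times the
in-plane voxel size. A *bone entry* along a profile is the first
positive local maximum of the central-difference derivative that
exceeds `profile.peakFrac = 0.25` of the profile's largest absolute
derivative (with a small absolute floor against numerical dust), at
least `profile.minOffsetSamples = 2` samples from the origin — the
origin's own bone-exit slope is skipped. Inside the pipeline the entry
must additionally coincide with a soft-to-bone transition of the
sampled GMM mask; on low-dose scans, correlated noise inside the joint
gap can otherwise exceed the derivative threshold.

The tangent sweep evaluates the entry distance `d(theta)` on half-lines
from `P_TMJa` at `sweep.coarseStepDeg = 5` degree steps from 0 to
`sweep.thetaMaxDeg = 50` degrees, gated to the head's own connected
component: past the tangent a line may still hit the fossa farther
out, but it no longer crosses the head, so `d` becomes undefined — a
jump. A jump is a step greater than `max(1 mm, 3 x median previous
increment)` (config `sweep.stepThresholdMm` overrides), or a transition
to "none". The bracketing coarse pair is re-swept at
`sweep.fineStepDeg = 0.5` degrees and the tangent angle is the mean of
the fine bracketing pair — for a step between 31.0° and 31.5°, 31.25°.
Two edge cases are handled explicitly: `d(theta)` accelerates towards
the tangent, so an early coarse "jump" whose fine sweep shows only
smooth growth is treated as a false alarm and the scan continues; and
when the discretized head still intersects every line at the sweep
limit (boundary-pixel grazing can push the apparent tangent ~1° past
the true one, which matters when the true tangent is near 50°), the
sweep reports the limit with a warning rather than failing.

The contact point is the bone entry of the last line still crossing the
head (interpolating at the tangent angle itself may already miss the
head after discretization; the error is bounded by the fine step). The
gap width is the bone-entry distance on the perpendicular profile from
the contact point, directed upward, away from the head — the contact
lies on the line through `P_TMJa`, so "towards `P_TMJa`" is degenerate
as a direction rule. Widths below one voxel are flagged degenerate
(clinically meaningful contact), not errors.

## The synthetic phantom

`generatePhantom()` renders a condyle (sphere or ellipsoid with
configurable long-axis azimuth) and a fossa whose inner surface is the
condyle's surface offset outward by the gap (optionally shifted for
eccentric gaps), as an ellipsoidal bone shell over the upper part of
the head. Soft tissue fills the joint gap and an envelope around the
bone; the rest is air. Defaults mirror the intensity regime observed
near the TMJ: bone 180, soft −60, air −950 pseudo-HU, all with sd 25 —
deliberately low-contrast so segmentation genuinely requires the
mixture model. The acceptance configuration is a 128³ grid at 0.3 mm
isotropic spacing with a 6 mm condyle and a 2.0 mm gap.

Three construction details exist to make the phantom honest about how
the method behaves on real anatomy:

* *Partial volume*: voxels straddling a boundary get fraction-weighted
  intensities (2×2×2 supersampling). Besides realism, this is what
  makes surface localization unbiased at the voxel scale.
* *No free-floating flat bone edges*: any artificial horizontal
  termination of a bone region shows up on one axial slice as a wide
  half-intensity ring — an extra intensity class that a 3-component
  mixture cannot represent, something real anatomy does not produce.
  The shell is therefore bounded by a cone (65° half-angle, axis tilted
  20° toward the medial side) so its rim is slanted, and it connects to
  a vertical-walled root strip running to the grid border, the way the
  temporal bone reaches the edge of any clinical VOI — which is also
  what makes the border-removal step delete it, as in real scans.
* *A condylar neck* continues below the head, as the mandibular ramus
  does, so every VOI slice contains some bone.

Ground truths (`rC`, `rD`, `rF`, tangent angles, azimuth, section
length) follow from the geometry in closed form or by bisection and
ray-casting in the reference plane, and are independent of the noise
seed.

What the phantom does **not** emulate: trabecular texture,
beam-hardening and scatter artifacts, anatomical shape variation,
osteophytes or flattening of degenerated condyles, and head-pose
deviation from Natural Head Position. Passing the phantom suite
therefore demonstrates the geometric and statistical machinery, not
robustness to pathological morphology — on strongly degenerated heads
the tangent search is expected to be the first stage to fail, and it
fails loudly.

## Numerical choices and limitations

* Indexing is 1-based inclusive throughout (R convention); axial slice
  index increases from superior to inferior, and all geometry uses
  index-derived millimetre coordinates.
* Test problem sizes: unit tests run a reduced phantom (80×80×64 at
  0.4 mm) so each pipeline run takes a few seconds; the acceptance
  tests use the full 128³/0.3 mm configuration.
* Mirror symmetry of the dorsal/frontal measurements holds to ~1e−12
  (one floating-point rounding per mirrored bilinear sample), not
  bitwise.
* The measured tangent angle carries an inherent positive bias of
  roughly one voxel divided by the P_TMJa-to-contact distance (grazing
  lines keep touching boundary pixels); at 0.3 mm voxels this is about
  1°. The gap widths are insensitive to it: near the tangency point the
  perpendicular direction changes slowly along the condyle outline.
* EM component count K = 3 matches the air/soft/bone regime near the
  joint. VOIs whose slices contain additional well-populated intensity
  classes (metal artifacts, large marrow spaces) would need K adjusted
  via `segmentation.components`.
* Determinism: for fixed inputs and configuration the entire pipeline
  is deterministic; reports are bytewise reproducible.
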