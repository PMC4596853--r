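---
title: "Spinal cord segmentation by 1-D template matching: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spinal cord segmentation by 1-D template matching: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cordseg)
```

## The model

`cordseg` segments the spinal cord from a 3-D MR volume by comparing
one-dimensional radial profiles of the gradient-magnitude image against a
database of such profiles taken from a manually segmented reference
subject. The key assumption is that the *shape* of the gradient profile
along a ray from the cord centre — low gradient inside the cord, a strong
peak at the cord/CSF interface, a second structure at the outer CSF
boundary — is reproducible across subjects at comparable radii, while its
absolute scale is not. Normalized cross-correlation (NCC) is exactly the
similarity that discards scale and offset:

$$\mathrm{NCC}(f, t) = \frac{1}{n}\sum_x
  \frac{(f(x)-\bar f)(t(x)-\bar t)}{\sigma_f\,\sigma_t},
  \qquad \sigma_f^2 = \frac{1}{n}\sum_x (f(x)-\bar f)^2 ,$$

with population ($1/n$) normalization, so NCC ∈ [−1, 1] and is invariant
to positive affine rescaling of either array. A constant array has
σ = 0; its similarity is defined as 0 and the profile is flagged and
excluded from matching rather than propagating NaN.

The cord's axis is a Catmull-Rom spline through control points thinned
from the user's markings. With Hermite basis functions and local
parameter $t' \in [0,1)$ on segment $i$:

$$p(t) = P_{i+1}\,h_{00}(t') + m_i\,h_{10}(t') + P_{i+2}\,h_{01}(t')
         + m_{i+1}\,h_{11}(t'),$$

where the tangents are $m_i = \tfrac12 (P_{i+2} - P_i)$ and ghost points
$P_0 = 2P_1 - P_2$, $P_{N+1} = 2P_N - P_{N-1}$ make the end tangents
point at the adjacent control point. Two design points deserve note:

* **Segment map.** We use $i = \lfloor t(N-1)\rfloor$,
  $t' = t(N-1) - i$; this is the only map that keeps $t' \in [0,1)$ per
  segment and makes $t \in [0,1]$ traverse all $N-1$ segments.
* **Tangent scale.** The conventional Catmull-Rom factor ½ is the
  default: it is shape-preserving and independent of the number of
  control points. A variant that scales tangents by the control-point
  count is available (`tangent_scale = "count"`); both interpolate the
  control points exactly, but the count scaling grows wild oscillations
  as $N$ increases, which is why it is not the default.

Arc length $s(t) = \int_0^t \lVert p'(u)\rVert\,du$ is precomputed by
dense trapezoidal quadrature (80 samples per segment; 8 for the
500-point refined spline) and cached as an invertible $(t, s)$ table.
Cylindrical coordinates $(z, \theta, r)$ of a point $x$ come from the
nearest spline point $t^*$ (coarse table search plus golden-section
refinement, with the interval ends checked explicitly because
golden-section search never lands on them): $z = s(t^*)$,
$r = \lVert x - p(t^*)\rVert$, and $\theta$ is measured from the
projection of a fixed reference direction $\hat d_0$ (default: the world
+x axis; the paper-style arccos formula is completed to a full
$[0, 2\pi)$ angle via the signed out-of-plane component, since 179
distinct radial directions need a full circle). The frame assumes
$\hat d_0$ is never parallel to the tangent — true for any cord-like,
roughly axial curve; it is checked at construction. A 30 mm capture
radius guards the nearest-point uniqueness assumption.

## Radial profiles and matching

Profiles walk outward from the centre in 0.1 mm world steps, appending
the gradient value of each *newly encountered* voxel until 70 voxels are
collected (naively keeping one value per step would cover only 7 mm;
deduplicated voxels cover ~27 mm at 0.39 mm spacing, matching the
design). Steps outside the grid contribute zeros. The walked distance at
which each voxel was first met is recorded; the mm position of a
fractional edge index is interpolated on the midpoints of consecutive
first-encounter distances, i.e. approximately the edge voxel's centre
distance — the choice that makes a self-segmentation reproduce its own
mask voxel for voxel along each matched ray.

The angle set is $\{0°, 2°, …, 356°\}$ — 179 directions, reproducing the
printed count (one less than 360/2; the omitted direction would be the
duplicate of a signed-angle convention).

Template edges take the last in-mask voxel of the contiguous run from the
centre, bridging holes of at most one voxel (mask noise tolerance).
Degenerate slices (fewer than 3 mask voxels) are skipped with a warning.

Matching visits thresholds 1.00, 0.98, … (200-basis-point decrements)
and stops at the first threshold reached by at least 50 templates; ties
beyond the 50th are broken by database insertion order, which makes runs
bit-reproducible. Below the floor (0.30) the top 50 by raw NCC are used
and the cell is flagged as a fallback — the schedule stays total instead
of failing, and the flag marks the cell for the smoothing cascade. The
inferred edge is the arithmetic mean of the matched templates' edge
indices, averaged in index space (templates and tests are built by the
identical voxel walk, so index space is the commensurate one) and
converted to mm along each test radial afterwards.

Edges from the 100 matched stations are linearly interpolated per angle
to every axial slice in between (no extrapolation beyond the first/last
station). The optional cleanup is a cascade of 1-D median filters with
kernels 5, 7, 9: over θ with circular wrap, then along z with reflect
padding, for each kernel in turn. Rasterization marks a voxel inside iff
its in-plane radius about the slice centre is at most the edge distance
linearly interpolated between the two adjacent angles — a star-convex
region by construction. Re-centering takes each segmented slice's
centroid (largest connected component if fragmented, with a warning),
resamples the centroid path to exactly 500 control points evenly spaced
in z, and fits the refined spline used for arc-distance and CSA work.

## Validation metrics

* **Dice** $2|A\cap B|/(|A|+|B|)$; undefined (error) when both masks are
  empty.
* **Mean centre-line distance (MD)**: in-plane distance between the two
  centre lines on each axial slice. The printed formula divides by
  $n-1$; read as a sum over slices it is inconsistent with "average
  distance per slice" (a constant 0.7 mm offset should give 0.7). We sum
  the $n-1$ slices after the origin slice and divide by $n-1$ — an exact
  per-slice mean that also honours the printed denominator.
* **Hausdorff distance**: computed between boundary-voxel centres
  (6-connectivity surface) in world mm, the "distance between
  segmentation surfaces" reading; a full-volume variant would only
  differ when one mask is contained in the other.
* **Regional CSA**: voxels are projected to arc length on a *shared*
  spline, so centre-line disagreement cannot masquerade as an area
  difference; CSA = in-region voxel volume / region arc length. Region
  bounds come from projecting rootlet markers (C3–C8) onto that spline.
* Cohort aggregation reports mean, sample (n−1) SD, and absolute
  min/max.

## The phantom generator

The phantom emulates the *appearance* the matcher depends on, not MR
physics: a dark cord (piecewise-linear radius 4.6–5.3 mm, rising then
falling like the cervical enlargement) around a sinusoidally deflected
centre line, a bright CSF ring (1.5 mm), mid-intensity background
(intensity ordering CSF 160 > tissue 90 > cord 60, per T2 contrast),
Gaussian partial-volume softening of σ 0.35 mm, and additive Gaussian
noise of σ 5. The softening is essential realism, not cosmetics: with
crisp one-voxel edges the gradient peak is a single sample and NCC
matching becomes brittle in a way real images — whose cord/CSF edge is
spread by the point-spread function and partial volume — are not.
Degradations (extra noise, obliterated-CSF z-ranges where the ring takes
tissue intensity, dark rootlet-like streaks across the ring) change
intensities only; the truth mask and centre line are bit-invariant under
`degrade()`.

The truth mask contains exactly the voxels whose centre lies within the
local radius of the analytic centre line (distance measured to the
curve), which makes the metric oracles analytic: mask volume converges
to $\pi \int r(z)^2\,dz$ as spacing shrinks. Manual markings are
emulated as the truth centre line plus *smooth* in-plane drift
(moving-average-filtered noise, σ 0.3 mm): white per-click jitter is the
wrong error model — an interpolating spline chases it, overshoots, and
inflates arc length by tens of percent, an artifact of the emulation
rather than of rater behaviour.

What the phantom does not model: k-space acquisition, coil profiles,
motion, intensity inhomogeneity, pathology, and anatomy beyond a single
tube (vertebrae, nerve roots as connected structures). Passing the
phantom suite therefore demonstrates the pipeline's geometric and
numerical correctness and its robustness to the listed degradations —
not clinical performance on real acquisitions.

## Study conditions used by the tests

The leave-one-out cohort (`cohort_configs()`) uses six phantoms of
128 × 128 × 100 voxels at the paper-matched 0.3906 × 0.3906 × 0.3 mm
spacing: curvature amplitudes 0–2.5 mm (λ = 80 mm), per-subject radius
scale ±4%, and two obliterated-CSF z-ranges on the last two subjects;
the template subject sits mid-range in radius with moderate curvature
(a deliberately ordinary reference, as one would choose in practice).
This grid keeps a full-size matching problem — 17,900 test arrays
against ~17,900 templates per volume — while the whole suite runs in
minutes on one CPU. The self-consistency fixture is a straight
uniform-radius phantom with 60 slices: at least 50 identical templates
per angle must exist for the schedule to terminate at the 1.00
threshold, which is a property of the database, not of the matcher.

## Numerical choices and degenerate inputs

* Gradient: central differences interior, one-sided at faces, per-axis
  spacing division, Euclidean norm; no pre-smoothing by default (an
  optional in-plane-only variant exists via `axes = 1:2`). The gradient
  is invariant to intensity offsets and scales linearly — properties the
  tests assert.
* Voxel rounding uses R's `round()` (half-to-even); profiles are
  deterministic given (volume, centre, direction).
* Masks read from NIfTI with labels other than {0, 1} are normalized
  with a warning; 2-D/4-D inputs are format errors naming the offending
  dimensionality.
* Fewer than 4 distinct markings is an error; fewer than `n_control` is
  a warning (all are used). Parameters outside [0, 1) are clamped with a
  warning.
* The template database persists via R serialization with an explicit
  format version checked on load; profile arrays, edge indices and
  provenance round-trip losslessly.
* Matching is embarrassingly parallel across stations; the
  implementation processes them in a fixed order so results are
  identical regardless of scheduling, and all randomness lives in the
  phantom module behind explicit seeds.

## Known limitations

* The fixed-$\hat d_0$ frame twists θ around high-torsion curves; a
  rotation-minimizing frame would decouple θ from curve geometry but is
  out of scope.
* Rasterization and template extraction use axial planes (masks are
  axial); at cervical-scale curvature the obliquity error is a small
  fraction of a voxel, but the approximation degrades for strongly
  tilted cords.
* The matcher searches the full database for every test array; a
  z-windowed search would be faster but is deliberately not the default,
  matching the described procedure.
* Edge estimates are quantized at the voxel scale; the median cascade
  trades a sub-voxel amount of genuine angular detail for outlier
  robustness.
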