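# cordseg

Semi-automatic spinal cord segmentation from 3-D MR volumes by
**one-dimensional normalized template matching**, with a synthetic
cord-phantom generator and a full validation-metric suite.

Measuring spinal cord atrophy, arc distances and cross-sectional areas
from high-resolution T2-weighted volumes requires an accurate delineation
of the cord/CSF boundary, which is tedious to draw by hand and hard to
automate robustly across curvature, reduced CSF and imaging artifacts.
`cordseg` implements a template-matching approach aimed at researchers who
have (or can create) one manually segmented reference subject and want to
segment further subjects from a one-minute centre-line initialization.

## Method

1. **Centre line.** User markings along the cord (first point at the
   ponto-medullary junction) are thinned to 20 control points of a
   Catmull-Rom spline `p(t)` built from Hermite basis functions
   `h00, h10, h01, h11`, with ghost end points so the end tangents aim at
   the adjacent control point. Arc length
   `s(t) = ∫ ||p′(t)|| dt` defines the longitudinal coordinate `z` of a
   generalized cylindrical system `(z, θ, r)` whose `θ = 0` direction is a
   fixed reference vector `d̂₀`.
2. **Templates.** On every axial slice of a manually segmented reference
   volume, 179 radial lines (2° increments) emanate from the segmentation
   centroid. Walking outward in 0.1 mm steps and recording each newly
   encountered voxel of the gradient-magnitude image gives a 70-sample
   radial array; the index where the manual mask ends is the template's
   edge position. One subject contributes `179 × (axial slices)` templates.
3. **Matching.** 17,900 test arrays (179 radials × 100 stations evenly
   spaced in arc length) are compared against every template by normalized
   cross-correlation `NCC = (1/n) Σ (f−f̄)(t−t̄) / (σ_f σ_t)`. A threshold
   schedule starts at 100% and drops by 200 basis points until 50
   templates qualify; the cord/CSF edge is the mean of their edge indices.
4. **Reconstruction.** Edges are linearly interpolated to the remaining
   axial slices, optionally cleaned by a cascade of 1-D median filters
   (kernels 5, 7, 9; over θ, then along z), rasterized into a star-convex
   region per slice, and the centre line is refined through the 500
   per-slice centroid control points.
5. **Validation.** Dice coefficient `2|A∩B|/(|A|+|B|)`, mean centre-line
   distance, Hausdorff distance between segmentation surfaces, and
   regional cross-sectional area `CSA = (voxels in region × voxel volume) /
   region arc length`, with regions demarcated by C3–C8 nerve-rootlet
   markers projected onto a shared spline.

Because no reference MRI data are distributable, the package ships a
phantom generator (`phantom_config()`, `generate_phantom()`, `degrade()`)
producing bright-CSF-ring cord phantoms with analytic ground truth —
curvature, cervical-enlargement radius profiles, partial-volume edge
softening, noise, obliterated-CSF segments and rootlet-like artifacts —
so the whole pipeline is testable end to end.

## Worked example

```r
library(cordseg)

# ground-truth subject: curved cord, cervical enlargement, mild noise
gt  <- generate_phantom(phantom_config(grid_shape = c(96, 96, 80),
                                       amplitude = 1.2, seed = 1))
db  <- build_template_db(gradient_magnitude(gt$volume), gt$truth_mask,
                         subject_id = "subject1")
db
#> <template_db> 14320 profiles x 70 samples from 1 subject(s)

# new subject: different curvature, radius and noise realization
subj <- generate_phantom(phantom_config(grid_shape = c(96, 96, 80),
                                        amplitude = 2,
                                        radius_mm = c(4.6, 5.0, 5.3, 4.4) * 0.97,
                                        seed = 2))

# manual centre-line markings (here: truth + smooth rater drift)
markings <- jitter_markings(subj, sd_mm = 0.3, seed = 19)
seg <- segment_cord(subj$volume, markings, db, n_slices = 80)
seg
#> <cord_segmentation> 35784 voxels over 80 slices; 363 fallback cells;
#>   refined spline 500 control points

dice(seg$mask, subj$truth_mask)                                   # 0.966
mean_centerline_distance(seg$refined_spline, truth_spline(subj))  # 0.133 mm
hausdorff(seg$mask, subj$truth_mask)                              # 1.80 mm
regional_csa(seg$mask, seg$refined_spline, c(5, 15))              # 72.3 mm^2
```

A Dice of 0.966 against the analytic truth, a mean centre-line error of
0.13 mm (about a third of an in-plane voxel) and a Hausdorff distance of
1.8 mm are typical for a clean phantom pair; the CSA agrees with the
subject's true `π r²` to a few percent. `smooth_segmentation(seg, volume)`
re-applies the median cascade to the same matches for A/B comparison, and
`loo_cohort(cohort_configs(6))` runs the whole leave-one-out protocol.

A command-line wrapper is installed at `inst/cli/cordseg`:

```sh
cordseg phantom --config cfg.yaml --out dir/
cordseg build-templates --volume v.nii.gz --mask m.nii.gz --out db.rds
cordseg segment --volume v.nii.gz --markings m.json --db db.rds --out seg.nii.gz
cordseg evaluate --pred seg.nii.gz --ref truth.nii.gz --out eval.json
cordseg loo-cohort --n-phantoms 6 --seed 1 --out report/
```

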