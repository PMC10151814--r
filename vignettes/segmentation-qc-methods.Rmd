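---
title: "Methods: multilevel quality control of short-axis contour segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilevel quality control of short-axis contour segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrqc)
```

## The problem

Automatic segmentation of cardiac MRI short-axis cine stacks is usually judged
by a single overlap score, which hides *where* and *why* a model fails and
what the failures cost in clinical units. `cmrqc` evaluates a pair of readers
— a reference reader ("expert") and an evaluated reader (typically a neural
network) — on three levels:

1. **Patient level**: the seven clinical function parameters (LVEDV, LVESV,
   LVEF, RVEDV, RVESV, RVEF, LVM) computed from the contours by disc
   summation, compared with paired t-tests, Pearson correlations pooled via
   Fisher's z', Bland-Altman limits, equivalence tests against tolerance
   intervals, and ICC(3,1) when several evaluated readers are available.
2. **Image level**: per-slice polygon Dice, boundary Hausdorff distance and
   the signed per-slice volume difference, computed on the contours
   themselves, never on rasterized masks.
3. **Position level**: every slice is assigned to a basal, midventricular or
   apical stratum anchored at the expert's extremal segmented slices, so that
   segmentation-decision errors (a structure segmented by only one reader)
   and geometric errors can be localized along the long axis.

All computations operate on subpixel polygon contours in pixel coordinates
(x = column, y = row), scaled by the anisotropic pixel spacing before any
distance or area is taken, so results are in mm, mm^2, ml and grams.

## Volumetry

Volumes use disc summation: the cross-sectional area of each segmented slice
times the slice spacing (thickness + gap), summed over slices. Slices where
the entity is absent contribute zero; no partial-disc interpolation is
applied at the base or apex, because any interpolation scheme would add an
assumption the contour data do not contain. Users comparing absolute volumes
against tools that interpolate a partial basal disc should expect small
systematic offsets.

The myocardium is strictly a derived entity: epicardial area minus
endocardial area (an annulus with a hole), never stored directly. This keeps
the two stored contours the single source of truth and makes the identity
`lvm + lv_endo = lv_epi` hold by construction. On slices where an
epicardial contour exists without an endocardial one — which happens
apically when the cavity vanishes — the full epicardial area is counted as
myocardium, and such slices are reported via an attribute so downstream
users can audit them. Myocardial mass uses a default tissue density of
1.05 g/ml (the standard CMR convention; configurable). Papillary muscles
and trabeculae are wherever the contours put them — by the annotation
convention modeled here they belong to the blood pool, and the engine
applies no carve-outs.

## Geometric metrics

**Dice.** `Dice(A,B) = 2|A∩B| / (|A|+|B|)`, in percent. The intersection is
computed by polygon clipping (Clipper, via the `polyclip` package) in
physical coordinates; regions with holes are handled through ring
orientation (outer counter-clockwise, holes clockwise, nonzero fill), which
makes hole subtraction implicit. Two conventions govern slices with
missing contours and are applied at *comparison* level, keeping the pure
`dice()` operation total and testable: a slice segmented by neither reader
scores 100, a slice segmented by only one scores 0. Correspondingly two
averages are reported: over **all slices** (decision-aware; mean only,
because the zero values make a standard deviation misleading) and over
slices **segmented by both** (mean ± sd). The all-slices average can never
exceed the both-only average once a decision error exists in a bucket.

**Hausdorff distance.** The symmetric sup-inf distance between the region
boundaries, approximated on boundary point sets densely resampled at
0.25 px (default) so the reported value is within two resampling steps of
the continuous contour Hausdorff distance. For the myocardium both the
epicardial and endocardial rings form the point set, since the entity's
boundary is both rings; this choice is recorded in the run metadata because
an epicardial-only convention would differ on displaced endocardial
contours.

**Numerical choices.** Identical ring sets short-circuit to Dice 100 and
Hausdorff 0 before any clipping, which keeps identity comparisons exact and
free of floating-point noise. The clipping route is cross-checked in the
test suite against an independent even-odd scanline rasterization of both
polygons on a 1024^2 grid; the two routes agree to well under 0.5 Dice
points on random phantom pairs. Mask rasterization labels a pixel by
containment of its center with boundary points counting as inside;
vectorization uses marching squares (base R `contourLines`) at iso-level
0.5, which yields subpixel vertices, followed by largest-polygon selection
per structure — mirroring the usual postprocessing of CNN output masks.

## Slice-position stratification

For each entity and phase, the expert's most basal segmented slice — plus
every slice beyond it (toward the base) that the evaluated reader segmented
— is **basal**; the mirrored rule at the apex gives the **apical** block;
everything strictly between the two anchors is **midventricular**. Interior
slices the reader skipped stay midventricular and count as false negatives
there. Reader slices beyond an anchor are absorbed into the anchor's block
even when separated from it by an unsegmented gap; the rule is "all false
positives above the basal anchor are basal", which keeps the partition
exhaustive. When the expert never segmented the structure, no anchor
exists: all slices are unassigned and the reader's false positives are
reported in a separate unassigned bucket rather than silently dropped.

Classification is per structure and per phase, because the basal extent of
a structure legitimately differs between ED and ES. Stratified tables pool
ED and ES. The "overall" rows pool the per-slice records across entities
and recompute precision and recall from the pooled confusion counts — with
a single evaluated reader this is the natural aggregate of the per-entity
rows.

Decision metrics use the per-slice confusion: `precision = tp/(tp+fp)`,
`recall = tp/(tp+fn)` in percent, with empty denominators reported as
undefined (`NA`), never as zero.

## Statistical layer

* **Paired t-test**: classical two-sided paired t on reader − expert
  differences (delegating to `stats::t.test`), with explicit degenerate
  handling: identical nonzero differences report a machine-floor p-value
  and a flag; all-zero differences give t = 0, p = 1. No multiple-testing
  correction is applied across the seven parameters — each is reported at
  its raw α = 0.05 level.
* **Fisher z' pooling**: `tanh(mean(atanh(r)))`. Inputs with |r| = 1 are
  rejected rather than silently mapped to infinity.
* **ICC(3,1)**: single-rater consistency ICC from the two-way mean squares,
  `(MS_R − MS_E)/(MS_R + (k−1)MS_E)`, with the 95% CI from the
  F-distribution method (`F = MS_R/MS_E` on (n−1, (n−1)(k−1)) df). Raters
  that differ by a fixed shift have ICC exactly 1 (consistency ignores
  additive offsets); zero between-subject variance yields an undefined
  marker.
* **Equivalence**: the 95% CI of the mean difference,
  `mean ± t_{0.975,n−1}·sd/√n`, must lie completely within a configured
  tolerance interval, inclusive at the boundary. The CI is t-based rather
  than normal-based — with cohort sizes in the tens the difference is
  material, and the t interval is the conservative choice; this is recorded
  in the run metadata. Tolerance intervals are runtime configuration,
  typically derived from published intraobserver variability, and are not
  hard-coded.
* **Bland-Altman**: bias and bias ± 1.96·sd limits of agreement.

## The synthetic phantom

The study's clinical data cannot be redistributed, so validation rests on a
phantom generator whose geometry has closed-form truth. A phantom case is a
contiguous stack (default 7 mm thickness, no gap, 1.4 mm isotropic pixels
on a 256×256 grid) of 10 segmented slices plus one empty grid slot at each
end, so decision-error models have room to add slices beyond the anchors.
The LV endo- and epicardium are circles with an ellipsoidally tapering
radius profile (default basal endo radius 24 mm, 8 mm wall); the RV is a
crescent built as the clipped difference of two offset disks, its truth
area taken from the generated polygon itself (shoelace) rather than from
fragile closed-form crescent algebra. ES contours are ED contours scaled
about their centroid by a contraction fraction (default 0.63 LV / 0.71 RV),
so areas scale with the square and the designed LVEF is near 60%. Contours
carry 256 boundary vertices by default; at that density the polygon-vs-circle
area deficit is about 2.5·10⁻⁴, comfortably below the 1% recovery tolerance
used in the tests. Cohorts draw per-case geometry (heart size, wall,
slice count, contraction) from physiological ranges using a per-case
substream seed derived by stable hashing of (seed, case id), so parallel or
partial regeneration is reproducible.

Reader-error models emulate the recurring failure modes of automatic
short-axis segmentation: basal/apical segmentation-decision errors (dropping
the anchor slice, adding a spurious slice beyond it), radial over-/under-
segmentation bias, whole-contour displacement, fragmentation (replacement by
a small centered fragment) and radial vertex jitter. Models compose in
declared order; position targeting is always resolved against the
unperturbed stack, so a basal-targeted model can never touch midventricular
or apical slices. Every injected event is book-kept with its expected
per-slice volume offset, which is what the parameter-recovery tests check
against the full pipeline.

What the phantom does **not** emulate: realistic image intensities (there
are no images at all), papillary/trabecular irregularity, valve-plane
obliquity, breath-hold misregistration between slices, and genuinely
non-star-shaped contour errors. Passing the phantom suite therefore
demonstrates the correctness of the measurement and statistics machinery,
not clinical performance of any segmentation model.

## Problem sizes and tolerances in the test suite

The suite validates geometry on 256–1024-vertex circle polygons (analytic
lens-overlap Dice 84.1% at 5 mm offset of 20 mm circles; translated-circle
Hausdorff 5 mm), volumetry at 256 vertices against closed forms (< 1%),
the clipping-vs-rasterization cross-check on 100 random pairs at a 1024^2
grid (< 0.5 Dice points), end-to-end identity on a 29-case cohort, t-test
calibration on 2,000 null simulations (rejection rate in [0.038, 0.062] at
α = 0.05), and ICC/t-test oracle agreement to 10⁻⁸ against independent
ANOVA-based references. These sizes were chosen as the smallest at which
the analytic tolerances are comfortably resolved.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
coh <- make_cohort(
  n_cases = 10,
  models = list(error_model("radial_bias", delta_mm = -0.5),
                error_model("basal_decision", p_drop_anchor = 0.3)),
  seed = 1)
res <- compare_readers(coh$experts, coh$readers,
                       tolerances = list(lvedv_ml = c(-12, 12),
                                         lvef_pct = c(-5, 5)))
res
build_report(res, "cmrqc_report")
```

## Known limitations

* One polygon per structure per slice: genuinely fragmented predictions are
  reduced to their largest polygon at import, as in the usual postprocessing
  convention, so the metrics never see multi-component readers.
* Endocardial contours may contain holes in the data model, but the
  annotation convention modeled here (papillary muscles in the blood pool)
  implies none in practice.
* No DICOM geometry: slices are assumed parallel and aligned; only the
  in-plane spacing, thickness and gap enter the computation.
* Disc summation without partial-disc interpolation (see above).
* The equivalence and tolerance machinery is only as meaningful as the
  tolerance intervals supplied to it.
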