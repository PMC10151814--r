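# cmrqc — multilevel quality control of cardiac MRI short-axis segmentations

`cmrqc` evaluates paired contour annotations of cardiac MR short-axis cine
stacks: a reference reader (an expert) against one or more evaluated readers
(typically neural-network segmentations of the LV endocardium, LV epicardium
and RV endocardium at end-diastole and end-systole). It answers three
questions at once:

* **Patient level** — do the clinical function parameters agree? EDV, ESV
  and EF for both ventricles plus LV myocardial mass are computed by disc
  summation, `V = Σ A_slice · (thickness + gap)`, directly from the subpixel
  polygons. Agreement is quantified with paired t-tests, per-parameter
  Pearson correlations pooled via Fisher's z'
  (`r_z' = tanh(mean(atanh(r_i)))`), Bland-Altman limits, ICC(3,1)
  (single-rater, consistency, two-way mixed model), and equivalence tests
  that require the 95% CI of the mean error to lie inside a tolerance
  interval.
* **Image level** — where do the contours disagree? Per slice and structure:
  polygon-clipping Dice `2|A∩B|/(|A|+|B|)`, boundary Hausdorff distance
  `max(sup_a inf_b d(a,b), sup_b inf_a d(a,b))` in mm, and the signed
  per-slice volume difference in ml. All metrics are contour-based; masks
  are never the unit of computation.
* **Position level** — are errors basal, midventricular or apical? Slices
  are stratified by a rule anchored at the expert's extremal segmented
  slices, and segmentation-decision errors (a structure segmented by only
  one reader) are counted as precision/recall per stratum.

Because clinical contour data usually cannot be shared, the package ships a
synthetic phantom generator with closed-form ground truth and parametric
reader-error models (radial bias, displacement, basal/apical decision
errors, fragmentation, jitter), which is also how the package validates
itself.

## Worked example

```r
library(cmrqc)

coh <- make_cohort(
  n_cases = 10,
  models = list(error_model("radial_bias", delta_mm = -0.5),
                error_model("basal_decision", p_drop_anchor = 0.3)),
  seed = 1)
res <- compare_readers(coh$experts, coh$readers,
                       tolerances = list(lvedv_ml = c(-12, 12),
                                         lvef_pct = c(-5, 5)))
res$comparisons$reader
#> # A tibble: 7 × 7
#>   parameter n_cases mean_diff sd_diff t_stat  p_value pearson_r
#>   <chr>       <int>     <dbl>   <dbl>  <dbl>    <dbl>     <dbl>
#> 1 lvedv_ml       10     -5.70    4.54  -3.97 0.00325      0.957
#> 2 lvesv_ml       10     -4.45    2.58  -5.46 0.000400     0.949
#> 3 lvef_pct       10      2.61    3.66   2.26 0.0504       0.733
#> 4 rvedv_ml       10      0       0      0    1            1
#> 5 rvesv_ml       10      0       0      0    1            1
#> 6 rvef_pct       10      0       0      0    1            1
#> 7 lvm_g          10      5.99    4.77   3.97 0.00325      0.952
```

The injected 0.5 mm radial under-segmentation of the LV endocardium shows up
exactly where it should: volumes drop by a few ml (and the derived
myocardial mass rises), the RV is untouched, and the ejection fraction is
pushed up. The stratified table localizes the decision errors:

```r
dplyr::filter(res$stratified$reader, entity == "overall")
#>   position       precision_pct recall_pct dice_all_pct dice_both_mean_pct
#> 1 basal                    100       83.3         81.9               98.3
#> 2 midventricular           100      100           97.8               97.8
#> 3 apical                   100      100           96.9               96.9
```

Only the basal stratum loses recall (the dropped anchor slices), and the
all-slices Dice average falls below the both-segmented average exactly
there. The equivalence test reads:

```r
res$equivalence$reader
#>   parameter mean_diff   ci_low ci_high tol_low tol_high equivalent
#> 1 lvedv_ml      -5.70 -8.95      -2.45     -12       12 TRUE
#> 2 lvef_pct       2.61 -0.00577    5.23      -5        5 FALSE
```

The LVEDV error stays within its ±12 ml tolerance band, while the LVEF CI
crosses the +5% bound, so equivalence is rejected for EF.
`build_report(res, "outdir")` writes all tables as CSV plus the figures
(candlelight boxplots, position-colored correlation scatter, Bland-Altman,
equivalence chart) and a JSON metadata sidecar.

## File formats and CLI

Contour stacks use a documented JSON format (schema in
`inst/extdata/contour-stack-schema.json`); `write_contour_stack()` /
`read_contour_stack()` round trip vertices bit-exactly. Label masks (PNG or
NIfTI) can be imported via marching-squares vectorization with
largest-polygon postprocessing (`mask_to_contours()`) and exported back
(`contours_to_mask()`).

A thin command-line wrapper over these functions lives at
`inst/cli/cmrqc.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "cmrqc.R", package = "cmrqc"))')" \
  simulate --n-cases 10 --seed 1 --outdir cohort
```

with subcommands `simulate | convert | params | metrics | stratify | stats |
compare | report` (exit codes: 0 success, 2 validation error, 3 I/O error).

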