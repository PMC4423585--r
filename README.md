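# icvsampler

Protocol evaluation for intracranial volume (ICV) estimation.

ICV — the volume of the cranial cavity — is the standard normalisation
covariate in brain morphometry, and its careful measurement matters most in
Alzheimer's disease (AD) studies, where head-size effects must be separated
from atrophy. The reference measurement is manual: a rater labels the
cavity on every MRI slice and ICV is the labelled-voxel count times the
voxel volume. Because that is slow, practical protocols trace only every
*m*-th slice and scale by *m* (the Cavalieri estimator):

    ICV_hat(m, s) = m * sum_k A_{f+s+km} * d / 1e6   [litres]

with per-slice areas `A_i` (mm²), slice spacing `d` (mm), first occupied
slice `f` and random start offset `s` in `0..m-1`. The package answers the
two protocol questions around this estimator for people designing ICV
measurement pipelines:

1. **How large may the sampling period be** before subsampled tracing stops
   being a reliable surrogate for full tracing — quantified by the empirical
   distribution, over random starts, of the two-way random-effects
   absolute-agreement intraclass correlation (Shrout–Fleiss ICC(2,1))
   between full and subsampled measurements, with guidelines extracted at
   `p5(ICC) >= 0.99` ("95% confidence of reliability above 0.99") or
   `p95 - p5 <= 0.005` ("tight spread");
2. **How much automated tools and repeated raters disagree** with the
   manual reference — paired t-tests, Pearson correlation, the mean related
   percentage of absolute difference `MRPAD = 100/n * sum |est-ref|/ref`,
   and a Type III factorial GLM of ICV on group, sex, age and method.

Because the original MRI cohort is not deposited, the package ships a
synthetic cranial-cavity phantom generator (perturbed ellipsoids with
seed-drawn, band-limited surface roughness and known ground-truth volume)
plus parametric simulators of operator tracing noise and automated-tool
bias, calibrated to published cohort summaries. Everything — cohorts,
tracings, reliability analysis, guidelines, comparison tables — runs from a
single master seed and is byte-reproducible.

## Worked example

```r
library(icvsampler)

## an AD-like phantom with known ground truth (192^3 voxels, 1 mm)
spec    <- phantom_preset("AD")
phantom <- generate_phantom(spec, subject_seed = 7)
icv_from_mask(phantom)
#> [1] 1.490446

## subsample it: every 10th slice, start offset 3
subsample_icv(phantom, m = 10, start_offset = 3)
#> <subsample_estimate> m = 10 (10.000 mm), start 3: 1.487830 L over 13 slices

## reliability of the subsampling protocol on an 11-subject cohort
cohort <- generate_cohort(spec, n_subjects = 11, "AD", master_seed = 1)
draws  <- run_randomized_reliability(cohort, periods = 2:30,
                                     n_reps = 500, seed = 2)
curve  <- summarize_curve(draws)
curve[curve$m %in% c(10, 20, 30), c("m", "icc_p5", "icc_spread", "mpe_p95")]
#>     m  icc_p5 icc_spread  mpe_p95
#> 9  10 0.99895    0.00069  1.38766
#> 19 20 0.98859    0.00754  5.06587
#> 29 30 0.96583    0.02591 11.21134

guideline_max_period(curve, "confidence_icc", slice_spacing = 1)
#> <guideline_result> confidence_icc: max safe period 18 slices (18 mm)
guideline_max_period(curve, "tight_spread", slice_spacing = 1)
#> <guideline_result> tight_spread: max safe period 17 slices (17 mm)
```

Reading: at a 10 mm sampling period, 95% of random sampling starts keep the
ICC with the full measurement above 0.9989 and the worst per-subject error
below ~1.4% in 95% of realisations; by 30 mm reliability has collapsed. For
this rough-surfaced AD-like cohort no period beyond 18 mm keeps the ICC
above 0.99 with 95% confidence — smoother AC-like cohorts tolerate longer
periods (about 21 mm under the same analysis), which is the package's
qualitative reproduction of the published population contrast.

The full two-phase study (cohorts for both groups, three tracings per
subject, six tool measurement series, reliability curves, guidelines,
agreement tables, factorial GLM) is one call:

```r
report <- run_study(study_config(master_seed = 42, out_dir = "study_out"))
print(report)
```

or from a shell, `Rscript inst/scripts/run_study.R --seed 42 --out study_out`.

The statistics are also usable standalone, e.g. the ICC on a worked
three-subject table:

```r
icc_two_way_random(c(1, 2, 3), c(2, 3, 4))
#> [1] 0.6666667
```

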