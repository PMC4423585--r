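---
title: "Evaluating ICV estimation protocols with synthetic cranial phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ICV estimation protocols with synthetic cranial phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icvsampler)
```

## The problem

Intracranial volume (ICV) — the volume of the cranial cavity bounded by the
dura — is the standard covariate used to normalise brain morphometry for
head size, particularly in Alzheimer's disease (AD) research where regional
atrophy must be separated from constitutional head-size differences. The
reference way to measure it is manual: a rater traces the cavity on every
slice of a T1-weighted volume, and ICV is the number of labelled voxels
times the voxel volume.

Tracing every slice is prohibitively slow, so practical protocols trace
only every *m*-th slice (the sampling period) and scale the result — the
Cavalieri estimator of stereology. Two protocol questions follow:

1. **How large can *m* be** before the subsampled estimate is no longer a
   reliable surrogate for the full measurement — and does the answer differ
   between patient (AD-like) and control (AC-like) populations?
2. **How trustworthy are automated tools** (atlas-based and
   tissue-class-based packages) relative to the manual reference?

The study design this package reproduces answers both with a two-phase
protocol: a reference rater traces every subject twice (two months apart),
a second rater once, automated tools run in both phases, and a randomized
resampling analysis quantifies the reliability of subsampled tracing.
Because the underlying MRI cohort is not publicly deposited, the package
generates synthetic cranial-cavity phantoms whose statistical structure
matches the published cohort summaries, and every analysis runs on those.

## The subsampling estimator

For a mask with per-slice cavity areas $A_1, \dots, A_S$ (mm²) and slice
spacing $d$ (mm), the full-sampling ICV is $\sum_i A_i \, d / 10^6$ litres.
The interleaved estimator with period $m$ and start offset
$s \in \{0, \dots, m-1\}$ (relative to the first occupied slice $f$) traces
slices $f+s, f+s+m, \dots$ and reports

$$\widehat{ICV}(m, s) \;=\; m \sum_{k} A_{f+s+km} \; d \,/\, 10^6 .$$

Averaging over all $m$ offsets recovers the full ICV exactly — the
estimator is design-unbiased — and with $m = 1$ it *is* the full
measurement. Both identities are kept bit-exact in the implementation by
routing every volume through one canonical voxel-count-times-spacing
expression; the test suite asserts them at machine precision.

## The randomized reliability analysis

Reliability of period $m$ is quantified by the intraclass correlation
between the full measurements and one random realisation of the subsampled
estimates across the cohort. `run_randomized_reliability()` repeats, per
period (default 5000 times):

* draw a start offset uniformly from $\{0, \dots, m-1\}$ — independently
  per subject by default (each scan is traced independently; a
  `shared_starts` mode is available);
* re-estimate every subject's ICV;
* record the ICC against the reference volumes and the maximum percentage
  error (MPE) over subjects.

The ICC is the single-measure, absolute-agreement, two-way random-effects
coefficient (Shrout–Fleiss ICC(2,1)):

$$ICC = \frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E + k\,(MS_C - MS_E)/n},
\qquad k = 2,$$

with $MS_R$, $MS_C$, $MS_E$ the target, rater and residual mean squares.
*Absolute agreement* is the deliberate choice: subsampling produces
realisation-specific systematic offsets, and a consistency-type ICC would
not penalise them. The consistency variant is exposed as an option. For
$k = 2$ the rater and residual mean squares reduce to functions of the
paired differences; computing them that way keeps both non-negative in
floating point, so $ICC \le 1$ holds by construction and perfect agreement
returns exactly 1.

`summarize_curve()` reduces the draws to the 5th/25th/50th/75th/95th
percentiles of the ICC per period (linear interpolation between order
statistics, `quantile(type = 7)`; with thousands of draws the estimator
choice is immaterial, but determinism requires fixing one), the spread
(95th minus 5th percentile), and the MPE band $[p_5, p_{95}]$ reported as
a 90% interval. The MPE of one repetition is the maximum over subjects;
its distribution is summarised across repetitions.

`guideline_max_period()` extracts the protocol guideline under two
criteria:

* **confidence_icc** — the 5th ICC percentile is at least 0.99, i.e. with
  95% probability a random subsampling realisation keeps reliability above
  0.99;
* **tight_spread** — the spread is at most 0.005.

The guideline is the largest tested $m$ such that *every* smaller tested
period also satisfies the criterion (contiguous-from-smallest rule). The
empirical ICC behaves erratically at large periods, where an isolated pass
is a sampling artefact, not a safe recommendation. Guidelines are reported
both in slices and in millimetres ($m \times$ slice spacing) so they
transfer across acquisitions; the slice spacing is therefore an explicit
input rather than something inferred.

## The phantom generator

`generate_phantom()` voxelises a perturbed ellipsoid: a voxel belongs to
the cavity iff its centre lies inside

$$R(\theta, \varphi) = r_{ell}(\theta, \varphi) +
  A \cdot P(\theta, \varphi),$$

where $r_{ell}$ is the radius of the base ellipsoid along the voxel's
direction, $A$ is the roughness amplitude (mm) and $P$ is a seed-drawn
band-limited field of unit maximum amplitude: eight random sinusoids in
$(\theta, \varphi)$ with frequencies up to `roughness_order`, coefficients
normalised to $\sum |c_j| = 1$, and $\sin\theta$ damping on the azimuthal
terms so the field is continuous at the poles. The centre-inside membership
rule matches voxel-count volumetry, makes the voxel volume converge to the
analytic $\tfrac43 \pi abc$ as spacing shrinks (tested at two resolutions),
and is unbiased to second order in the spacing.

Half of the perturbation terms are axisymmetric ($\varphi$-frequency
zero). This is a deliberate and load-bearing design point: a slice's area
integrates over azimuth, so purely azimuthal surface wiggles cancel and
leave the slice-area profile — the only thing the subsampling estimator
sees — almost untouched. During development, cohorts perturbed only
azimuthally were indistinguishable from smooth ellipsoids in the
reliability analysis at any amplitude. Axisymmetric terms, by contrast,
modulate the profile directly ($\Delta A(z) \approx 2\pi r(z) A
P_{axi}(\theta(z))$).

Requiring $A < \min(a, b, c)/2$ keeps the surface star-shaped around the
centre, which in turn keeps the voxelised cavity a single 26-connected
component (asserted by a flood-fill check in the tests). The surface must
also fit inside the grid with a two-voxel margin on every face; violations
are rejected with a geometry error.

### Group presets

`phantom_preset()` encodes the two study populations:

| preset | target ICV (L)      | roughness (mm / order) | demographics        |
|--------|---------------------|------------------------|---------------------|
| AD     | 1.4870 ± 0.16418    | 6 / 20                 | age 81 ± 9.31, 6F/5M per 11 |
| AC     | 1.4609 ± 0.14444    | 2.5 / 8                | age 71 ± 6.21, 9F/2M per 11 |

Cohorts draw per-subject target volumes from the group normal distribution
(truncated at 3.5 SD so extreme draws cannot overflow the default
192³ × 1 mm grid) and scale the base semi-axes — proportions (80, 72, 66),
roughly the shape of a cranial cavity — to match; the roughness field is
independent per subject. The published cohort attributes the patient
group's stricter sampling requirement to group differences without
modelling them; surface roughness is this package's single controllable
surrogate for that difference, and that attribution is an assumption, not
a finding. The amplitudes and orders were fixed once, by a calibration
sweep, so that (i) the guideline periods land at the reported 10–25 mm
scale and (ii) the rough preset needs a shorter safe period than the
smooth one in at least 90% of replicate experiments; the AD amplitude sits
near the maximum the grid margin admits.

### Operator and tool simulators

`simulate_operator_tracing()` models a human rater: per slice a signed
radial boundary offset $\delta \sim N(0, \sigma)$ is drawn. Manual tracing
variability ($\sigma \approx 0.005$–$0.05$ mm) is far below the voxel
size, so the offset cannot be rendered by moving voxels; instead it is
realised by stochastic boundary rounding — boundary pixels are included
(for $\delta > 0$) or excluded (for $\delta < 0$) with probability
$|\delta|/h$ — which displaces the boundary by $\delta$ *in expectation*
(expected area change $\approx$ perimeter $\times\ \delta$). With
$\sigma = 0$ the input mask is returned bit-identically. The default
$\sigma = 0.02$ mm puts the tracing MRPAD (mean related percentage of
absolute difference, below) near 0.005%, the middle of the 0.002–0.014%
range reported for careful raters; `calibrate_operator_jitter()` re-derives
such a value for any cohort by tracing it at candidate jitters.

`simulate_tool_icv()` models automated packages parametrically: measured
$= \text{true} \times b \times (1 + \varepsilon)$, with multiplicative
bias $b$ and noise CV. The presets (`FS` 1.08/0.05, `FSL` 2.77/0.10, `SPM`
0.90/0.05) are scaled to the error magnitudes published for the real
packages on adult cohorts — a mildly overestimating and a mildly
underestimating tool, plus one with gross overestimation
($b = 2.77 \Rightarrow$ MRPAD $= 177\%$ at zero noise). They are error
models, not simulations of the packages themselves.

## Agreement statistics

* `mrpad(est, ref)` $= \frac{100}{n}\sum_i |est_i - ref_i|/ref_i$ — scale
  invariant, used for rater and tool agreement.
* `paired_t_test()` — two-sided, $n-1$ df; zero-variance differences are
  flagged degenerate ($t = 0, p = 1$ for identical series) instead of
  erroring mid-pipeline.
* `pearson_r()` — clamped to $[-1, 1]$ against rounding; zero-variance
  input errors.
* `factorial_glm_anova()` — least-squares fit of ICV on group, sex, age
  and method with interactions; per-term F from Type III sums of squares
  under sum-to-zero contrasts. Numeric covariates are mean-centred, since
  an uncentred covariate makes every Type III "main effect" an
  extrapolation to covariate zero (age 0 here — during development this
  turned a overwhelming method effect into $p \approx 1$). Method is
  treated as an ordinary between-style factor, mirroring the single-GLM
  layout of the original analysis; its F therefore ignores within-subject
  correlation, which a mixed model would capture. Tool-vs-reference
  comparisons are plain paired t-tests per method within group rather than
  post-hoc contrasts under the GLM: the null is the same and the result
  does not depend on one package's contrast machinery. Noise-free designs
  (zero residual variance) are reported with limit-value F (0 for terms
  with zero sum of squares, Inf otherwise) and a warning.

## The orchestrated study

`run_study()` wires the stages together per group: generate cohort → trace
every subject three times (operator 1 in phases I and II, operator 2 in
phase I; operator 1/phase I is the reference) → simulate each tool in both
phases → randomized reliability on the reference tracings → guidelines
under both criteria → agreement batteries and the factorial GLM. Every
random draw derives from the master seed through fixed streams, so a
report is byte-reproducible from `(config, master_seed)`; all tables are
also written as CSV/JSON when an output directory is configured. The
defaults are the reference protocol (11 subjects/group, periods 2–40,
5000 repetitions); the bundled acceptance script runs a lighter but
statistically equivalent scale — periods 2–30 and 500 repetitions, which
bounds the Monte-Carlo error of a 5th percentile well below the guideline
granularity — and the test suite uses coarser grids (2 mm voxels) for the
end-to-end contracts, where only determinism and dataflow are at stake.

## What the phantoms do and do not establish

The generator reproduces: group ICV means and SDs, slice-profile roughness
differing between groups, rater noise at the reported MRPAD scale, and
tool bias/noise at the reported MRPAD scale. It does not reproduce: real
cranial shape (a perturbed ellipsoid has no skull base, sinuses or
foramen), MRI intensities or segmentation ambiguity (raters err here by
misjudging the dura, not by white radial noise), inter-subject shape
correlation, or any group difference other than size and surface
roughness. Passing tests therefore validate the *estimators and the
statistical machinery* — unbiasedness, exactness identities, ICC
correctness, guideline logic, calibration of the t-test — and demonstrate
that the pipeline recovers the qualitative population contrast built into
the presets. They do not re-derive the published cohort's numeric
guidelines, which depend on undeposited scans.

Other known limitations: the ICC's sampling distribution is entirely
empirical (no analytic ICC confidence intervals); the guideline's
confidence level is fixed at 0.95 by the stored 5th percentile; MPE is
max-over-subjects per repetition (the aggregation is a documented choice —
the alternative, max over repetitions, is available from the raw draws);
and whether the original procedure randomized starts over
$\{0, \dots, m-1\}$ or over all slices is not stated in the source — the
former is implemented, because any other support leaves leading occupied
slices permanently unsampled.
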