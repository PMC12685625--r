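---
title: "Quantifying subacute ischemic edema as net water uptake: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subacute ischemic edema as net water uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nwuct)
```

## The measurement

Ischemic edema draws water into infarcted brain tissue, and water lowers CT
attenuation: roughly, each percent increase in tissue water content drops the
density of parenchyma by about one percent of its baseline Hounsfield value.
Net water uptake (NWU) exploits this by comparing the mean density of the
ischemic lesion, $D_{ischemic}$, with the mean density of its mirrored
counterpart in the unaffected hemisphere, $D_{pre\text{-}ischemic}$:

$$\mathrm{NWU}\,[\%] = \left(1 - \frac{D_{ischemic}}{D_{pre\text{-}ischemic}}\right)\times 100\%.$$

The contralateral mirror serves as a per-patient, per-scan estimate of what
the lesioned tissue would have measured without infarction, which makes NWU
robust to scanner calibration offsets and to global anatomical differences.
Only voxels with density between 20 and 80 HU enter either region, which
removes cerebrospinal fluid and air below and bone, calcification and fresh
blood above. Hemorrhagic transformation is handled by subtraction rather than
exclusion of the patient: outlined hemorrhage voxels are removed from the
lesion segmentation before anything else happens, because blood raises
density and would otherwise mask true water uptake.

The processing chain for one subject is:

1. register each follow-up scan (24 h, 1 week) to the baseline scan with an
   affine transform;
2. register the baseline scan to a left–right symmetric reference atlas and
   carry the follow-ups along by composing the two transforms (follow-ups are
   never registered to the atlas directly);
3. subtract hemorrhage from the lesion mask, mirror the result across the
   midsagittal plane $x = 0$ of the atlas;
4. remove from the mirrored reference any voxel inside the subject's own
   lesion mask (bilateral lesions), flagging `midline_overlap`, and
   `small_reference` when more than half the reference is lost;
5. apply the 20–80 HU band to both regions and form the ratio;
6. report $\Delta\mathrm{NWU} = \mathrm{NWU}_{FU} - \mathrm{NWU}_{BL}$ per
   follow-up interval.

### Where the densities are averaged

Mirroring must happen in atlas space, where the midplane is known. The
densities, however, can be averaged either over the atlas-resampled
intensities or over the original scans with the mirrored reference mapped
back through the inverse transform. `run_nwu_pipeline()` defaults to the
latter (`measure_space = "native"`): trilinear resampling mixes intensities
across the lesion boundary, and because the mixing always pulls lesional
voxels toward healthy density while the homogeneous reference is unaffected,
it biases NWU toward zero — on 3&nbsp;mm phantoms by roughly a percentage
point at 15% uptake. Averaging on the acquired grid moves only masks
(nearest-neighbour, no intensity mixing) and removes that bias class
entirely. `measure_space = "atlas"` reproduces the resample-then-measure
variant for comparison.

### Numerical conventions

* The HU band is inclusive at both ends, $[20, 80]$; "between" is ambiguous
  and an open interval would discard measurable parenchyma at the limits.
* The band is applied independently to the lesion and the mirrored reference,
  so neither side is treated preferentially.
* Negative NWU (lesion denser than reference) is reported as computed, never
  clamped: clamping would bias cohort means upward and hide QC problems.
* Masks always travel by nearest-neighbour interpolation and are checked to
  remain binary; intensities always travel by trilinear interpolation.
* Mirroring uses the fixed atlas midplane $x = 0$; no per-subject midline is
  estimated. On the atlas grid the x-coordinates are symmetric about zero, so
  reflection is an exact voxel permutation and a double reflection is the
  identity, bit for bit.

## Registration

The registration is an intensity-driven affine fit: a rigid (optionally full
affine: rigid + per-axis log-scale and shear) transform parameterized about
the fixed image centre, initialized by the intensity centre of mass,
optimized by Nelder–Mead over a coarse-to-fine schedule. Each pyramid level
smooths at full resolution (Gaussian, $\sigma = f/2$ voxels for decimation
factor $f$) *before* decimating; smoothing after decimation aliases the
sharp brain edge and visibly biases the optimum. The default metric is
normalized mutual information (32 bins), which tolerates the density change
inside the lesion between timepoints; mean squared difference is available
and behaves almost identically on same-modality CT.

The optimizer is deterministic: no stochastic metric sampling, a fixed
iteration schedule (defaults: factors 4 and 2, 400 and 300 iterations), and
a fixed simplex scaling of 5&nbsp;mm per translation and 0.05&nbsp;rad per
rotation parameter. Identical inputs and settings therefore always give
identical transforms. A Nelder–Mead simplex was chosen over a fixed-step
gradient scheme because the NMI surface is cheap to evaluate but awkward to
differentiate; determinism, the property that matters for reproducibility,
is preserved either way. Results within 0.01&nbsp;mm and $10^{-4}$ of the
identity are snapped to the exact identity, so scans already in the target
space pass through untouched, and resampling an image through the exact
identity onto its own grid returns the input array unchanged. A registration
that cannot improve on its centre-of-mass initialization at the finest level
raises an error carrying both metric values.

The shipped reference atlas is the noise-free mean phantom (a symmetric
brain ellipsoid, midplane at $x = 0$); any left–right symmetric template on
a grid symmetric in $x$ can be substituted.

## The statistical model

Regressing a change score on treatment alone is biased when groups differ at
baseline, so follow-up NWU is modelled with baseline NWU as a covariate,

$$\mathrm{NWU}_{FU} = B_0 + B_1\,\mathrm{NWU}_{BL} + B_2\,\mathrm{IVT} + \dots,$$

and results are reported on the algebraically equivalent change scale,

$$\Delta\mathrm{NWU} = B_0 + (B_1 - 1)\,\mathrm{NWU}_{BL} + B_2\,\mathrm{IVT} + \dots$$

Because the two outcomes differ only by a regressor, every coefficient,
standard error and p-value except the baseline term is identical between the
parameterizations, and the baseline coefficient differs by exactly one —
`fit_delta_model()` fits either outcome and reports the change-scale
coefficients in both cases (the baseline term's test is against $B_1 = 1$).
The multivariable adjustment set is age, sex, baseline NIHSS, baseline
ASPECTS, reperfusion status and onset-to-randomization time, entered
untransformed (per-year, per-point, per-minute coefficients). Reperfusion is
dichotomized from the ordinal eTICI grade at $\geq$2B (successful) or
$\geq$2C (excellent); the multivariable models always retain baseline NWU as
a covariate even though published regression tables conventionally omit that row, because
the change-score derivation requires it. A `baseline_adjusted = FALSE`
toggle gives the raw change-score fit for sensitivity analysis. Tests are
two-sided at $\alpha = 0.05$.

`run_table2()` assembles the full set: six univariable models (IVT,
eTICI$\geq$2B, eTICI$\geq$2C at both intervals) and four multivariable
models (adjustment set with each eTICI definition at both intervals).

### Missing data

Incomplete covariates are imputed by chained equations: each incomplete
variable is regressed on all others, with predictive mean matching (Bayesian
coefficient draw, five donors, type-1 matching) for continuous and
bounded-integer variables and a Bayesian logistic draw for binaries;
20 imputations, 10 sweeps each, chain $c$ seeded as `seed + c`. Twenty
imputations and PMM are conventional for trial-sized cohorts; ten sweeps is
double the usual default and comfortably past convergence for the mild
missingness rates simulated here. Estimates are pooled by Rubin's rules with
Barnard–Rubin small-sample degrees of freedom; when the between-imputation
variance vanishes the pooled result reduces exactly to the common
single-imputation fit. Descriptive tables report median (IQR) with
Mann–Whitney U tests for continuous variables and counts (%) with chi-square
tests for categorical ones, switching to Fisher's exact test whenever any
expected cell count is below 5 (the conventional rule; the switching
criterion is otherwise arbitrary).

## The synthetic generators

No public imaging or tabular data exist for this design, so both levels of
the analysis are validated against synthetic data with known ground truth.

**Phantoms** (`generate_phantom()`) are a single axially aligned brain
ellipsoid (semi-axes 62/78/52 mm) of parenchyma at $35 \pm 2$ HU in air
(−1000 HU), centred so the midsagittal plane is exactly $x = 0$; the lesion
is an ellipsoid (default semi-axes 20/17/15 mm, ~25 mL, a typical
large-vessel-occlusion infarct) whose follow-up density is reduced by the
factor $1 - u$; the injected truth is $\mathrm{NWU} = 100u$. Optional
extras: a hyperdense hemorrhage blob (default 70 HU), baseline-level uptake,
and a rigid/affine misalignment of the follow-up acquisition, rendered
analytically (the follow-up voxel at $w$ shows the anatomy at $T(w)$) so the
injected transform is exact and noise is drawn i.i.d. per scan. The default
grid is $50\times60\times44$ voxels at 3 mm — coarse enough that the full
registration pipeline runs in seconds per subject, fine enough that mask
discretization stays below the measurement tolerances. At these defaults
brain voxels stay within the 20–80 HU band essentially surely (the band
edges sit more than 7 SD from the mean), so the band removes nothing by
accident. What phantoms deliberately lack: skull and bone, CT artifacts
(beam hardening, streaks), anatomical texture, partial-volume edges and any
real-brain asymmetry. Passing phantom tests therefore demonstrates
correctness of the measurement chain, not robustness to real-scan nuisance
structure — in particular, real registration accuracy will be better
constrained by internal anatomy than the featureless ellipsoid is.

**Cohorts** (`simulate_cohort()`) draw covariates from parametric forms
matched to a thrombectomy-trial population: age truncated normal (median 71, IQR
59–76), male sex 63%, NIHSS and ASPECTS as bounded rounded normals matched
to IQRs 11–19 and 8–10, onset-to-randomization log-normal (median 92 min,
IQR 70–140), IVT 59%. Baseline NWU is log-normal with the median fixed at
4.3% and the log-scale spread fitted to the IQR 2.1–6.8 (a two-parameter
family cannot match median and both quartiles simultaneously; the median is
prioritized and the upper quartile lands near 7.7). The eTICI ordinal is
drawn to satisfy both marginal constraints $P(\geq 2B) = 0.83$ and
$P(\geq 2C) = 0.57$, splitting uniformly within $\{0, 1, 2A\}$ and
$\{2C, 3\}$. Follow-up NWU then obeys the linear model exactly before
residual noise ($\sigma = 7\%$ NWU, a deliberate design choice — published
cohort tables report only IQRs, not residual variances) and before MCAR deletion.
Default effects are adjusted effect sizes typical of such cohorts (reperfusion −4.6/−6.5,
IVT 1.3/−0.7, and the small covariate effects, per timepoint), with
$B_1 = 1$ and intercepts 0 and 10 chosen so the simulated medians rise from
~4% at baseline to ~9% at 24 h and ~15% at 1 week, matching the reported
trajectory. Every injected coefficient is returned in a truth record, so
estimation is validated by parameter recovery rather than by comparison to
unreproducible cohort tables.

## Validation problem sizes

The shipped test-suite exercises, among others: exactness of the NWU formula
on noise-free phantoms (relative error below $10^{-6}$); recovery of
injected uptake within 1.5 percentage points under HU noise and a
registration-corrected 5 mm / 3° misalignment across 20 seeds;
hemorrhage-exclusion behaviour (exclusion restores truth, inclusion biases
downward); exact agreement of `compute_nwu`, the Mann–Whitney U test and
Fisher's exact test with brute-force enumeration on inputs of size ≤ 8;
machine-precision equivalence of the two model parameterizations; recovery
of injected effect sizes within ±0.5 at $n = 5000$; and, for the imputation
path, that pooled estimates after 20% MCAR at $n = 1000$ fall inside the
complete-data 95% CI in at least 90 of 100 replicates. These sizes were
chosen as the smallest at which the respective Monte-Carlo error is well
below the tolerance being checked.

## Known limitations

* The atlas is synthetic; real deployments would substitute a population CT
  template satisfying the same symmetry contract.
* Affine registration only — no deformable refinement, no skull stripping,
  no slice-wise handling of gantry tilt.
* The phantom's homogeneous hemispheres make the mirrored reference
  forgiving: reference-placement errors that would matter in textured brains
  are invisible here (this is why registration accuracy is additionally
  checked directly, via recovered transforms and mask Dice).
* MICE conditional models are linear/logistic only; interactions and
  non-linearities in the missingness model are out of scope.
* NWU is a densitometric marker; volumetric (mL) edema measures and any link
  to functional outcome are deliberately not modelled.
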