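# nwuct — densitometric net water uptake from serial non-contrast head CT

Cerebral edema after ischemic stroke draws water into infarcted tissue and
lowers its CT attenuation. **Net water uptake (NWU)** turns that density
drop into a quantitative, per-patient edema marker by comparing the mean
Hounsfield density of the lesion with that of its mirrored contralateral
counterpart:

```
NWU [%] = (1 − D_ischemic / D_pre-ischemic) × 100
```

where `D_ischemic` is the mean density over the (non-hemorrhagic,
20–80 HU-banded) lesion and `D_pre-ischemic` the mean density over the same
region mirrored across the midsagittal plane into the unaffected hemisphere.
Edema *progression* is `ΔNWU = NWU_FU − NWU_BL` between baseline and a
follow-up scan (24 h, 1 week).

The package is aimed at stroke-imaging researchers who want a tested,
reproducible NWU pipeline plus the accompanying cohort analysis:

* **Measurement** — affine registration of serial scans into a symmetric
  atlas space (follow-up → baseline → atlas, composed), midsagittal
  mirroring of lesion segmentations, hemorrhage subtraction, 20–80 HU
  banding, the NWU ratio and ΔNWU, with QC flags for bilateral lesions.
* **Inference** — the baseline-adjusted change-score regression
  `ΔNWU = B0 + (B1 − 1)·NWU_BL + B2·exposure + …` (exposures: IVT
  thrombolysis, successful reperfusion eTICI ≥ 2B, excellent reperfusion
  eTICI ≥ 2C; univariable and multivariable with age, sex, NIHSS, ASPECTS
  and onset-to-randomization time), chained-equations imputation with
  Rubin pooling, and trial-style descriptive tables.
* **Synthetic ground truth** — head-CT phantoms with known injected water
  uptake, hemorrhage, noise and inter-scan misalignment, and a cohort
  simulator with a known regression structure, so every stage is validated
  by parameter recovery.

NIfTI volumes are read and written via RNifti; tabular inputs and outputs
are CSV with JSON sidecars. A thin CLI (`inst/cli/nwuct`) exposes
`simulate-phantom`, `simulate-cohort`, `align`, `compute-nwu`, `fit-models`
and `run-all`.

## Worked example

Measure NWU on a phantom with 15% injected uptake, 2 HU noise and a
misaligned follow-up acquisition that the registration must correct:

```r
library(nwuct)

cfg <- phantom_config(true_uptake = 0.15, brain_hu_sd = 2,
                      misalignment = params_to_affine(translation = c(4, -2, 1),
                                                      angles = c(0.02, 0, 0.03)),
                      seed = 7)
ph    <- generate_phantom(cfg)
atlas <- default_atlas()
res <- run_nwu_pipeline(ph$baseline, list(`24h` = ph$followup),
                        list(baseline = ph$seg_baseline, `24h` = ph$seg_followup),
                        atlas, settings = reg_settings(dof = "rigid"))
res$measurements[["24h"]]
#> <nwu_measurement> phantom/24h: NWU 14.89% (D_isch 29.72, D_pre 34.92; 792/789 voxels)
res$delta
#>   subject_id      interval    value
#> 1    phantom baseline->24h 14.90812
```

The injected truth was 15%: the lesion measures 29.72 HU against a mirrored
reference of 34.92 HU, and the recovered NWU of 14.89% is within the noise
floor of the 790-voxel ROIs. Because this phantom has no baseline uptake,
ΔNWU over the interval equals the follow-up NWU.

Simulate a trial-like cohort (n = 115, 10% missing covariates), impute and
fit the full univariable + multivariable model set:

```r
sim  <- simulate_cohort(cohort_sim_config(n_patients = 115, missing_rate = 0.1, seed = 11))
imps <- mice_impute(sim$cohort, m = 20, seed = 11)
tab2 <- run_table2(imps)
subset(tab2$results, model == "multi_etici2b_24h" & term == "etici2b")
#>                model interval exposure adjusted    term estimate    se ci_lo  ci_hi      p significant
#> 13 multi_etici2b_24h      24h  etici2b     TRUE etici2b   -3.438 1.668 -6.75 -0.129 0.0419        TRUE
```

At this cohort size the pooled adjusted reperfusion effect (−3.4 percentage
points of ΔNWU, 95% CI −6.75 to −0.13) is a noisy but sign-correct estimate
of the injected −4.6; `sim$truth` carries every injected coefficient for
systematic recovery checks.

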