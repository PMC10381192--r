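# segstab

Radiomic feature stability under simulated segmentation variability.

## What this is for

Radiomic features — first-order and texture statistics of the image
intensities inside a region of interest — are only useful as imaging
biomarkers if they survive the contouring differences between human
annotators. Collecting multiple expert segmentations per study is usually
infeasible. `segstab` replaces the annotators with an *in silico* contour
generator: it perturbs a single ground-truth 3D mask under bounded affine
transformations that mimic rater behaviour, runs the perturbed contours
through a full radiomics pipeline, and scores every feature's stability
with the intraclass correlation coefficient. The intended users are
quantitative-imaging researchers screening features (here modelled on
whole-prostate multi-parametric MRI: T2w, diffusion-derived ADC, and
dynamic contrast-enhanced subtraction maps) before predictive modelling.

## The method in brief

For each of k synthetic contours (default 15) the mask is perturbed:

* **in-plane** — per axial slice, the contour's bounding-box width and
  height change by dw, dh ~ U(−2.7, 2.7) mm and the slice rotates by
  α ~ U(−5°, 5°) about its centroid;
* **out-of-plane** — the superior and inferior boundary-slice choices shift
  independently by δ ∈ {−1, 0, +1} slices;
* under **random** bias every slice draws independently; under
  **systematic** bias the signs of dw, dh, α are fixed per contour
  (a consistently "abundant" or "restrictive" rater).

Contour fidelity is measured by Dice = 2|A∩B|/(|A|+|B|). After
preprocessing (ADC fit, wash-in/wash-out subtraction maps split at 90 s,
resampling to 2 mm isotropic, ROI- or population-based normalization to
mean 300 / sd 100 with 3σ clipping), 1224 features are extracted per
image/mask pair: 17 filter variants (original, Laplacian-of-Gaussian
σ = 2–5 mm, 8 wavelet decompositions, 4 intensity remappings) × 72 features
(18 first-order, 22 GLCM, 16 GLRLM, 16 GLSZM) at fixed bin width 5.
Per feature, the n subjects × k raters matrix yields

    ICC(1,1) = (MSB − MSW) / (MSB + (k−1)·MSW)

with an F-based 95% confidence interval; a feature is **stable** when the
CI lower bound exceeds 0.90, and **robust** when it does so in two
datasets. A built-in phantom generator (irregular prostate-scale ellipsoids
with textured intensities, mono-exponential DWI and gamma-variate DCE
enhancement) makes every stage runnable and testable without patient data.

## Worked example

```r
library(segstab)

spec <- phantom_spec(seed = 42)                     # prostate-scale phantom
mask <- generate_phantom_mask(spec, sequence = "adc")
mask
#> <mask3d> 50x44x19 voxels, spacing 1.25x1.25x3 mm, origin -30.62, -26.88, -27 mm
#>   foreground: 8495 voxels (39820.3 mm^3)

cfg <- augmentation_config(scenario = "in_out_plane", bias = "systematic",
                           seed = 42)
set <- augment(mask, cfg)                           # 15 synthetic raters
set
#> <augmented_mask_set> 15 contours, scenario in_out_plane / bias systematic
#>   dice vs ground truth: mean 0.951, range [0.935, 0.960]
```

The mean Dice of ~0.95 says the simulated raters disagree with the ground
truth about as much as human annotators disagree with each other on
prostate MRI. Feeding a cohort of such sets through the pipeline
(`run_experiment()`, or stage by stage: `resample_image()`,
`normalize_roi()`, `extract_feature_table()`, `icc_table()`) produces a
per-feature stability table; `assess_robustness()`,
`select_best_filters()` and `summarize_fractions()` then compare two
cohorts and summarise stable/robust fractions per feature family, in the
Original and Best-Filtered configurations.

```r
icc_1_1(matrix(rep(1:8, 4), 8, 4) + matrix(rnorm(32, sd = 0.2), 8, 4))
#> <icc_result> ICC(1,1) = 0.9932, 95% CI [0.9805, 0.9984] (n=8, k=4)
```

A command-line interface wrapping each stage (`phantom`, `augment`,
`preprocess`, `extract`, `stability`, `report`, `run`) lives at
`inst/cli/segstab.R`; volumes are exchanged as NIfTI, tables as CSV,
configuration and logs as JSON.

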