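# focidose

Automated gamma-H2AX focus scoring and radiation biodosimetry, at desk
scale, in R.

Ionising radiation produces DNA double-strand breaks; each break recruits
phosphorylated histone H2AX (gamma-H2AX), visible as a green punctum — a
*focus* — in immunostained blood cells under confocal microscopy. Because
the mean number of foci per mononuclear cell (MNC) rises linearly with
absorbed dose, `y = a·x + b`, focus counts can be turned into dose
estimates: fit that calibration line on samples of known dose, then invert
it, `x̂ = (y − b) / a`, for an unknown sample. That workflow — radiation
*biodosimetry* — is what this package implements end to end for anyone who
wants a fully controlled, reproducible test bed for automated focus
scoring:

* a **simulator** of 3-channel confocal z-stacks (nucleus/DAPI in blue,
  gamma-H2AX in green, CD45 surface marker in red; 5 sections, 0.6 µm
  apart) with planted cells, polymorphonuclear distractors, Poisson focus
  counts with mean `λ(D) = 1.996·D + 0.769`, and exact ground-truth boxes
  and counts;
* the standard **preprocessing** chain (histogram matching, 3×3 median,
  Gaussian blur);
* **two-stage detection** — stage 1 finds and crops MNCs
  (Otsu + morphology + shape filters + a CD45 ring gate), stage 2 counts
  foci in the green channel of each crop (top-hat + multi-scale
  Laplacian-of-Gaussian + non-maximum suppression) — behind a pluggable
  detector contract with a deterministic classical reference backend;
* **evaluation**: IoU matching of detections to ground truth, pooled
  precision / recall / F1 per dose group;
* **biodosimetry**: OLS calibration fit with standard errors, dose
  inversion with extrapolation flags, per-group and average absolute dose
  error (MAD, in Gy);
* **agreement statistics**: two-way random-effects absolute-agreement ICC
  (single and mean-of-k, with 95% CIs) and Bland–Altman limits of
  agreement.

## Worked example

```r
library(focidose)

## one simulated frame at 2 Gy with exact ground truth
sc <- renderScene(2, SceneConfig(), seed = 42, nCells = 2, imageId = "demo")
trueCounts(sc)
#> [1] 2 7

## two-stage counting on its 5-slice stack
counts <- countFociTwoStage(gtStack(sc),
                            preParams = preprocessParams(gaussianSdPx = 1.25))
counts[, c("cell_id", "dose_gy", "n_slices", "cell_count")]
#>    cell_id dose_gy n_slices cell_count
#> 1 demo_c01       2        5        1.8
#> 2 demo_c02       2        5        6.6

## full pipeline: calibrate on 0/1/2/4 Gy, estimate an unseen 0/2/4/6 Gy set
cfg <- runConfig(scene = SceneConfig(seed = 1L), unseenCellsPerDose = 20L)
cal <- buildCalibration(cfg)          # 100 cells/dose, a few minutes
sprintf("y = %.3f x + %.3f (R^2 = %.3f)",
        calSlope(cal$curve), calIntercept(cal$curve), calRSquared(cal$curve))
#> [1] "y = 1.851 x + 0.756 (R^2 = 0.993)"

tri <- triageEstimate(cfg, cal$curve, preParams = cal$preParams)
tri$estimates
#>   actual_dose_gy n_cells mean_foci estimated_dose_gy    mad_gy extrapolated
#> 1              0      20      0.48        -0.1489316 0.1489316         TRUE
#> 2              2      20      4.66         2.1099000 0.1099000        FALSE
#> 3              4      20      7.95         3.8877841 0.1122159        FALSE
#> 4              6      20     11.25         5.6710721 0.3289279         TRUE
tri$averageMAD
#> [1] 0.1749938
```

Reading the output: the fitted slope (1.85 foci/Gy) sits below the
generating 1.996 because overlapping foci merge and off-plane foci dim —
but the *same* bias affects calibration and unseen data, so inverted doses
land within a few tenths of a Gy of truth; the 0 Gy group legitimately
inverts slightly negative (its mean count fell below the fitted
background intercept), and the 6 Gy group is flagged as an extrapolation
beyond the 0–4 Gy calibration range.

The agreement tools compare two scorers of the same cells:

```r
human <- c(1, 3, 5, 7, 9, 11); machine <- c(1, 2, 5, 6, 9, 12)
iccTwoWay(cbind(human, machine), unit = "mean_k")$icc
#> [1] 0.9919485
blandAltman(human, machine)[c("mean_diff", "loa_low", "loa_high")]
#> $mean_diff [1] 0.1666667  $loa_low [1] -1.308768  $loa_high [1] 1.642101
```

## Layout

| Where | What |
|---|---|
| `R/synthetic.R` | scene simulator and dataset generator |
| `R/imaging_io.R` | TIFF z-stack + JSON sidecar, annotations CSV, scenes JSON |
| `R/preprocess.R` | histogram matching, median/Gaussian denoising |
| `R/detect_mnc.R`, `R/detect_foci.R` | the two reference detector backends |
| `R/two_stage.R` | crop, count, link across z, aggregate per cell |
| `R/metrics.R` | IoU, matching, precision/recall/F1 per dose |
| `R/biodosimetry.R` | calibration fit, dose inversion, MAD |
| `R/agreement.R` | ICC, Bland–Altman |
| `R/workflow.R` | end-to-end orchestration |
| `vignettes/methods.Rmd` | models, parameters, design decisions, limits |
| `inst/scripts/focidose` | thin command-line wrapper over the above |
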