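---
title: "Simulated gamma-H2AX focus scoring and dose estimation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated gamma-H2AX focus scoring and dose estimation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focidose)
```

## The problem

After exposure to ionising radiation, DNA double-strand breaks recruit
phosphorylated histone H2AX (gamma-H2AX), visible under confocal
fluorescence microscopy as bright green puncta ("foci") inside the
nucleus. The mean number of foci per blood mononuclear cell (MNC) grows
linearly with absorbed dose over the first few Gray, which makes focus
counting a practical biodosimeter: fit a calibration line
$y = a x + b$ (mean foci per cell $y$ against dose $x$ in Gy) on samples
of known dose, then invert it, $\hat x = (y - b)/a$, to estimate the dose
an unknown sample received.

Scoring foci by eye is slow and observer-dependent, so automated scoring
pipelines replace the human with a two-stage detector: stage 1 localises
intact MNCs in the full frame (DAPI-positive nucleus with a bright CD45
surface ring, distinguishing them from polymorphonuclear granulocytes),
crops each one, and stage 2 counts the foci in the green channel of each
crop. `focidose` implements that whole chain at desk scale — simulator,
preprocessing, both detection stages behind a pluggable contract,
bounding-box evaluation metrics, calibration and inversion, and the
agreement statistics (ICC, Bland–Altman) used to compare an automated
scorer against manual counts.

## The synthetic-data model

No microscopy images ship with the package; the simulator
(`SceneConfig()`, `renderScene()`, `generateDataset()`) *is* the data
source, and its defaults define the study conditions the rest of the
package is tested under.

**Counts.** The per-cell focus count at dose $D$ is Poisson with mean
$\lambda(D) = a\,D + b$, defaults $a = 1.996$ foci/Gy and $b = 0.769$
foci. A Poisson count law is the standard assumption for
radiation-induced foci — particle tracks arrive independently — and gives
the tests an exact mean–variance law to check against. The working dose
range is 0–4 Gy for calibration with a 6 Gy group exercised as an
extrapolation case.

**Geometry.** Frames are 256 × 256 px by default — a 4× scaled-down
version of the 1024 × 1024 acquisition geometry the package emulates —
with 5 optical sections 0.6 µm apart. All length parameters are stated at
this working scale and scale proportionally; no physical pixel size is
asserted (the simulator is proportional, not calibrated to a microscope).
Each frame holds up to 4 non-overlapping cells: nuclei are soft-edged
ellipses (radius 18–30 px) in the blue channel; MNCs get a bright CD45
ring in red; polymorphonuclear distractors (expected `pmnFraction = 0.2`
per cell) get a 2–3-lobed nucleus and a dim ring and carry no
ground-truth cell box. Foci are 2-D Gaussians (sigma 1.2–2.0 px,
amplitude 0.6–0.9) planted inside the nucleus by dart-throwing with a
preferred minimum separation of 8 px; when a crowded nucleus cannot honour
it, the separation is halved until placement succeeds, which is exactly
how the overlapping-foci regime of high doses arises. Each focus has a
continuous focal depth: its amplitude falls off as a Gaussian across
slices (sd 2 slices) and its footprint blurs slightly off-plane. A
per-scene multiplicative gain (0.9–1.1) emulates staining/imaging batch
variation, additive Gaussian noise (sd 0.01 of the intensity range) is
applied per pixel, and intensities are clipped to [0, 1] and quantised to
the 16-bit grid used on disk.

**Ground truth.** Cell boxes are the nucleus extent plus the CD45 ring;
focus boxes are squares of side $2\lceil 2\sigma \rceil$ centred on each
planted peak. Counts, boxes and doses are exact by construction, so
detector evaluation needs no annotation step.

**What the simulator does not emulate:** a physically realistic confocal
point-spread function, photobleaching, autofluorescence texture,
out-of-focus haze from neighbouring cells, or real inter-donor
variability. Passing tests therefore demonstrate that the pipeline's
logic is correct under controlled conditions, not that the classical
reference detector would match a trained network on real micrographs.

## Preprocessing

The normalisation chain (`preprocessPipeline()`) is histogram matching to
a reference image (optional), a 3 × 3 median filter, then a Gaussian blur
— in that order, each stage shape-preserving and deterministic, with
symmetric (edge-repeating) border handling. The Gaussian sd is 5 px at
full 1024² resolution; `runConfig()` scales it by `min(imageSize)/1024`
(1.25 px at the working scale) so the blur stays proportional to the
geometry. The chain is applied exactly once per image, enforced by a
provenance flag on the image object, because blurring twice is not the
same operation.

**Why the workflow default skips histogram matching.** Rank-based
histogram specification removes batch-to-batch intensity variation, and
`histogramMatch()` implements it (rank-exact, monotone-invariant,
constant-reference-safe). But matching the *green* channel of every frame
to one fixed reference frame forces every frame's intensity distribution
to the reference's focus abundance: high-dose frames get their focus
pixels compressed downwards, 0 Gy frames get their brightest noise pixels
stretched up to focus level. A learned detector can tolerate that; the
classical intensity-based reference backend cannot (we measured overall
focus recall collapsing roughly five-fold with matching enabled). The
end-to-end default is therefore median + Gaussian only, with adaptive
thresholds (Otsu for nuclei, relative blob responses for foci) absorbing
the simulated gain variation; matching remains one parameter away
(`preprocessParams(referenceImage = ...)`) for backends that want it.

## The two-stage reference detector

The detector contract is a plain function: image in, confidence-sorted
detection table out, deterministic, boxes in bounds, confidences in
[0, 1]. The shipped backends are classical and fully deterministic; a
learned detector with the same signature can be swapped into
`countFociTwoStage()` without touching anything downstream.

**Stage 1, MNCs (`detectMNC()`).** Otsu threshold on the blue channel →
3 × 3 morphological opening → connected components → filters: area within
[350, 7000] px², solidity ≥ 0.85 (rejects multi-lobed/irregular nuclei),
border exclusion (incomplete cells), and a CD45 gate requiring mean red
intensity ≥ 0.2 in a 4 px ring around the nucleus (the double-positive
criterion; the simulated distractors sit well below it). Confidence is
the product of a normalised area score, the solidity and a normalised
ring score.

**Stage 2, foci (`detectFoci()`).** White top-hat (disc radius 6 px)
removes the diffuse nuclear background → scale-normalised
Laplacian-of-Gaussian responses at 4 log-spaced sigmas in [1.6, 3.2] px
(the focus footprint *after* the preprocessing blur) → 3 × 3 local maxima
→ keep peaks ≥ 0.2 × the strongest response in the crop, with an absolute
floor of 0.04 so that crops containing no focus at all (common at 0 Gy,
where the background rate is 0.769 foci/cell) do not promote noise peaks
— a purely relative threshold has no meaning in an empty crop → greedy
non-maximum suppression at IoU 0.3. Two foci closer than about one sigma
merge into a single response maximum; this undercounting at high dose is
a documented limitation of 2-D focus counting, is reproduced on demand by
the simulator's separation relaxation, and is largely absorbed by the
calibration (next section).

**z-aggregation and linking.** The acquisition produces 5 sections per
cell but results are reported per cell, so per-slice detections are
linked across z by box-centre proximity (within half a typical cell-box
side) and counts aggregated; `mean` over the slices a cell was seen in is
the default, with `max` and `best_slice` (the section with the largest
total green signal) available. The choice shifts the calibration slope
but, because the same rule is used for calibration and unseen data, has
little effect on estimated doses.

## Evaluation, calibration, agreement

**Matching.** Detections are matched to ground truth greedily in
confidence order, each claiming the unmatched truth of highest IoU
≥ 0.5 (half-open box convention, so area arithmetic is exact). Greedy
matching agrees with the exhaustive maximum-assignment oracle on all
tested random instances. Precision, recall and F1 are computed from
pooled TP/FP/FN per dose group plus a micro-averaged "overall" row —
pooling, not macro-averaging, because group sizes differ; undefined
metrics are `NA`, never silently 0. Printed tables round half-up
(`roundHalfUp()`), the convention under which the package reproduces its
reference worked examples.

**Calibration.** `fitCalibration()` is unweighted OLS (at least 3 dose
points), returning slope, intercept, their standard errors and $R^2$;
`estimateDose()` inverts the line, preserves negative estimates (a
count below the background intercept legitimately inverts below 0 Gy;
truncation at 0 is an option, not the default) and flags estimates
outside the calibration dose range as extrapolated. Dose error is
reported as the absolute difference $|\hat x - x|$ per group and its
average.

**Agreement.** `iccTwoWay()` computes the two-way random-effects,
absolute-agreement intraclass correlation from the ANOVA mean squares,
both single-rating and mean-of-k forms, with F-based 95% confidence
intervals (the mean-rating interval is the single-rating interval pushed
through the Spearman–Brown step-up; the two-way mixed-effects
absolute-agreement single-rating formula coincides with the
random-effects one, so one function covers both). The mean-of-k ≥ single
ordering holds for non-negative estimates; a pure-noise table can invert
it, which the tests respect. `blandAltman()` summarises paired
differences (oriented human − automated when comparing scorers) with
mean, sample SD and mean ± 1.96 SD limits of agreement.

## Numerical and design choices

* Boxes are 0-based half-open; slice indices in the R API are 1-based.
* Stacks are stored at 16-bit depth; all processing is double precision
  on [0, 1]; simulator output is pre-quantised to the 16-bit grid so
  write/read cycles are bit-exact.
* Median filtering uses a 19-exchange median network for the 3 × 3 case
  and symmetric padding everywhere; the Gaussian kernel is sampled to
  ± 4 sd and renormalised.
* All randomness flows from a single integer seed; per-scene seeds are
  derived deterministically, and the unseen dataset uses a seed stream
  disjoint from the calibration stream.
* Problem sizes used by the shipped end-to-end runs: calibration at
  0/1/2/4 Gy with 100 cells per dose and an unseen set at 0/2/4/6 Gy
  with 20 cells per group, on 256² frames with 5 sections — the package's
  desk-scale working point, at which a full run fits comfortably in a few
  minutes on one core. At this working point the pipeline's average
  absolute dose error is a few tenths of a Gy.

## Known limitations

* The classical reference backend is tuned to the simulator's working
  scale; real micrographs would need parameter re-scaling and would
  likely favour a learned stage-2 backend (the contract exists for that).
* Overlapping foci merge; counts at 4 Gy and above are biased low before
  calibration absorbs the consistent part of the bias.
* The calibration is strictly linear; linear-quadratic dose response,
  inverse-regression confidence limits on estimated dose, and
  time-post-exposure decay of the focus signal are out of scope.
* Detection metrics reported per slice understate per-cell recall when a
  focus is sharp in one section and dim in others; they are diagnostics,
  not the pipeline's figure of merit (the dose error is).
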