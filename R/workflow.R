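#' End-to-end run configuration
#'
#' Bundles everything one reproducible biodosimetry run needs: the
#' simulator configuration for the calibration dataset, the unseen dose
#' groups to triage, the preprocessing and detector parameters, the
#' z-aggregation rule and matching threshold, and the seed. By default the
#' Gaussian preprocessing sd is scaled from its full-resolution value of
#' 5 px by `min(imageSizePx) / 1024`, keeping the normalisation chain
#' proportional to the simulated geometry (1.25 px at the 256 x 256
#' working scale).
#'
#' @param scene a [SceneConfig-class] describing the calibration dataset
#'   (doses, cells per dose, geometry, seed).
#' @param unseenDosesGy dose groups of the unseen (triage) dataset.
#' @param unseenCellsPerDose cells per unseen dose group.
#' @param preParams [preprocessParams()]; `NULL` for the scaled default
#'   (3 x 3 median then scaled Gaussian, no histogram matching — see the
#'   methods vignette for why the classical backend keeps the intensity
#'   scale).
#' @param mncPar stage-1 [mncParams()].
#' @param fociPar stage-2 [fociParams()].
#' @param zAgg per-cell z aggregation (see [countFociTwoStage()]).
#' @param iouMin detection-matching IoU threshold for the metrics report.
#' @param outputDir optional directory for curve / counts / metrics /
#'   run-log artifacts.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(scene = SceneConfig(),
                      unseenDosesGy = c(0, 2, 4, 6),
                      unseenCellsPerDose = 20L,
                      preParams = NULL,
                      mncPar = mncParams(),
                      fociPar = fociParams(),
                      zAgg = "mean",
                      iouMin = 0.5,
                      outputDir = NULL) {
  stopifnot(is(scene, "SceneConfig"))
  if (any(unseenDosesGy < 0)) stop("unseen doses must be non-negative",
                                   call. = FALSE)
  structure(list(scene = scene, unseenDosesGy = as.numeric(unseenDosesGy),
                 unseenCellsPerDose = as.integer(unseenCellsPerDose),
                 preParams = preParams, mncPar = mncPar, fociPar = fociPar,
                 zAgg = zAgg, iouMin = iouMin, outputDir = outputDir),
            class = "RunConfig")
}

# Scaled default preprocessing for a scene geometry (no reference yet).
.scaledPreParams <- function(scene) {
  preprocessParams(referenceImage = NULL, medianKernelPx = 3L,
                   gaussianSdPx = max(0.5, 5 * min(scene@imageSizePx) / 1024))
}

# Render all frames of one dose group and return per-cell counts plus a
# light per-frame detection-metrics pass on the middle slice.
.processDoseGroup <- function(dose, nCellsTotal, cfg, pre, seedTag,
                              withMetrics = TRUE) {
  scene <- cfg$scene
  counts <- NULL
  mncMatches <- list(); fociMatches <- list()
  trueCountSum <- 0L
  left <- nCellsTotal; si <- 0L
  while (left > 0L) {
    si <- si + 1L
    nc_img <- min(scene@cellsPerImage, left)
    left <- left - nc_img
    sc <- renderScene(dose, scene,
                      seed = .childSeed(scene@seed, seedTag + si),
                      nCells = nc_img,
                      imageId = sprintf("g%g_s%03d", dose, si))
    trueCountSum <- trueCountSum + sum(sc@trueCounts)
    cc <- countFociTwoStage(sc@stack, preParams = pre,
                            mncPar = cfg$mncPar, fociPar = cfg$fociPar,
                            zAgg = cfg$zAgg)
    counts <- rbind(counts, cc)
    if (withMetrics) {
      zmid <- (nSlices(sc@stack) + 1L) %/% 2L
      img <- preprocessPipeline(mergeRGB(sc@stack, zmid), pre)
      md <- detectMNC(img, cfg$mncPar)
      mncMatches[[length(mncMatches) + 1L]] <-
        matchDetections(md, sc@mncBoxes, cfg$iouMin)
      for (ci in seq_len(nrow(sc@mncBoxes))) {
        gt <- sc@fociBoxes[[ci]]
        b <- sc@mncBoxes[ci, ]
        green <- pixels(img)[(b$y_min + 1):b$y_max,
                             (b$x_min + 1):b$x_max, 2L]
        fd <- detectFoci(green, cfg$fociPar)
        gt_local <- data.frame(x_min = gt$x_min - b$x_min,
                               y_min = gt$y_min - b$y_min,
                               x_max = gt$x_max - b$x_min,
                               y_max = gt$y_max - b$y_min)
        fociMatches[[length(fociMatches) + 1L]] <-
          matchDetections(fd, gt_local, cfg$iouMin)
      }
    }
  }
  list(counts = counts, mncMatches = mncMatches,
       fociMatches = fociMatches, trueCountSum = trueCountSum)
}

#' Build a dose-response calibration from simulated data
#'
#' Runs the full chain on the configured calibration dataset: render each
#' dose group, preprocess every slice, run two-stage counting, average counts per dose,
#' and fit the linear calibration by OLS. Also reports per-dose
#' mononuclear-cell and focus detection metrics measured on the middle
#' slice of every frame against the planted ground truth. Deterministic
#' for a fixed configuration: all scene seeds derive from
#' `cfg$scene@seed`.
#'
#' @param cfg a [runConfig()] list.
#' @return A list with `curve` ([CalibrationCurve-class]), `points`
#'   (data.frame dose / mean foci / n cells), `counts` (per-cell table),
#'   `mncMetrics` and `fociMetrics` (from [evaluateByDose()]), and `log`
#'   (seed and parameters). Artifacts are written to `cfg$outputDir` when
#'   set.
#' @export
buildCalibration <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  scene <- cfg$scene
  pre <- cfg$preParams
  if (is.null(pre)) pre <- .scaledPreParams(scene)
  allCounts <- NULL
  mncM <- list(); mncG <- character(0)
  fociM <- list(); fociG <- character(0)
  points <- NULL
  for (di in seq_along(scene@dosesGy)) {
    d <- scene@dosesGy[di]
    res <- .processDoseGroup(d, scene@cellsPerDose, cfg, pre,
                             seedTag = di * 10000L)
    if (is.null(res$counts) || nrow(res$counts) == 0L)
      stop(sprintf("calibration stage: no cells detected at %g Gy", d),
           call. = FALSE)
    allCounts <- rbind(allCounts, res$counts)
    points <- rbind(points, data.frame(
      dose_gy = d, mean_foci = mean(res$counts$cell_count),
      n_cells = nrow(res$counts)))
    mncM <- c(mncM, res$mncMatches)
    mncG <- c(mncG, rep(as.character(d), length(res$mncMatches)))
    fociM <- c(fociM, res$fociMatches)
    fociG <- c(fociG, rep(as.character(d), length(res$fociMatches)))
  }
  curve <- tryCatch(fitCalibration(points), error = function(e)
    stop(sprintf("calibration stage: %s", conditionMessage(e)),
         call. = FALSE))
  out <- list(
    curve = curve, points = points, counts = allCounts,
    mncMetrics = evaluateByDose(mncM, mncG),
    fociMetrics = evaluateByDose(fociM, fociG),
    preParams = pre,
    log = list(seed = scene@seed, doses_gy = scene@dosesGy,
               cells_per_dose = scene@cellsPerDose, z_agg = cfg$zAgg,
               iou_min = cfg$iouMin,
               gaussian_sd_px = pre$gaussianSdPx,
               median_kernel_px = pre$medianKernelPx,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
    writeCalibration(curve, file.path(cfg$outputDir, "curve.json"))
    utils::write.csv(out$points, file.path(cfg$outputDir, "points.csv"),
                     row.names = FALSE)
    cdf <- allCounts[, setdiff(names(allCounts), "per_slice")]
    utils::write.csv(cdf, file.path(cfg$outputDir, "counts.csv"),
                     row.names = FALSE)
    utils::write.csv(out$fociMetrics,
                     file.path(cfg$outputDir, "foci_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out$log, file.path(cfg$outputDir, "runlog.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Estimate doses for an unseen dataset
#'
#' The triage-facing tail of the pipeline: simulate the configured unseen
#' dose groups (seeds independent of the calibration stream), run the same
#' two-stage counting, convert each group's mean focus count into a dose
#' through the supplied calibration curve, and report per-group and
#' average absolute errors. Groups whose estimate falls outside the
#' curve's calibration range are flagged as extrapolated.
#'
#' @param cfg a [runConfig()] list.
#' @param curve a [CalibrationCurve-class], typically from
#'   [buildCalibration()].
#' @param preParams preprocessing to reuse; pass the `preParams` element
#'   of the [buildCalibration()] result so the unseen data are normalised
#'   identically (default: rebuild the scaled chain).
#' @return A list with `estimates` (data.frame: dose group, n cells, mean
#'   foci, estimated dose, MAD, extrapolated flag), `averageMAD` (Gy), and
#'   `counts` (per-cell table).
#' @export
triageEstimate <- function(cfg, curve, preParams = NULL) {
  stopifnot(inherits(cfg, "RunConfig"), is(curve, "CalibrationCurve"))
  pre <- preParams
  if (is.null(pre)) pre <- .scaledPreParams(cfg$scene)
  estimates <- NULL
  allCounts <- NULL
  for (di in seq_along(cfg$unseenDosesGy)) {
    d <- cfg$unseenDosesGy[di]
    res <- .processDoseGroup(d, cfg$unseenCellsPerDose, cfg, pre,
                             seedTag = 900000L + di * 1000L,
                             withMetrics = FALSE)
    if (is.null(res$counts) || nrow(res$counts) == 0L)
      stop(sprintf("triage stage: no cells detected at %g Gy", d),
           call. = FALSE)
    allCounts <- rbind(allCounts, res$counts)
    mf <- mean(res$counts$cell_count)
    est <- estimateDose(curve, mf, actualDoseGy = d)
    estimates <- rbind(estimates, data.frame(
      actual_dose_gy = d, n_cells = nrow(res$counts), mean_foci = mf,
      estimated_dose_gy = est$estimated_dose_gy, mad_gy = est$mad_gy,
      extrapolated = est$extrapolated))
  }
  avg <- averageMAD(estimates$mad_gy)
  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(estimates,
                     file.path(cfg$outputDir, "estimates.csv"),
                     row.names = FALSE)
  }
  list(estimates = estimates, averageMAD = avg, counts = allCounts)
}
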