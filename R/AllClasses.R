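#' @import methods
NULL

.CANONICAL_CHANNELS <- c("nucleus", "foci", "cd45")

#' ImageStack: a multi-channel confocal z-stack
#'
#' Container for a three-channel fluorescence z-stack (nucleus/DAPI,
#' gamma-H2AX foci, CD45 surface marker) with pixel geometry metadata and an
#' optional absorbed-dose label. Pixel intensities are stored as doubles on
#' the \[0, 1\] scale and quantised to the 16-bit grid on disk, the common
#' export depth for confocal TIFFs.
#'
#' @slot pixels 4-d numeric array indexed (channel, z, row, col); finite,
#'   non-negative.
#' @slot channelNames ordered channel labels; the canonical triple is
#'   \code{c("nucleus", "foci", "cd45")}.
#' @slot pixelSizeUm microns per pixel (> 0).
#' @slot zStepUm spacing between optical sections in microns (>= 0).
#' @slot doseGy absorbed dose label in Gy, or \code{NA} when unknown.
#' @slot imageId identifier used in annotation tables and manifests.
#'
#' @seealso [ImageStack()] for the constructor, [readStack()],
#'   [writeStack()], [mergeRGB()].
#' @export
setClass("ImageStack",
  representation(
    pixels = "array",
    channelNames = "character",
    pixelSizeUm = "numeric",
    zStepUm = "numeric",
    doseGy = "numeric",
    imageId = "character"
  )
)

setValidity("ImageStack", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 4L)
    return("pixels must be a 4-d array (channel, z, row, col)")
  if (length(object@channelNames) != dim(p)[1L])
    return("length(channelNames) must equal the channel dimension")
  if (identical(sort(object@channelNames), sort(.CANONICAL_CHANNELS)) &&
      dim(p)[1L] != 3L)
    return("canonical channel triple requires exactly 3 channels")
  if (any(dim(p)[3:4] < 16L))
    return("row/col dimensions must be >= 16")
  if (any(!is.finite(p)) || any(p < 0))
    return("all intensities must be finite and >= 0")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  if (length(object@zStepUm) != 1L || object@zStepUm < 0)
    return("zStepUm must be a single non-negative number")
  if (length(object@doseGy) != 1L ||
      (!is.na(object@doseGy) && object@doseGy < 0))
    return("doseGy must be NA or a single non-negative number")
  if (length(object@imageId) != 1L || !nzchar(object@imageId))
    return("imageId must be a non-empty string")
  TRUE
})

#' Construct an ImageStack
#'
#' @param pixels 4-d numeric array indexed (channel, z, row, col).
#' @param channelNames channel labels; defaults to the canonical
#'   \code{c("nucleus", "foci", "cd45")} triple.
#' @param pixelSizeUm microns per pixel.
#' @param zStepUm z spacing in microns; the acquisition emulated here uses
#'   0.6 um between 5 optical sections.
#' @param doseGy optional absorbed-dose label (Gy); \code{NA} when unknown.
#' @param imageId image identifier.
#' @return An [ImageStack-class] object.
#' @examples
#' px <- array(0, dim = c(3, 2, 32, 32))
#' s <- ImageStack(px, imageId = "ex1", doseGy = 2)
#' nSlices(s)
#' @export
ImageStack <- function(pixels, channelNames = .CANONICAL_CHANNELS,
                       pixelSizeUm = 0.124, zStepUm = 0.6,
                       doseGy = NA_real_, imageId = "stack") {
  new("ImageStack", pixels = pixels, channelNames = channelNames,
      pixelSizeUm = as.numeric(pixelSizeUm), zStepUm = as.numeric(zStepUm),
      doseGy = as.numeric(doseGy), imageId = imageId)
}

#' RGBImage: a merged three-colour slice
#'
#' One optical section with the fixed display channel order R = CD45,
#' G = gamma-H2AX foci, B = nucleus, as produced by [mergeRGB()]. Carries
#' provenance (source image id and slice index) and a flag recording whether
#' the normalisation pipeline has already been applied, so that it is never
#' applied twice.
#'
#' @slot pixels numeric array (row, col, 3), values in \[0, 1\].
#' @slot imageId source image identifier.
#' @slot zIndex 1-based slice index within the source stack.
#' @slot preprocessed logical flag set by [preprocessPipeline()].
#' @export
setClass("RGBImage",
  representation(
    pixels = "array",
    imageId = "character",
    zIndex = "integer",
    preprocessed = "logical"
  )
)

setValidity("RGBImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3L] != 3L)
    return("pixels must be a (row, col, 3) array")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    return("intensities must be finite and within [0, 1]")
  if (length(object@zIndex) != 1L || object@zIndex < 1L)
    return("zIndex must be a single index >= 1")
  TRUE
})

#' Construct an RGBImage
#'
#' @param pixels (row, col, 3) numeric array, channel order R = CD45,
#'   G = foci, B = nucleus, values in \[0, 1\].
#' @param imageId provenance: source image identifier.
#' @param zIndex provenance: 1-based slice index.
#' @param preprocessed whether the normalisation chain was already applied.
#' @return An [RGBImage-class] object.
#' @export
RGBImage <- function(pixels, imageId = "img", zIndex = 1L,
                     preprocessed = FALSE) {
  new("RGBImage", pixels = pixels, imageId = imageId,
      zIndex = as.integer(zIndex), preprocessed = preprocessed)
}

#' Box: an axis-aligned bounding box
#'
#' Pixel-coordinate rectangle using the 0-based, half-open convention
#' \[xmin, xmax) x \[ymin, ymax): x indexes columns, y indexes rows, and the
#' max edges are exclusive, so \code{area = (xmax - xmin) * (ymax - ymin)}
#' exactly and adjacent boxes tile without overlap. Bounding boxes are the
#' unit of cell labelling, cropping and detection matching.
#'
#' @slot xmin,ymin,xmax,ymax box edges in pixels; \code{xmin < xmax},
#'   \code{ymin < ymax}.
#' @export
setClass("Box",
  representation(xmin = "numeric", ymin = "numeric",
                 xmax = "numeric", ymax = "numeric")
)

setValidity("Box", function(object) {
  v <- c(object@xmin, object@ymin, object@xmax, object@ymax)
  if (length(v) != 4L || any(!is.finite(v)))
    return("box edges must be four finite scalars")
  if (object@xmin >= object@xmax || object@ymin >= object@ymax)
    return("box must satisfy xmin < xmax and ymin < ymax")
  TRUE
})

#' Construct a Box
#'
#' @param xmin,ymin,xmax,ymax edges in 0-based, half-open pixel coordinates.
#' @return A [Box-class] object.
#' @examples
#' b <- Box(0, 0, 10, 10)
#' boxIoU(b, Box(5, 0, 15, 10))
#' @export
Box <- function(xmin, ymin, xmax, ymax) {
  new("Box", xmin = as.numeric(xmin), ymin = as.numeric(ymin),
      xmax = as.numeric(xmax), ymax = as.numeric(ymax))
}

#' SceneConfig: simulator configuration
#'
#' All tunable parameters of the synthetic confocal scene generator. The
#' defaults emulate the acquisition the package models: 3-channel z-stacks
#' (5 slices, 0.6 um apart) of mononuclear cells whose per-cell
#' gamma-H2AX focus count is Poisson with a linear dose-dependent mean
#' lambda(D) = a * D + b, using the calibration slope a = 1.996 foci/Gy and
#' intercept b = 0.769 foci. Geometry defaults are stated at the 256 x 256
#' working scale (a 4x downscale of the 1024 x 1024 acquisition; lengths
#' scale proportionally).
#'
#' @slot imageSizePx (rows, cols) of each rendered frame.
#' @slot nZ number of optical sections per stack.
#' @slot dosesGy dose groups to simulate (Gy).
#' @slot cellsPerDose mononuclear cells rendered per dose group.
#' @slot cellsPerImage mononuclear cells per rendered frame.
#' @slot slopeATrue generating calibration slope (foci/Gy).
#' @slot interceptBTrue generating calibration intercept (foci).
#' @slot nucleusRadiusPx (min, max) nucleus radius in pixels.
#' @slot focusSigmaPx (min, max) focus Gaussian sigma in pixels.
#' @slot focusMinSepPx preferred minimum centre separation between foci;
#'   relaxed automatically when the nucleus is too crowded, which is how the
#'   overlapping-foci regime seen at high dose arises.
#' @slot noiseSd additive Gaussian noise sd on the \[0, 1\] intensity scale.
#' @slot batchGainRange (min, max) per-scene multiplicative gain, emulating
#'   staining/imaging batch variation.
#' @slot pmnFraction expected polymorphonuclear distractor cells per
#'   mononuclear cell.
#' @slot zFalloffSdSlices sd (in slices) of the Gaussian amplitude falloff
#'   of a focus away from its own focal plane.
#' @slot seed base RNG seed; every derived stream is a deterministic
#'   function of it.
#' @seealso [SceneConfig()], [renderScene()], [generateDataset()].
#' @export
setClass("SceneConfig",
  representation(
    imageSizePx = "integer",
    nZ = "integer",
    dosesGy = "numeric",
    cellsPerDose = "integer",
    cellsPerImage = "integer",
    slopeATrue = "numeric",
    interceptBTrue = "numeric",
    nucleusRadiusPx = "numeric",
    focusSigmaPx = "numeric",
    focusMinSepPx = "numeric",
    noiseSd = "numeric",
    batchGainRange = "numeric",
    pmnFraction = "numeric",
    zFalloffSdSlices = "numeric",
    seed = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  if (length(object@imageSizePx) != 2L || any(object@imageSizePx < 32L))
    return("imageSizePx must be (rows, cols), each >= 32")
  if (object@nZ < 1L) return("nZ must be >= 1")
  if (length(object@dosesGy) < 1L || any(object@dosesGy < 0))
    return("dosesGy must be non-negative")
  if (object@cellsPerDose < 1L) return("cellsPerDose must be >= 1")
  if (object@cellsPerImage < 1L) return("cellsPerImage must be >= 1")
  if (object@slopeATrue < 0) return("slopeATrue must be >= 0")
  if (object@interceptBTrue < 0) return("interceptBTrue must be >= 0")
  for (nm in c("nucleusRadiusPx", "focusSigmaPx", "batchGainRange")) {
    v <- slot(object, nm)
    if (length(v) != 2L || v[1L] > v[2L] || any(v <= 0))
      return(sprintf("%s must be (min, max) with 0 < min <= max", nm))
  }
  if (object@focusMinSepPx < 0) return("focusMinSepPx must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@pmnFraction < 0 || object@pmnFraction > 1)
    return("pmnFraction must be in [0, 1]")
  if (object@zFalloffSdSlices <= 0)
    return("zFalloffSdSlices must be > 0 (use a large value for flat z)")
  TRUE
})

#' Construct a SceneConfig
#'
#' @param imageSizePx (rows, cols) of each frame; default 256 x 256 working
#'   scale, set \code{c(1024, 1024)} for full acquisition scale.
#' @param nZ slices per stack (default 5).
#' @param dosesGy dose groups in Gy (default 0, 1, 2, 4).
#' @param cellsPerDose mononuclear cells per dose group.
#' @param cellsPerImage cells rendered per frame (default 4; frames never
#'   contain overlapping cells).
#' @param slopeATrue,interceptBTrue generating linear dose response of the
#'   mean focus count, lambda(D) = slopeATrue * D + interceptBTrue.
#' @param nucleusRadiusPx (min, max) nucleus radius in px.
#' @param focusSigmaPx (min, max) focus sigma in px.
#' @param focusMinSepPx preferred minimum focus separation in px.
#' @param noiseSd additive Gaussian noise sd on the \[0, 1\] scale.
#' @param batchGainRange (min, max) per-scene multiplicative gain.
#' @param pmnFraction expected polymorphonuclear distractors per cell.
#' @param zFalloffSdSlices focus amplitude falloff sd across slices.
#' @param seed base seed.
#' @return A validated [SceneConfig-class].
#' @examples
#' cfg <- SceneConfig(cellsPerDose = 8, seed = 7)
#' cfg
#' @export
SceneConfig <- function(imageSizePx = c(256L, 256L), nZ = 5L,
                        dosesGy = c(0, 1, 2, 4), cellsPerDose = 100L,
                        cellsPerImage = 4L,
                        slopeATrue = 1.996, interceptBTrue = 0.769,
                        nucleusRadiusPx = c(18, 30),
                        focusSigmaPx = c(1.2, 2.0),
                        focusMinSepPx = 8, noiseSd = 0.01,
                        batchGainRange = c(0.9, 1.1),
                        pmnFraction = 0.2, zFalloffSdSlices = 2.0,
                        seed = 1L) {
  new("SceneConfig",
      imageSizePx = as.integer(imageSizePx), nZ = as.integer(nZ),
      dosesGy = as.numeric(dosesGy), cellsPerDose = as.integer(cellsPerDose),
      cellsPerImage = as.integer(cellsPerImage),
      slopeATrue = as.numeric(slopeATrue),
      interceptBTrue = as.numeric(interceptBTrue),
      nucleusRadiusPx = as.numeric(nucleusRadiusPx),
      focusSigmaPx = as.numeric(focusSigmaPx),
      focusMinSepPx = as.numeric(focusMinSepPx),
      noiseSd = as.numeric(noiseSd),
      batchGainRange = as.numeric(batchGainRange),
      pmnFraction = as.numeric(pmnFraction),
      zFalloffSdSlices = as.numeric(zFalloffSdSlices),
      seed = as.integer(seed))
}

#' GroundTruthScene: a rendered frame plus exact ground truth
#'
#' The output of [renderScene()]: the simulated [ImageStack-class] together
#' with the planted mononuclear-cell boxes, the per-cell focus boxes, the
#' true per-cell counts and the generating dose. Polymorphonuclear
#' distractor cells are rendered into the pixels but carry no ground-truth
#' cell box.
#'
#' @slot stack the rendered [ImageStack-class].
#' @slot mncBoxes data.frame of mononuclear-cell boxes
#'   (columns \code{x_min, y_min, x_max, y_max}; 0-based half-open).
#' @slot fociBoxes list (one data.frame per cell, same columns) of planted
#'   focus boxes; squares of side \code{2 * ceiling(2 * sigma)} centred on
#'   each planted peak.
#' @slot trueCounts integer vector of planted focus counts per cell.
#' @slot doseGy generating dose (Gy).
#' @export
setClass("GroundTruthScene",
  representation(
    stack = "ImageStack",
    mncBoxes = "data.frame",
    fociBoxes = "list",
    trueCounts = "integer",
    doseGy = "numeric"
  )
)

setValidity("GroundTruthScene", function(object) {
  n <- nrow(object@mncBoxes)
  if (length(object@fociBoxes) != n || length(object@trueCounts) != n)
    return("mncBoxes, fociBoxes and trueCounts must describe the same cells")
  for (i in seq_len(n)) {
    if (nrow(object@fociBoxes[[i]]) != object@trueCounts[i])
      return("trueCounts must equal the number of focus boxes per cell")
  }
  if (length(object@doseGy) != 1L || object@doseGy < 0)
    return("doseGy must be a single non-negative dose")
  TRUE
})

#' CalibrationCurve: linear dose-response fit
#'
#' Ordinary-least-squares fit of mean foci per cell (y) against absorbed
#' dose in Gy (x), y = a x + b, with fit diagnostics and the dose range the
#' calibration is valid over. Inverting the curve with [estimateDose()]
#' converts a measured mean focus count into an absorbed-dose estimate;
#' estimates outside \code{doseRangeGy} are flagged as extrapolated.
#'
#' @slot slopeA slope a in foci/Gy.
#' @slot interceptB intercept b in foci (background focus level).
#' @slot rSquared coefficient of determination of the fit.
#' @slot seA,seB standard errors of slope and intercept.
#' @slot doseRangeGy (min, max) of the calibration doses.
#' @slot nPoints number of (dose, mean foci) points fitted.
#' @seealso [fitCalibration()], [predictFoci()], [estimateDose()].
#' @export
setClass("CalibrationCurve",
  representation(
    slopeA = "numeric",
    interceptB = "numeric",
    rSquared = "numeric",
    seA = "numeric",
    seB = "numeric",
    doseRangeGy = "numeric",
    nPoints = "integer"
  )
)

setValidity("CalibrationCurve", function(object) {
  if (!is.finite(object@slopeA)) return("slopeA must be finite")
  if (length(object@doseRangeGy) != 2L ||
      object@doseRangeGy[1L] >= object@doseRangeGy[2L])
    return("doseRangeGy must be (min, max) with min < max")
  if (!is.na(object@rSquared) &&
      (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
    return("rSquared must lie in [0, 1]")
  TRUE
})

#' MatchResult: detection-to-truth matching tally
#'
#' Result of greedy one-to-one matching of confidence-ranked detections to
#' ground-truth boxes at an IoU threshold: true-positive, false-positive
#' and false-negative counts plus the matched pairs.
#'
#' @slot tp,fp,fn non-negative integer tallies; \code{tp + fp} equals the
#'   number of predictions and \code{tp + fn} the number of truths.
#' @slot matchedPairs data.frame with columns \code{pred}, \code{truth},
#'   \code{iou} (1-based indices into the inputs).
#' @seealso [matchDetections()], [evaluateByDose()].
#' @export
setClass("MatchResult",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 matchedPairs = "data.frame")
)

setValidity("MatchResult", function(object) {
  if (any(c(object@tp, object@fp, object@fn) < 0L))
    return("tp, fp, fn must be non-negative")
  if (object@tp != nrow(object@matchedPairs))
    return("tp must equal the number of matched pairs")
  TRUE
})
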