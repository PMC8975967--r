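#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: \code{pixels()}
#' returns the raw intensity array, \code{imageId()} the provenance
#' identifier, \code{doseGy()} the dose label, \code{channelNames()} the
#' ordered channel labels, \code{nSlices()} the z-depth, and
#' \code{imageDim()} the (rows, cols) spatial size.
#'
#' @param x an [ImageStack-class] or [RGBImage-class].
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' @rdname accessors
#' @export
setGeneric("doseGy", function(x) standardGeneric("doseGy"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname accessors
#' @export
setGeneric("imageDim", function(x) standardGeneric("imageDim"))

#' @rdname accessors
setMethod("pixels", "ImageStack", function(x) x@pixels)

#' @rdname accessors
setMethod("pixels", "RGBImage", function(x) x@pixels)

#' @rdname accessors
setMethod("imageId", "ImageStack", function(x) x@imageId)

#' @rdname accessors
setMethod("imageId", "RGBImage", function(x) x@imageId)

#' @rdname accessors
setMethod("doseGy", "ImageStack", function(x) x@doseGy)

#' @rdname accessors
setMethod("doseGy", "GroundTruthScene", function(x) x@doseGy)

#' @rdname accessors
setMethod("channelNames", "ImageStack", function(x) x@channelNames)

#' @rdname accessors
setMethod("nSlices", "ImageStack", function(x) dim(x@pixels)[2L])

#' @rdname accessors
setMethod("imageDim", "ImageStack", function(x) dim(x@pixels)[3:4])

#' @rdname accessors
setMethod("imageDim", "RGBImage", function(x) dim(x@pixels)[1:2])

#' Ground-truth scene accessors
#'
#' @param x a [GroundTruthScene-class].
#' @return \code{gtStack()} the rendered stack; \code{mncBoxes()} the
#'   planted cell boxes; \code{fociBoxes()} the per-cell focus boxes;
#'   \code{trueCounts()} the planted counts.
#' @name scene-accessors
NULL

#' @rdname scene-accessors
#' @export
setGeneric("gtStack", function(x) standardGeneric("gtStack"))
#' @rdname scene-accessors
setMethod("gtStack", "GroundTruthScene", function(x) x@stack)

#' @rdname scene-accessors
#' @export
setGeneric("mncBoxes", function(x) standardGeneric("mncBoxes"))
#' @rdname scene-accessors
setMethod("mncBoxes", "GroundTruthScene", function(x) x@mncBoxes)

#' @rdname scene-accessors
#' @export
setGeneric("fociBoxes", function(x) standardGeneric("fociBoxes"))
#' @rdname scene-accessors
setMethod("fociBoxes", "GroundTruthScene", function(x) x@fociBoxes)

#' @rdname scene-accessors
#' @export
setGeneric("trueCounts", function(x) standardGeneric("trueCounts"))
#' @rdname scene-accessors
setMethod("trueCounts", "GroundTruthScene", function(x) x@trueCounts)

#' Calibration-curve accessors
#'
#' @param x a [CalibrationCurve-class].
#' @return \code{calSlope()}/\code{calIntercept()} the fitted coefficients,
#'   \code{calRSquared()} the fit R^2, \code{doseRange()} the valid dose
#'   range in Gy.
#' @name curve-accessors
NULL

#' @rdname curve-accessors
#' @export
setGeneric("calSlope", function(x) standardGeneric("calSlope"))
#' @rdname curve-accessors
setMethod("calSlope", "CalibrationCurve", function(x) x@slopeA)

#' @rdname curve-accessors
#' @export
setGeneric("calIntercept", function(x) standardGeneric("calIntercept"))
#' @rdname curve-accessors
setMethod("calIntercept", "CalibrationCurve", function(x) x@interceptB)

#' @rdname curve-accessors
#' @export
setGeneric("calRSquared", function(x) standardGeneric("calRSquared"))
#' @rdname curve-accessors
setMethod("calRSquared", "CalibrationCurve", function(x) x@rSquared)

#' @rdname curve-accessors
#' @export
setGeneric("doseRange", function(x) standardGeneric("doseRange"))
#' @rdname curve-accessors
setMethod("doseRange", "CalibrationCurve", function(x) x@doseRangeGy)

#' Match tallies
#'
#' @param x a [MatchResult-class].
#' @return integer tally (\code{truePositives} etc.) or the matched-pair
#'   table.
#' @name match-accessors
NULL

#' @rdname match-accessors
#' @export
setGeneric("truePositives", function(x) standardGeneric("truePositives"))
#' @rdname match-accessors
setMethod("truePositives", "MatchResult", function(x) x@tp)

#' @rdname match-accessors
#' @export
setGeneric("falsePositives", function(x) standardGeneric("falsePositives"))
#' @rdname match-accessors
setMethod("falsePositives", "MatchResult", function(x) x@fp)

#' @rdname match-accessors
#' @export
setGeneric("falseNegatives", function(x) standardGeneric("falseNegatives"))
#' @rdname match-accessors
setMethod("falseNegatives", "MatchResult", function(x) x@fn)

#' @rdname match-accessors
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))
#' @rdname match-accessors
setMethod("matchedPairs", "MatchResult", function(x) x@matchedPairs)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageStack '%s': %d channel(s) x %d slice(s) x %d x %d px\n",
              object@imageId, d[1L], d[2L], d[3L], d[4L]))
  cat(sprintf("  channels: %s\n", paste(object@channelNames, collapse = ", ")))
  cat(sprintf("  pixel size %.3g um, z step %.3g um, dose %s Gy\n",
              object@pixelSizeUm, object@zStepUm,
              ifelse(is.na(object@doseGy), "NA", format(object@doseGy))))
})

setMethod("show", "RGBImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RGBImage %d x %d px (R=cd45, G=foci, B=nucleus), '%s' z=%d%s\n",
              d[1L], d[2L], object@imageId, object@zIndex,
              if (object@preprocessed) ", preprocessed" else ""))
})

setMethod("show", "Box", function(object) {
  cat(sprintf("Box [%g, %g) x [%g, %g)  area %g px^2\n",
              object@xmin, object@xmax, object@ymin, object@ymax,
              (object@xmax - object@xmin) * (object@ymax - object@ymin)))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %d x %d px, %d slice(s), doses [%s] Gy\n",
              object@imageSizePx[1L], object@imageSizePx[2L], object@nZ,
              paste(object@dosesGy, collapse = ", ")))
  cat(sprintf("  %d cell(s)/dose (%d per frame), lambda(D) = %.3f D + %.3f\n",
              object@cellsPerDose, object@cellsPerImage,
              object@slopeATrue, object@interceptBTrue))
  cat(sprintf("  noise sd %.3g, gain [%.2f, %.2f], pmn fraction %.2f, seed %d\n",
              object@noiseSd, object@batchGainRange[1L],
              object@batchGainRange[2L], object@pmnFraction, object@seed))
})

setMethod("show", "GroundTruthScene", function(object) {
  cat(sprintf("GroundTruthScene '%s': dose %g Gy, %d cell(s), %d focus(es)\n",
              object@stack@imageId, object@doseGy, nrow(object@mncBoxes),
              sum(object@trueCounts)))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: y = %.4f x + %.4f  (R^2 = %.4f)\n",
              object@slopeA, object@interceptB, object@rSquared))
  cat(sprintf("  SE(a) %.4f, SE(b) %.4f; %d point(s); valid %g-%g Gy\n",
              object@seA, object@seB, object@nPoints,
              object@doseRangeGy[1L], object@doseRangeGy[2L]))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: TP %d, FP %d, FN %d\n",
              object@tp, object@fp, object@fn))
})
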