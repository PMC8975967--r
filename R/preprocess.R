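#' Preprocessing parameters
#'
#' Parameters of the intensity-normalisation chain applied to every merged
#' RGB slice before detection: optional per-channel histogram matching to a
#' reference image (removing staining/imaging batch variation), then a
#' median filter, then a Gaussian blur. The classical defaults are a 3 x 3
#' median kernel and Gaussian sd of 5 px at full 1024 x 1024 acquisition
#' scale; at a downscaled working geometry the Gaussian sd should be scaled
#' proportionally (see [runConfig()], which does this automatically).
#'
#' @param referenceImage an [RGBImage-class] used as the histogram-matching
#'   target, or `NULL` to skip matching.
#' @param medianKernelPx odd median window side in px (default 3).
#' @param gaussianSdPx Gaussian blur standard deviation in px (default 5).
#' @return A list of class `PreprocessParams`.
#' @export
preprocessParams <- function(referenceImage = NULL, medianKernelPx = 3L,
                             gaussianSdPx = 5) {
  medianKernelPx <- as.integer(medianKernelPx)
  if (medianKernelPx < 1L || medianKernelPx %% 2L != 1L)
    stop("medianKernelPx must be an odd integer >= 1", call. = FALSE)
  if (gaussianSdPx <= 0)
    stop("gaussianSdPx must be > 0", call. = FALSE)
  if (!is.null(referenceImage)) stopifnot(is(referenceImage, "RGBImage"))
  structure(list(referenceImage = referenceImage,
                 medianKernelPx = medianKernelPx,
                 gaussianSdPx = gaussianSdPx),
            class = "PreprocessParams")
}

# Rank-based histogram matching of one channel: each pixel is mapped to the
# reference quantile at its own empirical CDF position. Invariant under any
# strictly monotone re-labelling of the input intensities.
.matchChannel <- function(x, ref) {
  n <- length(x)
  srt_ref <- sort(as.numeric(ref))
  # empirical CDF position of each input pixel (average rank handles ties)
  rk <- rank(x, ties.method = "average")
  q <- (rk - 0.5) / n
  pos <- q * length(srt_ref) + 0.5
  lo <- pmin(pmax(floor(pos), 1), length(srt_ref))
  hi <- pmin(lo + 1, length(srt_ref))
  w <- pos - lo
  out <- srt_ref[lo] * (1 - w) + srt_ref[hi] * w
  matrix(out, nrow(x), ncol(x))
}

#' Histogram matching to a reference image
#'
#' Per-channel rank-based histogram specification: the output empirical
#' distribution of each channel approximates the reference channel's, which
#' removes the between-experiment intensity variation introduced by
#' staining and imaging. A constant reference channel maps every pixel of
#' that channel to the constant.
#'
#' @param img an [RGBImage-class] to normalise.
#' @param ref the reference [RGBImage-class].
#' @return An [RGBImage-class] with matched intensities; output values stay
#'   within the reference range.
#' @export
histogramMatch <- function(img, ref) {
  stopifnot(is(img, "RGBImage"), is(ref, "RGBImage"))
  out <- img@pixels
  for (ch in 1:3)
    out[, , ch] <- .matchChannel(img@pixels[, , ch], ref@pixels[, , ch])
  RGBImage(.clip(out), imageId = img@imageId, zIndex = img@zIndex,
           preprocessed = img@preprocessed)
}

#' Median + Gaussian denoising
#'
#' Applies, per channel, a `medianKernelPx` x `medianKernelPx` median
#' filter (rejecting impulse noise) followed by a Gaussian blur of sd
#' `gaussianSdPx`. Both filters use symmetric border handling and preserve
#' the image dimensions; constant images pass through unchanged.
#'
#' @param img an [RGBImage-class].
#' @param params a [preprocessParams()] list.
#' @return The denoised [RGBImage-class].
#' @export
denoise <- function(img, params = preprocessParams()) {
  stopifnot(is(img, "RGBImage"), inherits(params, "PreprocessParams"))
  d <- imageDim(img)
  if (params$medianKernelPx > min(d))
    stop("configuration error: median kernel larger than image",
         call. = FALSE)
  out <- img@pixels
  for (ch in 1:3) {
    m <- .medianFilter(img@pixels[, , ch], params$medianKernelPx)
    out[, , ch] <- .gaussianBlur(m, params$gaussianSdPx)
  }
  RGBImage(.clip(out), imageId = img@imageId, zIndex = img@zIndex,
           preprocessed = img@preprocessed)
}

#' The full normalisation chain
#'
#' Histogram matching (when a reference is configured) followed by
#' [denoise()], in that order. The chain is applied exactly once per image:
#' the result carries a provenance flag and re-running the pipeline on an
#' already-preprocessed image is an error (blurring twice is not the same
#' as blurring once).
#'
#' @param img an [RGBImage-class] fresh from [mergeRGB()].
#' @param params a [preprocessParams()] list.
#' @return The normalised [RGBImage-class], flagged as preprocessed.
#' @export
preprocessPipeline <- function(img, params = preprocessParams()) {
  stopifnot(is(img, "RGBImage"))
  if (img@preprocessed)
    stop("image has already been preprocessed", call. = FALSE)
  out <- img
  if (!is.null(params$referenceImage))
    out <- histogramMatch(out, params$referenceImage)
  out <- denoise(out, params)
  out@preprocessed <- TRUE
  out
}

#' Extract the green (foci) plane
#'
#' Returns the G plane of a merged RGB image exactly, with no rescaling:
#' the gamma-H2AX channel that the second detection stage operates on.
#'
#' @param img an [RGBImage-class].
#' @return A numeric matrix (row, col).
#' @export
extractGreen <- function(img) {
  stopifnot(is(img, "RGBImage"))
  img@pixels[, , 2L]
}
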