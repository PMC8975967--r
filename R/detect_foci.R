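#' Focus-detector parameters
#'
#' Parameters of the deterministic reference backend for the second
#' detection stage, a classical spot detector on the extracted green
#' channel: white top-hat background removal (disc of radius
#' `tophatRadiusPx`), multi-scale scale-normalised Laplacian-of-Gaussian
#' blob response over `nScales` sigmas spanning `logSigmaPx`, local-maxima
#' extraction, thresholding at `peakThreshold` times the strongest response
#' (with an absolute floor `minResponse` so empty cells do not promote
#' noise peaks), and greedy non-maximum suppression at IoU `nmsIoU`.
#' Sigma defaults are stated at the 256 x 256 working scale and describe
#' the focus footprint after the Gaussian preprocessing blur.
#'
#' @param tophatRadiusPx structuring-disc radius for background removal.
#' @param logSigmaPx (min, max) blob sigma range in px.
#' @param nScales number of logarithmically spaced scales.
#' @param peakThreshold relative response threshold in (0, 1].
#' @param minResponse absolute response floor; a crop whose strongest
#'   response is below it yields no detections.
#' @param nmsIoU IoU above which overlapping detections are suppressed.
#' @return A list of class `FociParams`.
#' @export
fociParams <- function(tophatRadiusPx = 6L, logSigmaPx = c(1.6, 3.2),
                       nScales = 4L, peakThreshold = 0.2,
                       minResponse = 0.04, nmsIoU = 0.3) {
  if (tophatRadiusPx < 1L) stop("tophatRadiusPx must be >= 1", call. = FALSE)
  if (length(logSigmaPx) != 2L || logSigmaPx[1L] > logSigmaPx[2L] ||
      any(logSigmaPx <= 0))
    stop("logSigmaPx must be (min, max) with 0 < min <= max", call. = FALSE)
  if (peakThreshold <= 0 || peakThreshold > 1)
    stop("peakThreshold must be in (0, 1]", call. = FALSE)
  if (nmsIoU < 0 || nmsIoU >= 1) stop("nmsIoU must be in [0, 1)",
                                      call. = FALSE)
  structure(list(tophatRadiusPx = as.integer(tophatRadiusPx),
                 logSigmaPx = as.numeric(logSigmaPx),
                 nScales = as.integer(nScales),
                 peakThreshold = peakThreshold, minResponse = minResponse,
                 nmsIoU = nmsIoU),
            class = "FociParams")
}

# Discrete 5-point Laplacian with symmetric borders.
.laplacian <- function(m) {
  p <- .padReflect(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  p[1:nr, 2:(nc + 1)] + p[3:(nr + 2), 2:(nc + 1)] +
    p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 3:(nc + 2)] - 4 * m
}

# 3x3-neighbourhood local maxima (strict against at least one neighbour,
# ties broken towards the first in scan order via >=).
.localMax3x3 <- function(m) {
  p <- .padReflect(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  mx <- matrix(-Inf, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1L && dj == 1L) next
    mx <- pmax(mx, p[(1 + di):(nr + di), (1 + dj):(nc + dj)])
  }
  m >= mx & m > 0
}

# Greedy non-maximum suppression on a detection table sorted by
# descending confidence; returns the kept row indices.
.nms <- function(det, iou_thr) {
  n <- nrow(det)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in which(keep)) {
      if (.iouNumeric(det$x_min[i], det$y_min[i], det$x_max[i], det$y_max[i],
                      det$x_min[j], det$y_min[j], det$x_max[j],
                      det$y_max[j]) > iou_thr) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  which(keep)
}

#' Reference gamma-H2AX focus detector
#'
#' Deterministic classical backend for stage 2 (see [fociParams()] for the
#' operator chain). Each detection is a square box of side
#' `2 * ceiling(2 * sigma)` centred on a blob-response peak, with
#' confidence equal to its response divided by the strongest response in
#' the crop; detections are confidence-sorted descending. Two foci closer
#' than about one sigma merge into a single response peak — the known
#' overlapping-foci limitation of 2-d focus counting at high dose.
#'
#' @param green single-channel non-negative matrix (the extracted green
#'   plane of a cell crop).
#' @param params a [fociParams()] list.
#' @param imageId provenance id stored in the output rows.
#' @return Detection data.frame (label `"focus"`, 0-based half-open boxes).
#' @export
detectFoci <- function(green, params = fociParams(), imageId = "crop") {
  if (!is.matrix(green) || any(green < 0))
    stop("detectFoci requires a non-negative single-channel matrix",
         call. = FALSE)
  p <- params
  nr <- nrow(green); nc <- ncol(green)
  if (max(green) == 0) return(.emptyDetections())
  brush_side <- min(2L * p$tophatRadiusPx + 1L, nr - (1 - nr %% 2L),
                    nc - (1 - nc %% 2L))
  if (brush_side >= 3L) {
    th <- EBImage::whiteTopHat(green,
                               EBImage::makeBrush(brush_side, "disc"))
    th <- as.matrix(th)
  } else th <- green
  sigmas <- exp(seq(log(p$logSigmaPx[1L]), log(p$logSigmaPx[2L]),
                    length.out = p$nScales))
  cand <- NULL
  for (s in sigmas) {
    resp <- -s^2 * .laplacian(.gaussianBlur(th, s))
    pk <- which(.localMax3x3(resp), arr.ind = TRUE)
    if (nrow(pk))
      cand <- rbind(cand, data.frame(row = pk[, 1L], col = pk[, 2L],
                                     sigma = s,
                                     resp = resp[pk]))
  }
  if (is.null(cand) || nrow(cand) == 0L) return(.emptyDetections())
  gmax <- max(cand$resp)
  if (gmax < p$minResponse) return(.emptyDetections())
  cand <- cand[cand$resp >= max(p$peakThreshold * gmax, p$minResponse), ,
               drop = FALSE]
  h <- ceiling(2 * cand$sigma)
  det <- data.frame(
    image_id = imageId, label = "focus",
    confidence = .clip(cand$resp / gmax),
    x_min = pmax(0, (cand$col - 1L) - h),
    y_min = pmax(0, (cand$row - 1L) - h),
    x_max = pmin(nc, (cand$col - 1L) + h),
    y_max = pmin(nr, (cand$row - 1L) + h),
    stringsAsFactors = FALSE)
  # clipping at the crop edge can degenerate a box; nudge it back inside
  det$x_max <- pmax(det$x_max, det$x_min + 1)
  det$y_max <- pmax(det$y_max, det$y_min + 1)
  det$x_min <- pmin(det$x_min, det$x_max - 1)
  det$y_min <- pmin(det$y_min, det$y_max - 1)
  det <- det[order(-det$confidence), , drop = FALSE]
  det <- det[.nms(det, p$nmsIoU), , drop = FALSE]
  rownames(det) <- NULL
  det
}
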