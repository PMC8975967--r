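#' Mononuclear-cell detector parameters
#'
#' Parameters of the deterministic reference backend for the first
#' detection stage. The backend thresholds the nucleus (blue) channel,
#' cleans the mask by morphological opening, labels connected components,
#' and keeps components that look like intact mononuclear cells: area
#' within \[`minAreaPx`, `maxAreaPx`\], solidity at least `minSolidity`
#' (rejecting irregular / multi-lobed shapes), not touching the image
#' border when `excludeBorder` (incomplete cells), and with a mean CD45
#' (red) intensity of at least `cd45Gate` in a ring of width `ringWidthPx`
#' around the nucleus — the "double-positive DAPI plus bright CD45"
#' criterion that separates mononuclear cells from polymorphonuclear
#' distractors. Defaults are stated at the 256 x 256 working scale.
#'
#' @param nucleusThreshold `"auto"` (Otsu) or a fixed threshold in
#'   \[0, 1\].
#' @param minAreaPx,maxAreaPx admissible nucleus area range in px^2.
#' @param minSolidity minimum component solidity (area / convex hull area).
#' @param cd45Gate minimum mean red intensity in the perinuclear ring.
#' @param ringWidthPx width of the CD45 ring probe in px.
#' @param boxMarginPx margin added around the tight nucleus bounding box.
#' @param excludeBorder drop components touching the image border.
#' @return A list of class `MncParams`.
#' @export
mncParams <- function(nucleusThreshold = "auto", minAreaPx = 350,
                      maxAreaPx = 7000, minSolidity = 0.85,
                      cd45Gate = 0.2, ringWidthPx = 4L, boxMarginPx = 4L,
                      excludeBorder = TRUE) {
  if (!identical(nucleusThreshold, "auto")) {
    nucleusThreshold <- as.numeric(nucleusThreshold)
    if (!is.finite(nucleusThreshold) || nucleusThreshold < 0 ||
        nucleusThreshold > 1)
      stop("nucleusThreshold must be 'auto' or a value in [0, 1]",
           call. = FALSE)
  }
  if (minAreaPx >= maxAreaPx) stop("minAreaPx must be < maxAreaPx",
                                   call. = FALSE)
  if (minSolidity < 0 || minSolidity > 1)
    stop("minSolidity must be in [0, 1]", call. = FALSE)
  structure(list(nucleusThreshold = nucleusThreshold,
                 minAreaPx = minAreaPx, maxAreaPx = maxAreaPx,
                 minSolidity = minSolidity, cd45Gate = cd45Gate,
                 ringWidthPx = as.integer(ringWidthPx),
                 boxMarginPx = as.integer(boxMarginPx),
                 excludeBorder = isTRUE(excludeBorder)),
            class = "MncParams")
}

# Solidity of a pixel set: pixel area over the area of the convex hull of
# the pixel centres (hull area gets a half-pixel boundary correction so a
# filled disc scores close to 1).
.solidity <- function(rows, cols) {
  n <- length(rows)
  if (n < 4L) return(1)
  pts <- unique(cbind(cols, rows))
  if (nrow(pts) < 3L) return(1)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  x <- hp[, 1L]; y <- hp[, 2L]
  hull_area <- abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  # boundary correction: hull of centres misses ~half a pixel per edge px
  peri <- sum(sqrt(diff(c(x, x[1L]))^2 + diff(c(y, y[1L]))^2))
  hull_area <- hull_area + peri / 2 + 1
  min(1, n / hull_area)
}

#' Reference mononuclear-cell detector
#'
#' Deterministic classical backend for stage 1 (see [mncParams()] for the
#' pipeline). Confidence is the product of a normalised area score, the
#' component solidity and a normalised CD45 ring score, clipped to
#' \[0, 1\]; detections are returned confidence-sorted descending. Any
#' detector with the same signature and contract (in-bounds boxes,
#' confidences in \[0, 1\], deterministic) can replace this backend in
#' [countFociTwoStage()].
#'
#' @param img a preprocessed [RGBImage-class].
#' @param params an [mncParams()] list.
#' @return Detection data.frame (columns `image_id, label, confidence,
#'   x_min, y_min, x_max, y_max`; label `"MNC"`; 0-based half-open boxes).
#' @export
detectMNC <- function(img, params = mncParams()) {
  if (!is(img, "RGBImage"))
    stop("format error: detectMNC requires a 3-channel RGBImage",
         call. = FALSE)
  p <- params
  blue <- img@pixels[, , 3L]
  red <- img@pixels[, , 1L]
  nr <- nrow(blue); nc <- ncol(blue)
  if (max(blue) - min(blue) < 0.05) return(.emptyDetections())
  th <- if (identical(p$nucleusThreshold, "auto")) EBImage::otsu(blue)
        else p$nucleusThreshold
  mask <- blue > th
  mask <- EBImage::opening(mask, EBImage::makeBrush(3L, "box"))
  lab <- EBImage::bwlabel(mask)
  lab <- as.matrix(lab)  # same orientation as input
  ncomp <- max(lab)
  if (ncomp == 0L) return(.emptyDetections())
  out <- .emptyDetections()
  for (ci in seq_len(ncomp)) {
    idx <- which(lab == ci, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < p$minAreaPx || area > p$maxAreaPx) next
    rows <- idx[, 1L]; cols <- idx[, 2L]
    if (p$excludeBorder &&
        (min(rows) == 1L || min(cols) == 1L || max(rows) == nr ||
         max(cols) == nc)) next
    sol <- .solidity(rows, cols)
    if (sol < p$minSolidity) next
    # CD45 gate: mean red intensity in a ring around the component
    comp <- lab == ci
    outer_d <- EBImage::dilate(comp,
                               EBImage::makeBrush(2L * p$ringWidthPx + 1L,
                                                  "disc"))
    ring <- as.matrix(outer_d) & !comp
    ring_mean <- if (any(ring)) mean(red[ring]) else 0
    if (ring_mean < p$cd45Gate) next
    area_score <- min(1, area / (2 * p$minAreaPx))
    cd45_score <- min(1, ring_mean / (2 * p$cd45Gate))
    conf <- .clip(area_score * sol * cd45_score)
    out <- rbind(out, data.frame(
      image_id = img@imageId, label = "MNC", confidence = conf,
      x_min = max(0L, min(cols) - 1L - p$boxMarginPx),
      y_min = max(0L, min(rows) - 1L - p$boxMarginPx),
      x_max = min(nc, max(cols) + p$boxMarginPx),
      y_max = min(nr, max(rows) + p$boxMarginPx),
      stringsAsFactors = FALSE))
  }
  out[order(-out$confidence), , drop = FALSE]
}

#' Crop detected cells out of an image
#'
#' One crop per detection, the rectangle expanded by `margin` px and
#' clipped to the image bounds, with provenance (parent image id, parent
#' box, slice index) recorded.
#'
#' @param img an [RGBImage-class].
#' @param dets detection data.frame with label `"MNC"`.
#' @param margin extra margin in px (default 0).
#' @return A list of `CellCrop` records, each with elements `pixels`
#'   ((rows, cols, 3) array), `parentImageId`, `parentBox` ([Box-class]),
#'   and `zIndex`. Empty detections give an empty list.
#' @export
cropCells <- function(img, dets, margin = 0L) {
  stopifnot(is(img, "RGBImage"))
  if (nrow(dets) == 0L) return(list())
  .checkDetections(dets, "dets")
  if (!all(dets$label == "MNC"))
    stop("cropCells expects MNC-labelled detections", call. = FALSE)
  d <- imageDim(img)
  lapply(seq_len(nrow(dets)), function(i) {
    x0 <- max(0, dets$x_min[i] - margin); y0 <- max(0, dets$y_min[i] - margin)
    x1 <- min(d[2L], dets$x_max[i] + margin)
    y1 <- min(d[1L], dets$y_max[i] + margin)
    crop <- img@pixels[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
    structure(list(pixels = crop, parentImageId = img@imageId,
                   parentBox = Box(x0, y0, x1, y1), zIndex = img@zIndex),
              class = "CellCrop")
  })
}
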