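#' Two-stage focus counting on a z-stack
#'
#' The concatenated workflow applied to one stack: for every optical
#' section, merge the channels, run the normalisation chain, detect
#' mononuclear cells (stage 1), crop each detection, extract the green
#' plane and detect foci inside it (stage 2). Per-slice cells are then
#' linked across z by box-centre proximity (two detections belong to the
#' same cell when their centres lie within half a typical cell diameter)
#' and the per-slice focus counts of each cell are aggregated into a
#' single `cell_count`:
#' \describe{
#'   \item{`mean`}{mean count over the slices the cell was detected in
#'     (default);}
#'   \item{`max`}{maximum per-slice count;}
#'   \item{`best_slice`}{count at the slice with the largest total green
#'     intensity inside the cell crop (the best-focused section).}
#' }
#'
#' Both detectors are pluggable: any function with the reference backend's
#' signature and contract (deterministic, in-bounds boxes, confidences in
#' \[0, 1\], sorted descending) can be passed.
#'
#' @param stack an [ImageStack-class].
#' @param preParams [preprocessParams()] for the normalisation chain.
#' @param mncPar [mncParams()] for stage 1.
#' @param fociPar [fociParams()] for stage 2.
#' @param zAgg aggregation of per-slice counts: `"mean"`, `"max"` or
#'   `"best_slice"`.
#' @param mncBackend stage-1 detector (default [detectMNC()]).
#' @param fociBackend stage-2 detector (default [detectFoci()]).
#' @param linkDistPx cross-slice linking radius in px; default half the
#'   median detected cell-box side.
#' @return data.frame with one row per linked cell: `cell_id`, `image_id`,
#'   `dose_gy`, `cx`, `cy` (mean box centre), `n_slices` (slices the cell
#'   was seen in), `cell_count`, and a `per_slice` list-column of the raw
#'   per-slice counts. A blank stack yields zero rows.
#' @export
countFociTwoStage <- function(stack,
                              preParams = preprocessParams(),
                              mncPar = mncParams(),
                              fociPar = fociParams(),
                              zAgg = c("mean", "max", "best_slice"),
                              mncBackend = detectMNC,
                              fociBackend = detectFoci,
                              linkDistPx = NULL) {
  stopifnot(is(stack, "ImageStack"))
  zAgg <- match.arg(zAgg)
  recs <- NULL
  for (z in seq_len(nSlices(stack))) {
    img <- preprocessPipeline(mergeRGB(stack, z), preParams)
    dets <- tryCatch(mncBackend(img, mncPar), error = function(e)
      stop(sprintf("stage1 failed (image %s, z %d): %s",
                   imageId(stack), z, conditionMessage(e)), call. = FALSE))
    if (nrow(dets) == 0L) next
    crops <- cropCells(img, dets, margin = 0L)
    for (k in seq_along(crops)) {
      green <- crops[[k]]$pixels[, , 2L]
      fd <- tryCatch(fociBackend(green, fociPar),
                     error = function(e)
        stop(sprintf("stage2 failed (image %s, z %d, cell %d): %s",
                     imageId(stack), z, k, conditionMessage(e)),
             call. = FALSE))
      b <- crops[[k]]$parentBox
      recs <- rbind(recs, data.frame(
        z = z, cx = (b@xmin + b@xmax) / 2, cy = (b@ymin + b@ymax) / 2,
        side = max(b@xmax - b@xmin, b@ymax - b@ymin),
        count = nrow(fd), green_sum = sum(green),
        stringsAsFactors = FALSE))
    }
  }
  empty <- data.frame(cell_id = character(0), image_id = character(0),
                      dose_gy = numeric(0), cx = numeric(0), cy = numeric(0),
                      n_slices = integer(0), cell_count = numeric(0))
  if (is.null(recs)) { empty$per_slice <- list(); return(empty) }
  if (is.null(linkDistPx)) linkDistPx <- stats::median(recs$side) / 2

  # greedy cross-slice linking on running track centres
  track <- integer(nrow(recs))
  tcx <- numeric(0); tcy <- numeric(0); tn <- integer(0)
  for (i in seq_len(nrow(recs))) {
    best <- Inf; bj <- 0L
    for (j in seq_along(tcx)) {
      dd <- sqrt((tcx[j] - recs$cx[i])^2 + (tcy[j] - recs$cy[i])^2)
      if (dd < best) { best <- dd; bj <- j }
    }
    if (bj > 0L && best <= linkDistPx) {
      track[i] <- bj
      tcx[bj] <- (tcx[bj] * tn[bj] + recs$cx[i]) / (tn[bj] + 1L)
      tcy[bj] <- (tcy[bj] * tn[bj] + recs$cy[i]) / (tn[bj] + 1L)
      tn[bj] <- tn[bj] + 1L
    } else {
      tcx <- c(tcx, recs$cx[i]); tcy <- c(tcy, recs$cy[i])
      tn <- c(tn, 1L)
      track[i] <- length(tcx)
    }
  }

  out <- NULL
  for (tr in seq_along(tcx)) {
    sub <- recs[track == tr, , drop = FALSE]
    cnt <- switch(zAgg,
      mean = mean(sub$count),
      max = max(sub$count),
      best_slice = sub$count[which.max(sub$green_sum)])
    row <- data.frame(
      cell_id = sprintf("%s_c%02d", imageId(stack), tr),
      image_id = imageId(stack), dose_gy = doseGy(stack),
      cx = tcx[tr], cy = tcy[tr], n_slices = nrow(sub),
      cell_count = cnt, stringsAsFactors = FALSE)
    row$per_slice <- list(sub$count)
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

#' Mean number of foci per cell
#'
#' Arithmetic mean of the aggregated per-cell counts, optionally restricted
#' to one dose group — the y of every calibration point.
#'
#' @param counts data.frame from [countFociTwoStage()] (or any table with
#'   `cell_count` and optionally `dose_gy`).
#' @param doseGy optional dose filter.
#' @return The mean count (scalar).
#' @export
meanFociPerCell <- function(counts, doseGy = NULL) {
  v <- counts$cell_count
  if (!is.null(doseGy)) v <- v[!is.na(counts$dose_gy) &
                                 counts$dose_gy == doseGy]
  if (length(v) == 0L)
    stop("no cells in the requested group", call. = FALSE)
  mean(v)
}
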