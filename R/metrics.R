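# Scalar IoU on raw coordinates (half-open convention).
.iouNumeric <- function(ax0, ay0, ax1, ay1, bx0, by0, bx1, by1) {
  iw <- min(ax1, bx1) - max(ax0, bx0)
  ih <- min(ay1, by1) - max(ay0, by0)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((ax1 - ax0) * (ay1 - ay0) + (bx1 - bx0) * (by1 - by0) - inter)
}

#' Intersection-over-union of two boxes
#'
#' Area of intersection divided by area of union under the 0-based,
#' half-open coordinate convention, so boxes sharing only an edge have
#' IoU 0. Symmetric; result in \[0, 1\].
#'
#' @param a,b [Box-class] objects.
#' @return IoU in \[0, 1\].
#' @examples
#' boxIoU(Box(0, 0, 10, 10), Box(5, 0, 15, 10))  # 1/3
#' @export
boxIoU <- function(a, b) {
  stopifnot(is(a, "Box"), is(b, "Box"))
  .iouNumeric(a@xmin, a@ymin, a@xmax, a@ymax,
              b@xmin, b@ymin, b@xmax, b@ymax)
}

#' Match detections to ground-truth boxes
#'
#' Greedy one-to-one matching: predictions are taken in descending
#' confidence order and each claims the still-unmatched truth box of
#' highest IoU, provided that IoU reaches `iouMin`. Unclaimed predictions
#' count as false positives, unclaimed truths as false negatives, so
#' `tp + fp` equals the number of predictions and `tp + fn` the number of
#' truths.
#'
#' @param preds detection data.frame (confidence-sorted internally).
#' @param truths data.frame of ground-truth boxes (columns
#'   `x_min, y_min, x_max, y_max`).
#' @param iouMin matching threshold in \[0, 1); default 0.5, the standard
#'   object-detection criterion.
#' @return A [MatchResult-class].
#' @export
matchDetections <- function(preds, truths, iouMin = 0.5) {
  if (length(iouMin) != 1L || !is.finite(iouMin) || iouMin < 0 ||
      iouMin >= 1)
    stop("iouMin must lie in [0, 1)", call. = FALSE)
  nP <- nrow(preds); nT <- nrow(truths)
  pairs <- data.frame(pred = integer(0), truth = integer(0),
                      iou = numeric(0))
  if (nP > 0L && nT > 0L) {
    ord <- order(-preds$confidence)
    used <- logical(nT)
    for (oi in ord) {
      best <- 0; best_j <- 0L
      for (j in seq_len(nT)) {
        if (used[j]) next
        v <- .iouNumeric(preds$x_min[oi], preds$y_min[oi],
                         preds$x_max[oi], preds$y_max[oi],
                         truths$x_min[j], truths$y_min[j],
                         truths$x_max[j], truths$y_max[j])
        if (v > best) { best <- v; best_j <- j }
      }
      if (best_j > 0L && best >= iouMin) {
        used[best_j] <- TRUE
        pairs <- rbind(pairs, data.frame(pred = oi, truth = best_j,
                                         iou = best))
      }
    }
  }
  tp <- nrow(pairs)
  new("MatchResult", tp = as.integer(tp), fp = as.integer(nP - tp),
      fn = as.integer(nT - tp), matchedPairs = pairs)
}

#' Precision, recall and F1
#'
#' The standard detection metrics: `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)` and the F1 score, their harmonic mean
#' `2 P R / (P + R)`. When a denominator is zero the metric is undefined
#' and returned as `NA` (an explicit sentinel, never silently 0).
#' Rounding to the 3 decimals used in printed tables is presentation-only:
#' apply [roundHalfUp()] at the end.
#'
#' @param tp,fp,fn non-negative counts.
#' @param p,r precision and recall in \[0, 1\].
#' @return A value in \[0, 1\], or `NA` when undefined.
#' @examples
#' f1Score(0.924, 0.897)            # 0.9109...
#' roundHalfUp(f1Score(0.924, 0.897), 3)
#' @name detection-metrics
NULL

#' @rdname detection-metrics
#' @export
detectionPrecision <- function(tp, fp) {
  if (tp < 0 || fp < 0) stop("counts must be non-negative", call. = FALSE)
  if (tp + fp == 0) return(NA_real_)
  tp / (tp + fp)
}

#' @rdname detection-metrics
#' @export
detectionRecall <- function(tp, fn) {
  if (tp < 0 || fn < 0) stop("counts must be non-negative", call. = FALSE)
  if (tp + fn == 0) return(NA_real_)
  tp / (tp + fn)
}

#' @rdname detection-metrics
#' @export
f1Score <- function(p, r) {
  if (is.na(p) || is.na(r)) return(NA_real_)
  if (p < 0 || p > 1 || r < 0 || r > 1)
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  if (p + r == 0) return(NA_real_)
  2 * p * r / (p + r)
}

#' Per-dose and pooled detection metrics
#'
#' Pools TP/FP/FN within each dose group and computes precision, recall
#' and F1 per group, plus an `"overall"` row that pools the raw counts
#' across all groups (micro-average). Pooling — rather than averaging the
#' per-group metrics — is the convention used here because group sizes
#' differ.
#'
#' @param matches list of [MatchResult-class] objects (one per image or
#'   crop).
#' @param groups vector of dose labels, one per element of `matches`.
#' @return data.frame with columns `group, tp, fp, fn, precision, recall,
#'   f1`; metrics are `NA` where undefined.
#' @export
evaluateByDose <- function(matches, groups) {
  if (length(matches) == 0L)
    stop("evaluateByDose needs at least one match result", call. = FALSE)
  if (length(groups) != length(matches))
    stop("groups must parallel matches", call. = FALSE)
  tab <- data.frame(
    group = as.character(groups),
    tp = vapply(matches, truePositives, integer(1)),
    fp = vapply(matches, falsePositives, integer(1)),
    fn = vapply(matches, falseNegatives, integer(1)),
    stringsAsFactors = FALSE)
  pool <- function(df, label) {
    tp <- sum(df$tp); fp <- sum(df$fp); fn <- sum(df$fn)
    p <- detectionPrecision(tp, fp); r <- detectionRecall(tp, fn)
    data.frame(group = label, tp = tp, fp = fp, fn = fn,
               precision = p, recall = r, f1 = f1Score(p, r),
               stringsAsFactors = FALSE)
  }
  glev <- unique(tab$group)
  out <- do.call(rbind, lapply(glev, function(g)
    pool(tab[tab$group == g, , drop = FALSE], g)))
  out <- rbind(out, pool(tab, "overall"))
  rownames(out) <- NULL
  out
}
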