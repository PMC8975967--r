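# Internal numeric helpers shared across modules.

# Symmetric (edge-including) padding of a matrix by p rows/cols on each side.
.padReflect <- function(m, p) {
  if (p == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (p > nr || p > nc)
    stop("padding exceeds image size", call. = FALSE)
  ri <- c(p:1, seq_len(nr), nr:(nr - p + 1L))
  ci <- c(p:1, seq_len(nc), nc:(nc - p + 1L))
  m[ri, ci, drop = FALSE]
}

# Sampled, normalised 1-d Gaussian kernel; radius covers +/- 4 sd.
.gaussKernel1d <- function(sd) {
  r <- max(1L, as.integer(ceiling(4 * sd)))
  k <- exp(-((-r):r)^2 / (2 * sd^2))
  k / sum(k)
}

# Separable 2-d convolution with symmetric border handling.
.convSeparable <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  p <- .padReflect(m, r)
  # rows
  acc <- matrix(0, nrow(p), ncol(m))
  for (j in seq_along(k))
    acc <- acc + k[j] * p[, j:(j + ncol(m) - 1L), drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * acc[i:(i + nrow(m) - 1L), , drop = FALSE]
  out
}

.gaussianBlur <- function(m, sd) {
  if (sd <= 0) return(m)
  .convSeparable(m, .gaussKernel1d(sd))
}

# k x k median filter with symmetric border handling. The 3 x 3 case runs
# through a 19-exchange median network on whole matrices; other odd sizes
# fall back to a direct per-pixel sort.
.medianFilter <- function(m, k) {
  if (k == 1L) return(m)
  if (k %% 2L != 1L) stop("median kernel must be odd", call. = FALSE)
  r <- (k - 1L) %/% 2L
  if (k > nrow(m) || k > ncol(m))
    stop("median kernel larger than image", call. = FALSE)
  p <- .padReflect(m, r)
  nr <- nrow(m); nc <- ncol(m)
  win <- vector("list", k * k)
  idx <- 1L
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    win[[idx]] <- p[di:(di + nr - 1L), dj:(dj + nc - 1L), drop = FALSE]
    idx <- idx + 1L
  }
  if (k == 3L) return(.median9(win))
  arr <- vapply(win, as.numeric, numeric(nr * nc))
  matrix(apply(arr, 1L, stats::median), nr, nc)
}

.median9 <- function(w) {
  xch <- function(i, j) {
    lo <- pmin(w[[i]], w[[j]])
    w[[j]] <<- pmax(w[[i]], w[[j]])
    w[[i]] <<- lo
  }
  # Paeth's 19-exchange 9-element median network
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 2); xch(4, 5); xch(7, 8)
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 4); xch(6, 9); xch(5, 8)
  xch(4, 7); xch(2, 5); xch(3, 6)
  xch(5, 8); xch(5, 3); xch(7, 5)
  xch(5, 3)
  w[[5]]
}

# Presentation rounding: half-up at `digits` decimals (so 0.555 -> 0.56),
# the convention used for printed tables.
#' Round half-up for presentation
#'
#' Rounds to `digits` decimals with halves always rounded away from zero,
#' the convention used when printing metric and dose tables (in contrast to
#' [round()]'s round-half-even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(0.5550, 2)   # 0.56
#' round(0.5550, 2)         # 0.55 or 0.56 depending on binary representation
#' @export
roundHalfUp <- function(x, digits = 0L) {
  s <- sign(x)
  # nudge by an ulp-scale epsilon so decimal halves stored just below .5
  # in binary still round up
  s * floor(abs(x) * 10^digits + 0.5 + 1e-9) / 10^digits
}

# Quantise [0,1] intensities to the 16-bit grid (the on-disk depth).
.quantise16 <- function(x) round(x * 65535) / 65535

# Clip into [lo, hi].
.clip <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Empty detection table with the canonical column set.
.emptyDetections <- function() {
  data.frame(image_id = character(0), label = character(0),
              confidence = numeric(0), x_min = numeric(0),
              y_min = numeric(0), x_max = numeric(0), y_max = numeric(0),
              stringsAsFactors = FALSE)
}

.DET_COLS <- c("image_id", "label", "confidence",
               "x_min", "y_min", "x_max", "y_max")
.DET_LABELS <- c("MNC", "focus")

# Validate a detection table (see readAnnotations for the dialect).
.checkDetections <- function(det, where = "detections") {
  if (!is.data.frame(det) || !all(.DET_COLS %in% names(det)))
    stop(sprintf("%s must be a data.frame with columns %s", where,
                 paste(.DET_COLS, collapse = ", ")), call. = FALSE)
  if (nrow(det) == 0L) return(invisible(det))
  bad <- which(!(det$label %in% .DET_LABELS))
  if (length(bad))
    stop(sprintf("%s: invalid label in row %d (must be one of %s)", where,
                 bad[1L], paste(.DET_LABELS, collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(det$confidence) | det$confidence < 0 |
                 det$confidence > 1)
  if (length(bad))
    stop(sprintf("%s: confidence outside [0, 1] in row %d", where, bad[1L]),
         call. = FALSE)
  bad <- which(det$x_min >= det$x_max | det$y_min >= det$y_max)
  if (length(bad))
    stop(sprintf("%s: degenerate box (min >= max) in row %d", where, bad[1L]),
         call. = FALSE)
  invisible(det)
}

# data.frame of boxes -> list of Box objects
.rowsToBoxes <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    Box(df$x_min[i], df$y_min[i], df$x_max[i], df$y_max[i]))
}

# Derive a child RNG seed from a base seed and an index, staying within
# 32-bit integer range.
.childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 100003) %% 2147483647)
}
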