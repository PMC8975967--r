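# Shared fixtures: all test inputs are generated in code, seeded.

# Small deterministic stack on the 16-bit grid (so TIFF roundtrips are
# bit-exact).
tinyStack <- function(seed = 1, nz = 2L, side = 32L, dose = 2) {
  set.seed(seed)
  px <- array(round(runif(3 * nz * side * side) * 65535) / 65535,
              dim = c(3L, nz, side, side))
  ImageStack(px, doseGy = dose, imageId = sprintf("tiny%d", seed))
}

rgbFrom <- function(mat3, id = "img") RGBImage(mat3, imageId = id)

# Clean-limit simulator settings: no noise, no gain variation, no
# distractors, flat z-profile, foci well separated relative to their
# footprint (>= 6 * sigma_max).
cleanConfig <- function(..., seed = 1L) {
  SceneConfig(imageSizePx = c(160L, 160L), nZ = 1L, cellsPerImage = 1L,
              cellsPerDose = 1L, noiseSd = 0, batchGainRange = c(1, 1),
              pmnFraction = 0, zFalloffSdSlices = 1e6,
              focusMinSepPx = 14, seed = seed, ...)
}

# Preprocessing at the 256-scale working geometry.
scaledPre <- function() preprocessParams(gaussianSdPx = 1.25)

# A raw matrix with k planted Gaussian spots; returns list(mat, centres)
# with centres in 0-based (x, y) pixel coordinates.
plantSpots <- function(side, centres, sigma = 1.8, amp = 0.8, bg = 0.02) {
  m <- matrix(bg, side, side)
  for (i in seq_len(nrow(centres))) {
    cx <- centres[i, 1]; cy <- centres[i, 2]
    for (r in seq_len(side)) for (cc in seq_len(side)) {
      d2 <- ((cc - 1) - cx)^2 + ((r - 1) - cy)^2
      m[r, cc] <- m[r, cc] + amp * exp(-d2 / (2 * sigma^2))
    }
  }
  m
}

# Independent maximum-bipartite-matching oracle: maximum number of
# one-to-one pred/truth pairs with IoU >= thr, by exhaustive recursion
# (inputs kept <= 6 boxes).
oracleMaxMatches <- function(preds, truths, thr) {
  nP <- nrow(preds); nT <- nrow(truths)
  if (nP == 0L || nT == 0L) return(0L)
  iou1 <- function(i, j) {
    iw <- min(preds$x_max[i], truths$x_max[j]) -
      max(preds$x_min[i], truths$x_min[j])
    ih <- min(preds$y_max[i], truths$y_max[j]) -
      max(preds$y_min[i], truths$y_min[j])
    if (iw <= 0 || ih <= 0) return(0)
    inter <- iw * ih
    a1 <- (preds$x_max[i] - preds$x_min[i]) *
      (preds$y_max[i] - preds$y_min[i])
    a2 <- (truths$x_max[j] - truths$x_min[j]) *
      (truths$y_max[j] - truths$y_min[j])
    inter / (a1 + a2 - inter)
  }
  ok <- matrix(FALSE, nP, nT)
  for (i in seq_len(nP)) for (j in seq_len(nT)) ok[i, j] <- iou1(i, j) >= thr
  rec <- function(i, used) {
    if (i > nP) return(0L)
    best <- rec(i + 1L, used)           # leave pred i unmatched
    for (j in seq_len(nT)) {
      if (!used[j] && ok[i, j]) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, nT))
}

# Random detection/truth instance for matcher property tests.
randomBoxes <- function(n, span = 100, smin = 8, smax = 26,
                        with_conf = FALSE) {
  x0 <- runif(n, 0, span - smax); y0 <- runif(n, 0, span - smax)
  w <- runif(n, smin, smax); h <- runif(n, smin, smax)
  df <- data.frame(x_min = x0, y_min = y0, x_max = x0 + w, y_max = y0 + h)
  if (with_conf) {
    df$image_id <- rep("r", n); df$label <- rep("focus", n)
    df$confidence <- runif(n)
  }
  df
}
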