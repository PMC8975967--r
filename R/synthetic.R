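#' Sample a per-cell focus count at a given dose
#'
#' Draws the number of gamma-H2AX foci for one cell exposed to `doseGy`.
#' Counts are Poisson with the linear dose-dependent mean
#' `lambda(D) = slopeATrue * D + interceptBTrue`, the standard model for
#' radiation-induced focus formation: tracks through the nucleus are
#' independent and their expected number grows linearly with absorbed dose,
#' on top of a dose-independent background. Uses the current RNG state;
#' seed with [set.seed()] for reproducibility.
#'
#' @param doseGy absorbed dose in Gy (non-negative scalar).
#' @param cfg a [SceneConfig-class] supplying the generating slope and
#'   intercept.
#' @param n number of cells to draw (default 1).
#' @return Integer vector of `n` non-negative counts.
#' @examples
#' set.seed(1)
#' cfg <- SceneConfig()
#' mean(sampleFocusCount(2, cfg, n = 1000))   # near 1.996*2 + 0.769
#' @export
sampleFocusCount <- function(doseGy, cfg, n = 1L) {
  stopifnot(is(cfg, "SceneConfig"))
  if (length(doseGy) != 1L || !is.finite(doseGy) || doseGy < 0)
    stop("doseGy must be a single non-negative dose", call. = FALSE)
  lambda <- cfg@slopeATrue * doseGy + cfg@interceptBTrue
  stats::rpois(n, lambda)
}

# Fill an ellipse (soft edge) into a matrix; returns the updated matrix.
# cx, cy in 0-based pixel coordinates; edge softness in px.
.addEllipse <- function(m, cx, cy, rx, ry, theta, amp, edge = 1.5) {
  nr <- nrow(m); nc <- ncol(m)
  rmax <- max(rx, ry) + 4 * edge
  rows <- max(1L, floor(cy - rmax + 1)):min(nr, ceiling(cy + rmax + 1))
  cols <- max(1L, floor(cx - rmax + 1)):min(nc, ceiling(cx + rmax + 1))
  y <- (rows - 1) - cy
  x <- (cols - 1) - cx
  # rotated normalised radius on the local grid
  X <- matrix(rep(x, each = length(y)), length(y), length(x))
  Y <- matrix(rep(y, times = length(x)), length(y), length(x))
  u <- (X * cos(theta) + Y * sin(theta)) / rx
  v <- (-X * sin(theta) + Y * cos(theta)) / ry
  r <- sqrt(u^2 + v^2)
  prof <- amp / (1 + exp((r - 1) * max(rx, ry) / edge))
  m[rows, cols] <- m[rows, cols] + prof
  m
}

# Add an annular ring (between radius scale 1 and 1 + w/r) around an
# ellipse outline.
.addRing <- function(m, cx, cy, rx, ry, theta, width, amp, edge = 1.0) {
  outer_m <- .addEllipse(matrix(0, nrow(m), ncol(m)), cx, cy,
                         rx + width, ry + width, theta, amp, edge)
  inner_m <- .addEllipse(matrix(0, nrow(m), ncol(m)), cx, cy,
                         rx, ry, theta, amp, edge)
  m + pmax(outer_m - inner_m, 0)
}

# Add a 2-d Gaussian spot of peak amplitude amp, sd sigma, at (cx, cy).
.addGaussianSpot <- function(m, cx, cy, sigma, amp) {
  nr <- nrow(m); nc <- ncol(m)
  r <- ceiling(4 * sigma)
  rows <- max(1L, floor(cy - r + 1)):min(nr, ceiling(cy + r + 1))
  cols <- max(1L, floor(cx - r + 1)):min(nc, ceiling(cx + r + 1))
  y <- (rows - 1) - cy
  x <- (cols - 1) - cx
  g <- amp * exp(-outer(y^2, x^2, "+") / (2 * sigma^2))
  m[rows, cols] <- m[rows, cols] + g
  m
}

# Dart-throwing placement of k focus centres inside an ellipse with a
# preferred minimum separation; the separation is halved after repeated
# failures so crowded nuclei (high dose) produce overlapping foci rather
# than failing.
.placeFoci <- function(k, cx, cy, rx, ry, theta, margin, min_sep) {
  if (k == 0L) return(matrix(numeric(0), 0L, 2L))
  pts <- matrix(NA_real_, k, 2L)
  placed <- 0L
  sep <- min_sep
  fails <- 0L
  while (placed < k) {
    u <- sqrt(stats::runif(1)); a <- stats::runif(1, 0, 2 * pi)
    ex <- u * cos(a) * max(rx - margin, 1)
    ey <- u * sin(a) * max(ry - margin, 1)
    px <- cx + ex * cos(theta) - ey * sin(theta)
    py <- cy + ex * sin(theta) + ey * cos(theta)
    ok <- placed == 0L ||
      all((pts[seq_len(placed), 1L] - px)^2 +
            (pts[seq_len(placed), 2L] - py)^2 >= sep^2)
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- c(px, py)
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails > 50L) { sep <- sep / 2; fails <- 0L }
    }
  }
  pts
}

#' Render one synthetic confocal scene with exact ground truth
#'
#' Draws a frame of non-overlapping cells at the given dose: each
#' mononuclear cell is a filled ellipse in the nucleus (blue) channel with
#' a bright CD45 ring in the red channel; polymorphonuclear distractors
#' (expected `pmnFraction` per cell) get a multi-lobed nucleus and a dim
#' CD45 ring and carry no ground-truth cell box. Per-cell focus counts are
#' drawn by [sampleFocusCount()]; each focus is a 2-d Gaussian in the green
#' channel placed inside the nucleus respecting `focusMinSepPx` when
#' feasible. A focus has a continuous focal depth: away from its own plane
#' its amplitude falls off as a Gaussian in z (`zFalloffSdSlices`) and its
#' footprint blurs slightly. Finally a per-scene multiplicative gain
#' (batch effect) and additive Gaussian noise are applied, and intensities
#' are clipped and quantised to the on-disk 16-bit grid.
#'
#' Ground-truth focus boxes are squares of side `2 * ceiling(2 * sigma)`
#' centred on each planted peak.
#'
#' @param doseGy dose in Gy for every cell in the frame.
#' @param cfg a [SceneConfig-class].
#' @param seed RNG seed for this scene (default `cfg@seed`).
#' @param nCells number of mononuclear cells (default `cfg@cellsPerImage`).
#' @param imageId identifier stored in the stack.
#' @return A [GroundTruthScene-class].
#' @examples
#' sc <- renderScene(2, SceneConfig(cellsPerDose = 4L), seed = 11)
#' trueCounts(sc)
#' @export
renderScene <- function(doseGy, cfg, seed = cfg@seed,
                        nCells = cfg@cellsPerImage, imageId = "scene") {
  stopifnot(is(cfg, "SceneConfig"))
  if (length(doseGy) != 1L || !is.finite(doseGy) || doseGy < 0)
    stop("doseGy must be a single non-negative dose", call. = FALSE)
  nCells <- as.integer(nCells)
  if (nCells < 1L) stop("nCells must be >= 1", call. = FALSE)
  nr <- cfg@imageSizePx[1L]; nc <- cfg@imageSizePx[2L]
  rmax <- cfg@nucleusRadiusPx[2L]
  ringW <- max(2, round(rmax / 6))
  border <- rmax + ringW + 4
  if (2 * border >= min(nr, nc))
    stop("configuration error: nucleus cannot fit in the image", call. = FALSE)

  set.seed(seed)
  nPmn <- stats::rbinom(1L, nCells, cfg@pmnFraction)
  nTotal <- nCells + nPmn
  isPmnAll <- c(rep(FALSE, nCells), rep(TRUE, nPmn))

  # sample each cell's geometry first, then place cells so that their
  # ground-truth boxes stay disjoint (with a small gap); distractors that
  # do not fit are dropped, missing mononuclear cells are an error
  geom <- data.frame(rx = stats::runif(nTotal, cfg@nucleusRadiusPx[1L],
                                       cfg@nucleusRadiusPx[2L]),
                     ry = stats::runif(nTotal, cfg@nucleusRadiusPx[1L],
                                       cfg@nucleusRadiusPx[2L]),
                     th = stats::runif(nTotal, 0, pi))
  geom$ex <- sqrt((geom$rx * cos(geom$th))^2 +
                    (geom$ry * sin(geom$th))^2) + ringW + 1
  geom$ey <- sqrt((geom$rx * sin(geom$th))^2 +
                    (geom$ry * cos(geom$th))^2) + ringW + 1
  centres <- matrix(NA_real_, nTotal, 2L)
  keep <- logical(nTotal)
  gap <- 3
  for (i in seq_len(nTotal)) {
    placedIdx <- which(keep)
    for (tries in seq_len(2000L)) {
      px <- stats::runif(1, border, nc - 1 - border)
      py <- stats::runif(1, border, nr - 1 - border)
      ok <- TRUE
      for (j in placedIdx) {
        if (abs(px - centres[j, 1L]) <
              geom$ex[i] + geom$ex[j] + gap &&
            abs(py - centres[j, 2L]) <
              geom$ey[i] + geom$ey[j] + gap) { ok <- FALSE; break }
      }
      if (ok) { centres[i, ] <- c(px, py); keep[i] <- TRUE; break }
    }
    if (!keep[i] && !isPmnAll[i])
      stop("configuration error: cannot place all cells without overlap",
           call. = FALSE)
  }
  centres <- centres[keep, , drop = FALSE]
  geom <- geom[keep, , drop = FALSE]
  isPmn <- isPmnAll[keep]
  nTotal <- sum(keep)

  blue <- matrix(0, nr, nc); green <- matrix(0, nr, nc)
  red <- matrix(0, nr, nc)
  zprof <- array(0, dim = c(cfg@nZ, nr, nc))  # green varies across z
  mnc <- data.frame(x_min = numeric(0), y_min = numeric(0),
                    x_max = numeric(0), y_max = numeric(0))
  fociB <- list(); counts <- integer(0)

  for (i in seq_len(nTotal)) {
    cx <- centres[i, 1L]; cy <- centres[i, 2L]
    rx <- geom$rx[i]; ry <- geom$ry[i]; th <- geom$th[i]
    if (!isPmn[i]) {
      blue <- .addEllipse(blue, cx, cy, rx, ry, th, 0.65)
      red <- .addRing(red, cx, cy, rx, ry, th, ringW, 0.75)
      red <- .addEllipse(red, cx, cy, rx, ry, th, 0.10)
      k <- sampleFocusCount(doseGy, cfg)
      sig <- stats::runif(k, cfg@focusSigmaPx[1L], cfg@focusSigmaPx[2L])
      marg <- if (k > 0L) max(2 * max(sig), 3) else 3
      pts <- .placeFoci(k, cx, cy, rx, ry, th, marg, cfg@focusMinSepPx)
      boxes <- data.frame(x_min = numeric(0), y_min = numeric(0),
                          x_max = numeric(0), y_max = numeric(0))
      if (k > 0L) {
        amp <- stats::runif(k, 0.6, 0.9)
        zc <- stats::runif(k, 1, cfg@nZ)
        for (j in seq_len(k)) {
          for (z in seq_len(cfg@nZ)) {
            dz <- z - zc[j]
            az <- amp[j] * exp(-dz^2 / (2 * cfg@zFalloffSdSlices^2))
            sz <- sig[j] * sqrt(1 + 0.1 * dz^2)
            zprof[z, , ] <- .addGaussianSpot(zprof[z, , ], pts[j, 1L],
                                             pts[j, 2L], sz, az)
          }
        }
        h <- ceiling(2 * sig)
        boxes <- data.frame(x_min = round(pts[, 1L]) - h,
                            y_min = round(pts[, 2L]) - h,
                            x_max = round(pts[, 1L]) + h,
                            y_max = round(pts[, 2L]) + h)
      }
      # cell box: nucleus extent plus CD45 ring, clipped to the frame
      ex <- geom$ex[i]; ey <- geom$ey[i]
      mnc <- rbind(mnc, data.frame(
        x_min = max(0, floor(cx - ex)), y_min = max(0, floor(cy - ey)),
        x_max = min(nc, ceiling(cx + ex)), y_max = min(nr, ceiling(cy + ey))))
      fociB[[length(fociB) + 1L]] <- boxes
      counts <- c(counts, k)
    } else {
      # polymorphonuclear distractor: 2-3 nuclear lobes, dim CD45
      nl <- sample(2:3, 1L)
      for (l in seq_len(nl)) {
        lth <- stats::runif(1, 0, 2 * pi)
        off <- stats::runif(1, 0.35, 0.6) * rx
        blue <- .addEllipse(blue, cx + off * cos(lth), cy + off * sin(lth),
                            rx * 0.55, ry * 0.55, stats::runif(1, 0, pi),
                            0.6)
      }
      red <- .addRing(red, cx, cy, rx, ry, th, ringW, 0.08)
    }
  }

  gain <- stats::runif(1, cfg@batchGainRange[1L], cfg@batchGainRange[2L])
  bg <- 0.02
  px <- array(0, dim = c(3L, cfg@nZ, nr, nc))
  for (z in seq_len(cfg@nZ)) {
    ch <- list(blue, zprof[z, , ], red)
    for (ci in 1:3) {
      m <- (ch[[ci]] + bg) * gain
      if (cfg@noiseSd > 0)
        m <- m + matrix(stats::rnorm(nr * nc, sd = cfg@noiseSd), nr, nc)
      # storage order nucleus, foci, cd45
      tgt <- c(1L, 2L, 3L)[ci]
      px[tgt, z, , ] <- .quantise16(.clip(m))
    }
  }
  stack <- ImageStack(px, pixelSizeUm = 0.5, zStepUm = 0.6,
                      doseGy = doseGy, imageId = imageId)
  new("GroundTruthScene", stack = stack, mncBoxes = mnc, fociBoxes = fociB,
      trueCounts = counts, doseGy = doseGy)
}

#' Generate a full synthetic dataset on disk
#'
#' Renders `cellsPerDose` mononuclear cells per dose group (split across
#' frames of `cellsPerImage` cells), writing one TIFF stack + JSON sidecar
#' per frame, a ground-truth `scenes.json` and a `manifest.csv` listing
#' image id, file, dose and cell count. Fully reproducible: every scene
#' seed is a deterministic function of `cfg@seed`.
#'
#' @param cfg a [SceneConfig-class].
#' @param outDir output directory (created if needed).
#' @param overwrite if `FALSE` (default), refuse to clobber an existing
#'   `manifest.csv`.
#' @return Invisibly, a list with `manifest` (data.frame), `scenesPath`,
#'   and `dir`.
#' @export
generateDataset <- function(cfg, outDir, overwrite = FALSE) {
  stopifnot(is(cfg, "SceneConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  manPath <- file.path(outDir, "manifest.csv")
  if (file.exists(manPath) && !overwrite)
    stop(sprintf("manifest already exists in %s (use overwrite = TRUE)",
                 outDir), call. = FALSE)
  manifest <- NULL
  truth <- list()
  for (di in seq_along(cfg@dosesGy)) {
    d <- cfg@dosesGy[di]
    left <- cfg@cellsPerDose
    si <- 0L
    while (left > 0L) {
      si <- si + 1L
      nc_img <- min(cfg@cellsPerImage, left)
      left <- left - nc_img
      id <- sprintf("d%02d_s%03d", di, si)
      sc <- renderScene(d, cfg, seed = .childSeed(cfg@seed, di * 10000L + si),
                        nCells = nc_img, imageId = id)
      f <- file.path(outDir, paste0(id, ".tif"))
      writeStack(sc@stack, f)
      manifest <- rbind(manifest, data.frame(
        image_id = id, file = basename(f), dose_gy = d, n_cells = nc_img,
        stringsAsFactors = FALSE))
      sc@stack <- ImageStack(array(0, c(3, 1, 16, 16)), imageId = id)
      truth[[length(truth) + 1L]] <- sc
    }
  }
  utils::write.csv(manifest, manPath, row.names = FALSE)
  scPath <- file.path(outDir, "scenes.json")
  writeScenes(truth, scPath)
  invisible(list(manifest = manifest, scenesPath = scPath, dir = outDir))
}
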