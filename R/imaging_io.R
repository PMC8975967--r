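#' Read a confocal z-stack from a multi-page TIFF
#'
#' Reads a 3-channel z-stack written by [writeStack()]: a multi-page TIFF
#' holding one page per channel x slice in channel-major order (all slices
#' of channel 1, then channel 2, then channel 3), plus a JSON metadata
#' sidecar (`<path>.json`) carrying pixel size, z step, dose label, image id
#' and channel names. When the sidecar is absent, canonical channel names
#' and default geometry are assumed and the page count must be divisible
#' by 3.
#'
#' Pixels are stored on disk at 16-bit depth; in memory they are doubles on
#' the \[0, 1\] scale, and a write/read cycle is bit-exact.
#'
#' @param path path to the TIFF file.
#' @return An [ImageStack-class].
#' @seealso [writeStack()], [mergeRGB()]
#' @examples
#' s <- ImageStack(array(0.5, dim = c(3, 2, 32, 32)), imageId = "demo")
#' p <- tempfile(fileext = ".tif")
#' writeStack(s, p)
#' identical(pixels(readStack(p)), pixels(s))
#' @export
readStack <- function(path) {
  if (!file.exists(path))
    stop(sprintf("stack file not found: %s", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    meta <- list()
  }
  nC <- if (!is.null(meta$n_channels)) as.integer(meta$n_channels) else 3L
  if (nC != 3L)
    stop(sprintf(
      "format error: channel axis has %d channel(s); 3 are required", nC),
      call. = FALSE)
  if (length(pages) %% nC != 0L)
    stop(sprintf(
      "format error: %d page(s) not divisible into %d channel(s) (z axis)",
      length(pages), nC), call. = FALSE)
  nZ <- length(pages) %/% nC
  nr <- nrow(pages[[1L]]); nc <- ncol(pages[[1L]])
  px <- array(0, dim = c(nC, nZ, nr, nc))
  idx <- 1L
  for (ch in seq_len(nC)) for (z in seq_len(nZ)) {
    pg <- pages[[idx]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # tolerate grey-as-RGB
    px[ch, z, , ] <- pg
    idx <- idx + 1L
  }
  ImageStack(
    px,
    channelNames = if (!is.null(meta$channel_names))
      as.character(meta$channel_names) else .CANONICAL_CHANNELS,
    pixelSizeUm = if (!is.null(meta$pixel_size_um)) meta$pixel_size_um
      else 0.124,
    zStepUm = if (!is.null(meta$z_step_um)) meta$z_step_um else 0.6,
    doseGy = if (!is.null(meta$dose_gy) && !is.na(meta$dose_gy))
      meta$dose_gy else NA_real_,
    imageId = if (!is.null(meta$image_id)) meta$image_id
      else tools::file_path_sans_ext(basename(path))
  )
}

#' Write a confocal z-stack as a multi-page TIFF with JSON sidecar
#'
#' Inverse of [readStack()]. Pages are written in channel-major order at
#' 16-bit depth; metadata goes to `<path>.json`. Intensities are quantised
#' to the 16-bit grid on write, so a stack whose values already lie on that
#' grid (all simulator output does) round-trips bit-exactly.
#'
#' @param stack an [ImageStack-class].
#' @param path output TIFF path; an existing file is replaced.
#' @return Invisibly, `path`.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("output directory does not exist: %s", dir), call. = FALSE)
  d <- dim(stack@pixels)
  pages <- vector("list", d[1L] * d[2L])
  idx <- 1L
  for (ch in seq_len(d[1L])) for (z in seq_len(d[2L])) {
    pages[[idx]] <- .quantise16(.clip(stack@pixels[ch, z, , ]))
    idx <- idx + 1L
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("could not write TIFF to %s", path), call. = FALSE)
  meta <- list(
    image_id = stack@imageId,
    pixel_size_um = stack@pixelSizeUm,
    z_step_um = stack@zStepUm,
    dose_gy = if (is.na(stack@doseGy)) NULL else stack@doseGy,
    channel_names = as.list(stack@channelNames),
    n_channels = d[1L],
    n_z = d[2L]
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Merge the three channels of one slice into an RGB image
#'
#' Produces the display-order merge used throughout the workflow:
#' R = CD45 surface marker, G = gamma-H2AX foci, B = nucleus. Channels are
#' located by name, so the result does not depend on the storage order of
#' the channels in the stack. Values are clipped to \[0, 1\].
#'
#' @param stack an [ImageStack-class] with the canonical channel triple.
#' @param z 1-based slice index.
#' @return An [RGBImage-class]; its G plane equals the foci channel of
#'   slice `z` exactly.
#' @export
mergeRGB <- function(stack, z) {
  stopifnot(is(stack, "ImageStack"))
  nz <- nSlices(stack)
  if (length(z) != 1L || z < 1L || z > nz)
    stop(sprintf("slice index %s out of range [1, %d]", format(z), nz),
         call. = FALSE)
  cn <- stack@channelNames
  if (!all(.CANONICAL_CHANNELS %in% cn))
    stop("stack must carry the canonical channels nucleus/foci/cd45",
         call. = FALSE)
  d <- imageDim(stack)
  px <- array(0, dim = c(d[1L], d[2L], 3L))
  px[, , 1L] <- stack@pixels[match("cd45", cn), z, , ]
  px[, , 2L] <- stack@pixels[match("foci", cn), z, , ]
  px[, , 3L] <- stack@pixels[match("nucleus", cn), z, , ]
  RGBImage(.clip(px), imageId = stack@imageId, zIndex = z)
}

#' Read box annotations from CSV
#'
#' The annotation dialect is a flat CSV with one box per row and columns
#' `image_id, label, confidence, x_min, y_min, x_max, y_max`. Labels come
#' from the closed set `MNC` / `focus`; confidences lie in \[0, 1\]; box
#' coordinates are 0-based, half-open pixels. [writeAnnotations()] inverts
#' it losslessly.
#'
#' @param path CSV path.
#' @return A detection data.frame with the columns above (possibly 0 rows).
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path))
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  det <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(image_id = "character",
                                        label = "character"))
  if (nrow(det) == 0L) return(.emptyDetections())
  miss <- setdiff(.DET_COLS, names(det))
  if (length(miss))
    stop(sprintf("parse error: missing column(s) %s in %s",
                 paste(miss, collapse = ", "), path), call. = FALSE)
  num_cols <- c("confidence", "x_min", "y_min", "x_max", "y_max")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(det[[cc]]))
    bad <- which(is.na(v) & !is.na(det[[cc]]))
    if (length(bad))
      stop(sprintf("parse error in %s row %d: column %s is not numeric",
                   path, bad[1L], cc), call. = FALSE)
    det[[cc]] <- v
  }
  .checkDetections(det[, .DET_COLS], where = path)
  det[, .DET_COLS]
}

#' Write box annotations to CSV
#'
#' @param det detection data.frame (see [readAnnotations()] for the
#'   dialect).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeAnnotations <- function(det, path) {
  .checkDetections(det, where = "det")
  utils::write.csv(det[, .DET_COLS, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

# ---- ground-truth scenes JSON dialect ---------------------------------

.boxesToRecords <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    list(x_min = df$x_min[i], y_min = df$y_min[i],
         x_max = df$x_max[i], y_max = df$y_max[i]))
}

.recordsToBoxes <- function(recs) {
  if (length(recs) == 0L)
    return(data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0)))
  do.call(rbind, lapply(recs, function(r)
    data.frame(x_min = r$x_min, y_min = r$y_min,
               x_max = r$x_max, y_max = r$y_max)))
}

#' Write ground-truth scenes to JSON
#'
#' Serialises the ground truth of a list of [GroundTruthScene-class]
#' objects (boxes, counts, dose labels — not the pixels, which live in the
#' TIFFs) to a single JSON file.
#'
#' @param scenes list of [GroundTruthScene-class] objects.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @seealso [readScenes()]
#' @export
writeScenes <- function(scenes, path) {
  recs <- lapply(scenes, function(sc) {
    stopifnot(is(sc, "GroundTruthScene"))
    list(
      image_id = sc@stack@imageId,
      dose_gy = sc@doseGy,
      mnc_boxes = .boxesToRecords(sc@mncBoxes),
      foci_boxes_per_cell = lapply(sc@fociBoxes, .boxesToRecords),
      true_counts = as.list(sc@trueCounts)
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground-truth scenes from JSON
#'
#' @param path JSON path written by [writeScenes()].
#' @return A list with one element per scene, each a list with fields
#'   `image_id`, `dose_gy`, `mnc_boxes` (data.frame),
#'   `foci_boxes_per_cell` (list of data.frames) and `true_counts`
#'   (integer vector).
#' @export
readScenes <- function(path) {
  if (!file.exists(path))
    stop(sprintf("scenes file not found: %s", path), call. = FALSE)
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    list(
      image_id = r$image_id,
      dose_gy = as.numeric(r$dose_gy),
      mnc_boxes = .recordsToBoxes(r$mnc_boxes),
      foci_boxes_per_cell = lapply(r$foci_boxes_per_cell, .recordsToBoxes),
      true_counts = as.integer(unlist(r$true_counts, use.names = FALSE))
    )
  })
}
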