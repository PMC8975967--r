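test_that("stack write/read round-trips pixels and metadata bit-exactly", {
  s <- tinyStack(seed = 3, nz = 5L, side = 64L, dose = 4)
  p <- withr::local_tempfile(fileext = ".tif")
  writeStack(s, p)
  s2 <- readStack(p)
  expect_identical(pixels(s2), pixels(s))
  expect_identical(dim(pixels(s2)), c(3L, 5L, 64L, 64L))
  expect_equal(doseGy(s2), 4)
  expect_equal(imageId(s2), imageId(s))
  expect_equal(channelNames(s2), channelNames(s))
  expect_equal(s2@pixelSizeUm, s@pixelSizeUm)

  # overwrite replaces contents
  s3 <- tinyStack(seed = 9, nz = 5L, side = 64L)
  writeStack(s3, p)
  expect_identical(pixels(readStack(p)), pixels(s3))
})

test_that("stack reading rejects missing files and non-3-channel input", {
  expect_error(readStack(file.path(tempdir(), "nope.tif")), "not found")

  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 32, 32), matrix(0.2, 32, 32)), p,
                  bits.per.sample = 16L)
  jsonlite::write_json(list(n_channels = 2L), paste0(p, ".json"),
                       auto_unbox = TRUE)
  expect_error(readStack(p), "channel")

  # without sidecar, page count must split into 3 channels
  p2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 32, 32), matrix(0.2, 32, 32)), p2,
                  bits.per.sample = 16L)
  expect_error(readStack(p2), "format error")
})

test_that("mergeRGB maps channels by name with G = foci exactly", {
  s <- tinyStack(seed = 5, nz = 3L)
  img <- mergeRGB(s, 2)
  expect_identical(pixels(img)[, , 2L], pixels(s)[2, 2, , ])
  expect_identical(pixels(img)[, , 1L], pixels(s)[3, 2, , ])
  expect_identical(pixels(img)[, , 3L], pixels(s)[1, 2, , ])
  expect_error(mergeRGB(s, 0), "out of range")
  expect_error(mergeRGB(s, 4), "out of range")

  # permuting channel storage while renaming accordingly changes nothing
  perm <- c(2L, 3L, 1L)
  s_perm <- ImageStack(pixels(s)[perm, , , , drop = FALSE],
                       channelNames = channelNames(s)[perm],
                       doseGy = doseGy(s), imageId = imageId(s))
  expect_identical(pixels(mergeRGB(s_perm, 2)), pixels(img))

  # zero cd45 and nucleus channels give R = B = 0, G = foci plane
  px <- pixels(s)
  px[c(1, 3), , , ] <- 0
  s0 <- ImageStack(px, imageId = "z")
  img0 <- mergeRGB(s0, 1)
  expect_true(all(pixels(img0)[, , c(1L, 3L)] == 0))
  expect_identical(pixels(img0)[, , 2L], px[2, 1, , ])
})

test_that("extract/merge composition returns the foci plane elementwise", {
  s <- tinyStack(seed = 7, nz = 4L)
  for (z in c(1L, 4L))
    expect_identical(extractGreen(mergeRGB(s, z)), pixels(s)[2, z, , ])
})

test_that("annotation CSV round-trips and validates its rows", {
  p <- withr::local_tempfile(fileext = ".csv")

  # empty table
  writeAnnotations(
    data.frame(image_id = character(0), label = character(0),
               confidence = numeric(0), x_min = numeric(0),
               y_min = numeric(0), x_max = numeric(0),
               y_max = numeric(0)), p)
  expect_equal(nrow(readAnnotations(p)), 0L)

  det <- data.frame(
    image_id = c("a", "a", "b"), label = c("MNC", "focus", "focus"),
    confidence = c(0.9, 0.5, 1),
    x_min = c(0, 10.5, 3), y_min = c(0, 4, 2),
    x_max = c(20, 14.5, 9), y_max = c(18, 8, 6),
    stringsAsFactors = FALSE)
  writeAnnotations(det, p)
  back <- readAnnotations(p)
  expect_equal(back, det)

  bad <- det; bad$confidence[2] <- 1.5
  utils::write.csv(bad, p, row.names = FALSE)
  expect_error(readAnnotations(p), "confidence.*row 2")

  bad2 <- det; bad2$x_min[3] <- 99
  utils::write.csv(bad2, p, row.names = FALSE)
  expect_error(readAnnotations(p), "row 3")

  bad3 <- det; bad3$x_max <- as.character(bad3$x_max); bad3$x_max[1] <- "wide"
  utils::write.csv(bad3, p, row.names = FALSE)
  expect_error(readAnnotations(p), "row 1.*x_max|x_max.*row 1")
})

test_that("ground-truth scenes JSON round-trips boxes and counts", {
  sc <- renderScene(1, cleanConfig(), seed = 21, nCells = 1, imageId = "s1")
  sc2 <- renderScene(0, cleanConfig(), seed = 22, nCells = 1, imageId = "s2")
  p <- withr::local_tempfile(fileext = ".json")
  writeScenes(list(sc, sc2), p)
  back <- readScenes(p)
  expect_length(back, 2L)
  expect_equal(back[[1]]$image_id, "s1")
  expect_equal(back[[1]]$dose_gy, 1)
  expect_equal(back[[1]]$mnc_boxes, mncBoxes(sc))
  expect_equal(back[[1]]$true_counts, trueCounts(sc))
  expect_equal(nrow(back[[1]]$foci_boxes_per_cell[[1]]),
               trueCounts(sc)[1])
  if (trueCounts(sc)[1] > 0)
    expect_equal(back[[1]]$foci_boxes_per_cell[[1]],
                 fociBoxes(sc)[[1]])
})

test_that("degenerate containers are rejected by class validity", {
  expect_error(Box(5, 0, 5, 10), "xmin < xmax")
  expect_error(ImageStack(array(0, c(2, 1, 32, 32))), "channel")
  expect_error(ImageStack(array(-1, c(3, 1, 32, 32))), "finite")
  expect_error(RGBImage(array(2, c(8, 8, 3))), "0, 1")
})
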