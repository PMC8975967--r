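test_that("MNC detection finds clean cells and ignores blanks", {
  blank <- rgbFrom(array(0.02, c(64, 64, 3)))
  expect_equal(nrow(detectMNC(blank)), 0L)
  expect_error(detectMNC(matrix(0, 16, 16)), "format error")

  for (seed in c(41, 42)) {
    sc <- renderScene(1, cleanConfig(), seed = seed, nCells = 1)
    img <- preprocessPipeline(mergeRGB(gtStack(sc), 1), scaledPre())
    det <- detectMNC(img)
    expect_equal(nrow(det), 1L)
    mb <- mncBoxes(sc)
    gcx <- (mb$x_min[1] + mb$x_max[1]) / 2
    gcy <- (mb$y_min[1] + mb$y_max[1]) / 2
    expect_true(det$x_min[1] <= gcx && gcx <= det$x_max[1] &&
                  det$y_min[1] <= gcy && gcy <= det$y_max[1])
    expect_true(det$confidence[1] > 0 && det$confidence[1] <= 1)
  }
})

test_that("the CD45 gate separates mononuclear cells from distractors", {
  # pmnFraction = 1 plants one dim-CD45 multi-lobed distractor per cell
  cfg <- cleanConfig(seed = 1L)
  cfg@pmnFraction <- 1
  cfg@imageSizePx <- c(220L, 220L)
  found <- 0L
  for (seed in c(51, 52, 53)) {
    sc <- renderScene(0, cfg, seed = seed, nCells = 1)
    img <- preprocessPipeline(mergeRGB(gtStack(sc), 1), scaledPre())
    det <- detectMNC(img)
    expect_lte(nrow(det), 1L)   # distractor never passes the gate
    if (nrow(det) == 1L) {
      mb <- mncBoxes(sc)
      ov <- boxIoU(Box(det$x_min, det$y_min, det$x_max, det$y_max),
                   Box(mb$x_min[1], mb$y_min[1], mb$x_max[1], mb$y_max[1]))
      expect_gt(ov, 0.5)
      found <- found + 1L
    }
  }
  expect_gte(found, 2L)  # gate rejects distractors, not the cells
})

test_that("cell cropping slices the exact rectangles with provenance", {
  set.seed(15)
  a <- array(runif(40 * 40 * 3), c(40, 40, 3))
  img <- rgbFrom(a, id = "crops")
  full <- data.frame(image_id = "crops", label = "MNC", confidence = 1,
                     x_min = 0, y_min = 0, x_max = 40, y_max = 40)
  cr <- cropCells(img, full, margin = 0L)
  expect_length(cr, 1L)
  expect_identical(cr[[1]]$pixels, a)

  sub <- data.frame(image_id = "crops", label = "MNC", confidence = 1,
                    x_min = 10, y_min = 10, x_max = 20, y_max = 20)
  cr2 <- cropCells(img, sub, margin = 0L)
  expect_identical(cr2[[1]]$pixels, a[11:20, 11:20, , drop = FALSE])
  expect_equal(cr2[[1]]$parentImageId, "crops")

  corner <- data.frame(image_id = "crops", label = "MNC", confidence = 1,
                       x_min = 0, y_min = 0, x_max = 8, y_max = 8)
  cr3 <- cropCells(img, corner, margin = 5L)
  d <- dim(cr3[[1]]$pixels)
  expect_true(all(d[1:2] <= 8 + 2 * 5))
  expect_identical(cr3[[1]]$pixels, a[1:13, 1:13, , drop = FALSE])

  expect_length(cropCells(img, focidose:::.emptyDetections()), 0L)
})

test_that("focus detection recovers well-separated planted spots", {
  expect_equal(nrow(detectFoci(matrix(0, 32, 32))), 0L)

  centres <- rbind(c(10, 10), c(10, 34), c(34, 10), c(34, 34), c(22, 22))
  m <- plantSpots(48, centres, sigma = 1.8)
  det <- detectFoci(m)
  expect_equal(nrow(det), 5L)
  for (i in seq_len(5)) {
    inside <- det$x_min <= centres[i, 1] & centres[i, 1] <= det$x_max &
      det$y_min <= centres[i, 2] & centres[i, 2] <= det$y_max
    expect_true(any(inside))
  }
  expect_true(all(diff(det$confidence) <= 0))  # sorted descending
  expect_true(all(det$x_min >= 0 & det$x_max <= 48 &
                    det$y_min >= 0 & det$y_max <= 48))

  # determinism
  expect_identical(detectFoci(m), det)
})

test_that("merged foci at sub-sigma separation collapse towards one spot", {
  sep <- 0.9   # sigma / 2 with sigma = 1.8
  m <- plantSpots(32, rbind(c(15, 15), c(15 + sep, 15)), sigma = 1.8)
  det <- detectFoci(m)
  expect_gte(nrow(det), 1L)
  expect_lte(nrow(det), 2L)
})

test_that("two-stage counting matches planted counts on clean stacks", {
  cfg <- cleanConfig(seed = 3L)
  cfg@nZ <- 3L
  for (seed in c(61, 62, 63)) {
    sc <- renderScene(2, cfg, seed = seed, nCells = 1)
    for (agg in c("mean", "max", "best_slice")) {
      cc <- countFociTwoStage(gtStack(sc), preParams = scaledPre(),
                              zAgg = agg)
      expect_equal(nrow(cc), 1L)
      expect_equal(cc$cell_count, as.numeric(trueCounts(sc)))
      expect_equal(cc$n_slices, 3L)
    }
  }

  blank <- ImageStack(array(0.02, c(3, 2, 64, 64)), imageId = "blank")
  expect_equal(nrow(countFociTwoStage(blank, preParams = scaledPre())), 0L)
})

test_that("z aggregation follows the configured rule via stub backends", {
  stack <- tinyStack(seed = 16, nz = 5L, side = 48L, dose = NA_real_)
  oneCell <- function(img, params) data.frame(
    image_id = "t", label = "MNC", confidence = 1,
    x_min = 8, y_min = 8, x_max = 40, y_max = 40,
    stringsAsFactors = FALSE)
  slice_counts <- c(3L, 4L, 4L, 4L, 5L)
  calls <- new.env(); calls$i <- 0L
  countingStub <- function(green, params) {
    calls$i <- calls$i + 1L
    k <- slice_counts[calls$i]
    if (k == 0L) return(focidose:::.emptyDetections())
    data.frame(image_id = "t", label = "focus", confidence = 1,
               x_min = seq_len(k), y_min = 1, x_max = seq_len(k) + 2,
               y_max = 3, stringsAsFactors = FALSE)
  }
  run <- function(agg) {
    calls$i <- 0L
    countFociTwoStage(stack, preParams = scaledPre(), zAgg = agg,
                      mncBackend = oneCell, fociBackend = countingStub)
  }
  expect_equal(run("mean")$cell_count, 4)
  expect_equal(run("max")$cell_count, 5)

  # a failing backend is wrapped with stage context
  boom <- function(green, params) stop("boom")
  expect_error(
    countFociTwoStage(stack, preParams = scaledPre(),
                      mncBackend = oneCell, fociBackend = boom),
    "stage2.*z 1")
})

test_that("meanFociPerCell averages per group and rejects empty groups", {
  counts <- data.frame(cell_count = c(2, 2, 2), dose_gy = c(1, 1, 2))
  expect_equal(meanFociPerCell(counts), 2)
  counts2 <- data.frame(cell_count = c(0, 4), dose_gy = c(1, 1))
  expect_equal(meanFociPerCell(counts2), 2)
  expect_equal(meanFociPerCell(counts, doseGy = 2), 2)
  expect_error(meanFociPerCell(counts, doseGy = 9), "no cells")

  # the mean of ground-truth counts converges to lambda(D)
  set.seed(20)
  cfg <- SceneConfig()
  g <- data.frame(cell_count = sampleFocusCount(2, cfg, n = 500),
                  dose_gy = 2)
  expect_lt(abs(meanFociPerCell(g) - 4.761), 3 * sqrt(4.761 / 500))
})
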