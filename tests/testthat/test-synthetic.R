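test_that("focus counts follow the linear-in-dose Poisson law", {
  cfg <- SceneConfig()

  # zero-rate Poisson never fires
  cfg0 <- SceneConfig(slopeATrue = 0, interceptBTrue = 0)
  set.seed(1)
  expect_true(all(sampleFocusCount(3, cfg0, n = 500) == 0L))

  # mean at 2 Gy converges to lambda = 1.996 * 2 + 0.769 = 4.761
  set.seed(42)
  draws <- sampleFocusCount(2, cfg, n = 10000)
  lambda <- 1.996 * 2 + 0.769
  expect_lt(abs(mean(draws) - lambda), 3 * sqrt(lambda / 10000))

  # determinism under a fixed seed
  set.seed(7); a <- sampleFocusCount(1, cfg, n = 50)
  set.seed(7); b <- sampleFocusCount(1, cfg, n = 50)
  expect_identical(a, b)

  expect_error(sampleFocusCount(-1, cfg), "non-negative")
})

test_that("rendered scenes carry exact, consistent ground truth", {
  cfg <- SceneConfig(cellsPerImage = 3L, seed = 2L)
  for (seed in c(11, 12, 13)) {
    sc <- renderScene(2, cfg, seed = seed, nCells = 3)
    expect_equal(length(fociBoxes(sc)), nrow(mncBoxes(sc)))
    expect_equal(vapply(fociBoxes(sc), nrow, integer(1)),
                 trueCounts(sc))
    mb <- mncBoxes(sc)
    # every focus box lies inside its cell's box
    for (i in seq_len(nrow(mb))) {
      fb <- fociBoxes(sc)[[i]]
      if (nrow(fb) == 0) next
      expect_true(all(fb$x_min >= mb$x_min[i] & fb$x_max <= mb$x_max[i] &
                        fb$y_min >= mb$y_min[i] & fb$y_max <= mb$y_max[i]))
    }
    # cell boxes pairwise disjoint
    if (nrow(mb) > 1) {
      for (i in 1:(nrow(mb) - 1)) for (j in (i + 1):nrow(mb)) {
        expect_equal(boxIoU(Box(mb$x_min[i], mb$y_min[i], mb$x_max[i],
                                mb$y_max[i]),
                            Box(mb$x_min[j], mb$y_min[j], mb$x_max[j],
                                mb$y_max[j])), 0)
      }
    }
  }
})

test_that("scene rendering is deterministic and honours pmnFraction = 0", {
  cfg <- SceneConfig(cellsPerImage = 2L, pmnFraction = 0)
  s1 <- renderScene(1, cfg, seed = 5, nCells = 2)
  s2 <- renderScene(1, cfg, seed = 5, nCells = 2)
  expect_identical(pixels(gtStack(s1)), pixels(gtStack(s2)))
  expect_identical(mncBoxes(s1), mncBoxes(s2))
  # with no distractors every rendered cell carries a ground-truth box
  expect_equal(nrow(mncBoxes(s1)), 2L)
})

test_that("invalid scene configurations are rejected", {
  expect_error(SceneConfig(cellsPerDose = 0L), "cellsPerDose")
  expect_error(SceneConfig(slopeATrue = -1), "slopeATrue")
  expect_error(SceneConfig(nucleusRadiusPx = c(30, 18)), "min <= max")
  # nucleus too large for the frame
  big <- SceneConfig(imageSizePx = c(64L, 64L), nucleusRadiusPx = c(30, 40))
  expect_error(renderScene(1, big, seed = 1, nCells = 1),
               "configuration error")
  expect_error(renderScene(-2, SceneConfig(), seed = 1), "non-negative")
})

test_that("clean scenes show one intensity peak per planted focus", {
  # noise-free, flat z, separation >= 6 sigma: local maxima of the raw
  # green plane above background count the planted foci exactly
  localMaxCount <- function(m, lo) {
    n <- 0L
    for (r in 2:(nrow(m) - 1)) for (cc in 2:(ncol(m) - 1)) {
      v <- m[r, cc]
      if (v > lo && v == max(m[(r - 1):(r + 1), (cc - 1):(cc + 1)]))
        n <- n + 1L
    }
    n
  }
  hits <- 0L; cells <- 0L
  for (seed in c(31, 32, 33, 34)) {
    sc <- renderScene(2, cleanConfig(), seed = seed, nCells = 1)
    g <- pixels(gtStack(sc))[2, 1, , ]
    mb <- mncBoxes(sc)
    sub <- g[(mb$y_min[1] + 1):mb$y_max[1], (mb$x_min[1] + 1):mb$x_max[1]]
    cells <- cells + 1L
    if (localMaxCount(sub, lo = 0.1) == trueCounts(sc)[1])
      hits <- hits + 1L
  }
  expect_equal(hits, cells)
})

test_that("expected true counts increase with dose", {
  cfg <- SceneConfig(cellsPerImage = 4L)
  meanAt <- function(d, seeds) {
    tot <- 0L; n <- 0L
    for (s in seeds) {
      sc <- renderScene(d, cfg, seed = s, nCells = 4)
      tot <- tot + sum(trueCounts(sc)); n <- n + length(trueCounts(sc))
    }
    tot / n
  }
  m0 <- meanAt(0, 101:110)   # 40 cells, lambda 0.769
  m4 <- meanAt(4, 201:210)   # 40 cells, lambda 8.753
  expect_lt(m0, m4)
  expect_lt(abs(m0 - 0.769), 3 * sqrt(0.769 / 40))
  expect_lt(abs(m4 - 8.753), 3 * sqrt(8.753 / 40))
})

test_that("dataset generation is reproducible and refuses collisions", {
  cfg <- SceneConfig(imageSizePx = c(128L, 128L), nZ = 2L,
                     dosesGy = c(0, 2), cellsPerDose = 2L,
                     cellsPerImage = 2L, nucleusRadiusPx = c(10, 16),
                     seed = 9L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- generateDataset(cfg, d1)
  r2 <- generateDataset(cfg, d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_identical(readLines(file.path(d1, "scenes.json")),
                   readLines(file.path(d2, "scenes.json")))
  expect_identical(pixels(readStack(file.path(d1, r1$manifest$file[1]))),
                   pixels(readStack(file.path(d2, r2$manifest$file[1]))))
  expect_error(generateDataset(cfg, d1), "manifest already exists")
  expect_silent(generateDataset(cfg, d1, overwrite = TRUE))

  # single dose, single cell: exactly one scene
  cfg1 <- SceneConfig(imageSizePx = c(128L, 128L), nZ = 1L, dosesGy = 0,
                      cellsPerDose = 1L, cellsPerImage = 1L,
                      nucleusRadiusPx = c(10, 16), seed = 4L)
  d3 <- withr::local_tempdir()
  r3 <- generateDataset(cfg1, d3)
  expect_equal(nrow(r3$manifest), 1L)
  expect_length(readScenes(file.path(d3, "scenes.json")), 1L)
})
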