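test_that("normalizeImage converts, rescales and validates input", {
  # constant image is invariant under resampling
  out <- normalizeImage(matrix(0.5, 320, 320), 144)
  expect_equal(dim(out), c(144, 144))
  expect_true(all(abs(out - 0.5) < 1e-12))

  # brute-force 2x2 box-filter oracle: a single white pixel averaged down
  src <- matrix(0, 16, 16); src[1, 1] <- 1
  boxOracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    boxOracle[i, j] <- mean(src[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  got <- normalizeImage(src, 8)
  expect_equal(got, boxOracle, tolerance = 1e-6)
  expect_equal(got[1, 1], 0.25, tolerance = 1e-6)

  # RGB arrays collapse to gray, 0-255 inputs rescale
  rgb <- array(c(255, rep(0, 11)), c(2, 2, 3))
  expect_true(all(normalizeImage(rgb, 8) <= 1))

  expect_error(normalizeImage(matrix(numeric(0), 0, 0)), "empty")
  expect_error(normalizeImage(matrix(NA_real_, 4, 4)), "non-finite")
  expect_error(normalizeImage(matrix(0.5, 16, 16), 4), ">= 8")
})

test_that("sampleAffine draws uniformly within configured ranges", {
  # degenerate ranges always give the identity
  p <- sampleAffine(10, identityAffineRanges(), seed = 1)
  expect_true(all(p$scale == 1 & p$tx == 0 & p$ty == 0 & p$rot == 0))

  draws <- sampleAffine(1e5, seed = 2)
  r <- defaultAffineRanges()
  expect_true(min(draws$scale) >= r$scale[1] && max(draws$scale) <= r$scale[2])
  expect_true(min(draws$tx) >= r$tx[1] && max(draws$tx) <= r$tx[2])
  expect_true(min(draws$rot) >= r$rot[1] && max(draws$rot) <= r$rot[2])
  expect_equal(mean(draws$scale), 1.0, tolerance = 1e-3)

  # rotation convention: 1.0 = 360 degrees, so 0.02 is 7.2 degrees
  expect_equal(0.02 * 360, 7.2)

  bad <- defaultAffineRanges(); bad$scale <- c(1.1, 0.9)
  expect_error(sampleAffine(1, bad), "lo <= hi")
})

test_that("applyAffine composes a single smooth transform about the center", {
  img <- renderImage(fxDataset(), 1)
  expect_identical(applyAffine(img, data.frame(scale = 1, tx = 0, ty = 0, rot = 0)),
                   img)

  # tx = 0.15 on a 144 px image shifts content by 21.6 px: verify via the
  # centroid of a single bright blob
  big <- matrix(0, 144, 144); big[60:66, 70:76] <- 1
  shifted <- applyAffine(big, data.frame(scale = 1, tx = 0.15, ty = 0, rot = 0),
                         background = 0)
  centroid <- function(m) sum(row(m) * m) / sum(m)
  expect_equal(centroid(shifted) - centroid(big), 0.15 * 144, tolerance = 0.05)

  # out-of-frame fill uses the background gray
  far <- applyAffine(img, data.frame(scale = 1, tx = 0.45, ty = 0, rot = 0))
  expect_true(all(abs(far[1:5, ] - 0.5) < 1e-6))
})

test_that("synthetic dataset manifests have the declared structure", {
  ds <- makeSyntheticDataset(syntheticDatasetSpec(10, 4, 5, imageSize = 16))
  expect_equal(nrow(ds$manifest), 10 * 4 * 5)
  expect_equal(length(ds$categories), 10)
  expect_true(all(ds$manifest$category %in% ds$categories))
  # render ids distinct within exemplar
  byEx <- split(ds$manifest$render,
                paste(ds$manifest$category, ds$manifest$exemplar))
  expect_true(all(vapply(byEx, anyDuplicated, integer(1)) == 0))

  # full-corpus scale: 942 exemplars across 100 categories x 20 renders
  nEx <- rep(c(9, 10), c(58, 42))   # sums to 942
  big <- makeSyntheticDataset(syntheticDatasetSpec(
    100, nEx, 20, imageSize = 16))
  expect_equal(nrow(big$manifest), 18840)
})

test_that("synthetic rendering is deterministic and category-structured", {
  ds <- fxDataset()
  expect_identical(renderImage(ds, 5), renderImage(ds, 5))
  ds2 <- makeSyntheticDataset(ds$spec)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(renderImage(ds, 12), renderImage(ds2, 12))

  imgs <- fxImages()
  expect_true(all(vapply(imgs, function(m) min(m) >= 0 && max(m) <= 1,
                         logical(1))))
  # render variation (same exemplar) is smaller than exemplar variation
  m <- ds$manifest
  sameEx <- mean((imgs[[1]] - imgs[[2]])^2)      # renders 1,2 of exemplar 1
  otherEx <- mean((imgs[[1]] - imgs[[3]])^2)     # exemplar 2 of same category
  expect_lt(sameEx, otherEx)
})

test_that("train/test split is by exemplar, disjoint and deterministic", {
  ds <- makeSyntheticDataset(syntheticDatasetSpec(10, 4, 5, imageSize = 16))
  sp <- splitTrainTest(ds$manifest, 1, seed = 3)
  expect_equal(nrow(sp$test), 10 * 1 * 5)
  expect_equal(nrow(sp$train), 10 * 3 * 5)
  for (cat in unique(ds$manifest$category)) {
    exTr <- unique(sp$train$exemplar[sp$train$category == cat])
    exTe <- unique(sp$test$exemplar[sp$test$category == cat])
    expect_length(exTe, 1)
    expect_length(intersect(exTr, exTe), 0)
  }
  # default two exemplars per category are reserved
  sp2 <- splitTrainTest(ds$manifest, seed = 3)
  tab <- table(unique(sp2$test[c("category", "exemplar")])$category)
  expect_true(all(tab == 2))
  # n = 0: everything trains
  sp0 <- splitTrainTest(ds$manifest, 0)
  expect_equal(nrow(sp0$train), nrow(ds$manifest))
  expect_equal(nrow(sp0$test), 0)
  expect_identical(splitTrainTest(ds$manifest, 1, seed = 9),
                   splitTrainTest(ds$manifest, 1, seed = 9))
  small <- makeSyntheticDataset(syntheticDatasetSpec(2, 2, 2, imageSize = 16))
  expect_error(splitTrainTest(small$manifest, 2, seed = 1), "cat001")
})

test_that("manifests round-trip through CSV", {
  ds <- fxDataset()
  path <- withr::local_tempfile(fileext = ".csv")
  writeManifest(ds$manifest, path)
  back <- readManifest(path)
  expect_equal(back$category, ds$manifest$category)
  expect_equal(back$seed, ds$manifest$seed)
})
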