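test_that("computeNormStats pools pixels with the population convention", {
  s <- computeNormStats(list(matrix(0, 1, 1), matrix(1, 1, 1)))
  expect_equal(s$mean, 0.5)
  expect_equal(s$std, 0.5)
  # invariant to image order
  set.seed(3)
  imgs <- lapply(1:5, function(i) matrix(runif(12), 3, 4))
  s1 <- computeNormStats(imgs)
  s2 <- computeNormStats(rev(imgs))
  expect_equal(s1, s2)
  expect_error(computeNormStats(list(matrix(0.3, 4, 4))), "zero variance")
  expect_error(computeNormStats(list()), "at least one")
})

test_that("normalizeAndResize emits side x side x 3 with identical channels", {
  set.seed(4)
  patch <- matrix(runif(50 * 50), 50, 50)
  stats <- list(mean = 0.5, std = 0.2)
  out <- normalizeAndResize(patch, stats)
  expect_equal(dim(out), c(224, 224, 3))
  expect_identical(out[, , 1], out[, , 2])
  expect_identical(out[, , 1], out[, , 3])
  # constant patch at the mean maps to all zeros
  z <- normalizeAndResize(matrix(0.5, 20, 20), stats, side = 32)
  expect_true(all(abs(z) < 1e-12))
  expect_error(normalizeAndResize(patch, list(mean = 0, std = 0)), "std")
})

test_that("validation preprocessing shape is independent of box aspect ratio", {
  set.seed(5)
  img <- matrix(runif(96 * 96), 96, 96)
  stats <- list(mean = 0.5, std = 0.3)
  for (b in list(Box(10, 10, 80, 20), Box(10, 10, 20, 80),
                 Box(-10, 40, 30, 50), Box(60, 60, 120, 140))) {
    out <- validationPreprocess(img, b, stats, side = 64)
    expect_equal(dim(out), c(64, 64, 3))
  }
})

test_that("augmentation with all stochastic branches off equals validation", {
  r <- renderFace(facePhenotype(orbital = 1), renderConfig(width = 96, height = 96),
                  seed = 2)
  stats <- computeNormStats(list(r$image))
  off <- augmentationParams(flipP = 0, brightnessRange = 0, contrastRange = 0,
                            jitterP = 0, rotBilinearP = 0, rotNearestP = 0,
                            resizeNearestP = 0)
  set.seed(11)
  a <- sampleTrainingAugmentation(r$image, r$truth$box, stats, off, side = 64)
  v <- validationPreprocess(r$image, r$truth$box, stats, side = 64)
  expect_equal(a, v, tolerance = 1e-12)
})

test_that("augmentation draws are deterministic given the RNG state", {
  r <- renderFace(facePhenotype(), renderConfig(width = 96, height = 96),
                  seed = 3)
  stats <- computeNormStats(list(r$image))
  set.seed(99)
  a1 <- sampleTrainingAugmentation(r$image, r$truth$box, stats, side = 48)
  set.seed(99)
  a2 <- sampleTrainingAugmentation(r$image, r$truth$box, stats, side = 48)
  expect_identical(a1, a2)
})

test_that("augmentation branch frequencies match the configured probabilities", {
  # small canvas keeps 10,000 draws affordable; probabilities are unchanged
  r <- renderFace(facePhenotype(), renderConfig(width = 64, height = 64),
                  seed = 4)
  stats <- computeNormStats(list(r$image))
  n <- 10000
  set.seed(123)
  det <- vector("list", n)
  for (i in seq_len(n))
    det[[i]] <- attr(sampleTrainingAugmentation(r$image, r$truth$box, stats,
                                                side = 32, details = TRUE),
                     "augmentation")
  flips <- mean(vapply(det, `[[`, TRUE, "flipped"))
  rot <- vapply(det, `[[`, "", "rotation")
  bright <- vapply(det, `[[`, 0, "brightness")
  angles <- vapply(det, `[[`, 0, "angle")
  expect_true(abs(flips - 0.5) < 0.02)
  expect_true(abs(mean(rot != "none") - 0.5) < 0.02)
  expect_true(abs(mean(rot == "bilinear") - 0.25) < 0.02)
  expect_true(all(bright >= 0.85 & bright <= 1.15))
  expect_true(all(abs(angles) <= 10))
  expect_true(abs(mean(vapply(det, `[[`, TRUE, "jittered")) - 0.5) < 0.02)
})

test_that("augmentation parameter validation rejects bad probabilities", {
  expect_error(augmentationParams(flipP = 1.5), "probabilities")
  expect_error(augmentationParams(rotBilinearP = 0.6, rotNearestP = 0.6),
               "sum")
  expect_error(augmentationParams(brightnessRange = -0.1), "non-negative")
})

test_that("norm stats survive the JSON sidecar round trip", {
  s <- list(mean = 0.4812345678901, std = 0.1098765432109)
  path <- tempfile(fileext = ".json")
  writeNormStats(s, path)
  s2 <- readNormStats(path)
  expect_equal(s2$mean, s$mean)
  expect_equal(s2$std, s$std)
})
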