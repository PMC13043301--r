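test_that("the default manifest has the documented 41-feature composition", {
  m <- defaultFeatureManifest()
  expect_equal(nrow(m), 41L)
  comp <- table(m$type)
  expect_equal(unname(comp["point_acceleration"]), 6L)
  expect_equal(unname(comp["point_speed"]), 6L)
  expect_equal(unname(comp["pair_distance"]), 13L)
  expect_equal(unname(comp["border_distance"]), 6L)
  expect_equal(unname(comp["pair_angle"]), 7L)
  expect_equal(unname(comp["polygon_area"]), 2L)
  expect_equal(unname(comp["axis_angular_velocity"]), 1L)
})

test_that("extractFeatures emits one column per manifest entry", {
  ses <- simulateKeypointSession(defaultRegimeModel(), nFrames = 100, seed = 2)
  f <- extractFeatures(ses$track)
  expect_equal(dim(f), c(100L, 41L))
  expect_true(all(is.finite(f)))
  expect_equal(colnames(f), defaultFeatureManifest()$name)
})

test_that("a stationary track has zero kinematic features", {
  tr <- handTrack(cbind(rep(150, 50), rep(120, 50)))
  f <- extractFeatures(tr)
  kin <- grepl("^(speed|accel|angvel)", colnames(f))
  expect_true(all(abs(f[, kin]) < 1e-12))
  # geometric features are constant and sensible
  expect_true(all(f[, "dist_left_ear_right_ear"] == 4))
})

test_that("pair distances are plain Euclidean distances", {
  tr <- handTrack(cbind(c(100, 103, 100), c(100, 104, 100)))
  f <- extractFeatures(tr)
  # body_center at path, nose at path + (6, 0)
  expect_equal(unname(f[, "dist_nose_body_center"]), rep(6, 3))
  # frame-2 displacement of body_center is the 3-4-5 triangle
  expect_equal(unname(f[2, "speed_body_center"]), 5)
})

test_that("border distances come from the corner-defined arena rectangle", {
  tr <- handTrack(cbind(c(10, 10, 10), c(10, 10, 10)))
  f <- extractFeatures(tr)
  expect_equal(unname(f[1, "border_body_center"]), 10)
  tr2 <- handTrack(cbind(rep(220, 3), rep(140, 3)))
  f2 <- extractFeatures(tr2)
  expect_equal(unname(f2[1, "border_body_center"]), 140)
  miss <- KeypointTrack(x = matrix(0, 5, 2), y = matrix(0, 5, 2),
                        parts = c("nose", "left_ear"))
  expect_error(extractFeatures(miss), "missing part")
})

test_that("normalization and expansion produce the documented geometry", {
  ses <- simulateKeypointSession(defaultRegimeModel(), nFrames = 200, seed = 3)
  f <- extractFeatures(ses$track)
  ne <- normalizeAndExpand(f, halfwidth = 15)
  expect_equal(ncol(ne$expanded), 41L * 31L)
  expect_equal(nrow(ne$expanded), 200L)
  z <- sweep(sweep(f, 2, ne$stats$center), 2, ne$stats$scale, "/")
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
  # halfwidth 0 is the identity expansion
  ne0 <- normalizeAndExpand(f, halfwidth = 0)
  expect_equal(ncol(ne0$expanded), 41L)
  expect_equal(unname(ne0$expanded), unname(z), tolerance = 1e-12)
  # stored stats reproduce the same expansion on reuse
  ne2 <- normalizeAndExpand(f, halfwidth = 15, stats = ne$stats)
  expect_identical(ne$expanded, ne2$expanded)
})

test_that("zero-variance columns are passed through as zeros with a warning", {
  f <- cbind(a = rnorm(50), b = rep(2, 50))
  expect_warning(ne <- normalizeAndExpand(f, halfwidth = 1), "zero-variance")
  expect_true(all(ne$expanded[, grepl("^b", colnames(ne$expanded))] == 0))
})

test_that("k-means recovers separable blobs exactly and deterministically", {
  set.seed(9)
  blobs <- rbind(matrix(rnorm(200, 0, 0.2), 100, 2),
                 matrix(rnorm(200, 8, 0.2), 100, 2),
                 cbind(rnorm(100, 0, 0.2), rnorm(100, 16, 0.2)))
  truth <- rep(1:3, each = 100)
  m <- fitClusters(blobs, k = 3, seed = 5, halfwidth = 0L,
                   featureNames = c("x", "y"))
  expect_equal(mclust::adjustedRandIndex(attr(m, "labels"), truth), 1.0)
  m2 <- fitClusters(blobs, k = 3, seed = 5, halfwidth = 0L,
                    featureNames = c("x", "y"))
  expect_identical(clusterCenters(m), clusterCenters(m2))
  expect_error(fitClusters(blobs[1:2, ], k = 3), "cannot fit")
  # the published default is ten clusters
  ses <- simulateKeypointSession(defaultRegimeModel(), nFrames = 300, seed = 4)
  ne <- normalizeAndExpand(extractFeatures(ses$track), halfwidth = 2)
  mdef <- fitClusters(ne$expanded, seed = 1, stats = ne$stats,
                      featureNames = ne$featureNames, halfwidth = 2L)
  expect_equal(mdef@k, 10L)
})

test_that("label assignment is the exact k-means prediction", {
  set.seed(10)
  x <- matrix(rnorm(600), 200, 3)
  m <- fitClusters(x, k = 4, seed = 2, halfwidth = 0L,
                   featureNames = c("a", "b", "c"))
  lab <- assignLabels(m, x)
  expect_identical(lab, attr(m, "labels"))
  expect_true(all(lab %in% 0:3))
  # a row equal to centroid j gets label j
  labC <- assignLabels(m, clusterCenters(m))
  expect_identical(labC, 0:3)
  expect_error(assignLabels(m, x[, 1:2]), "dimension")
})

test_that("the neural transfer classifier reproduces nearest-centroid labels", {
  set.seed(11)
  x <- rbind(matrix(rnorm(300, 0, 0.3), 100, 3),
             matrix(rnorm(300, 6, 0.3), 100, 3))
  m <- fitClusters(x, k = 2, seed = 3, halfwidth = 0L,
                   featureNames = c("a", "b", "c"))
  clf <- trainTransferClassifier(x, attr(m, "labels"), size = 4, seed = 1)
  lab <- assignLabels(m, x, classifier = clf)
  expect_gt(mean(lab == attr(m, "labels")), 0.99)
})

test_that("label smoothing takes the windowed mode with center tie-keeping", {
  expect_equal(smoothLabels(c(1, 1, 2, 1, 1)), c(1, 1, 1, 1, 1))
  expect_equal(smoothLabels(rep(3, 10)), rep(3, 10))
  expect_equal(smoothLabels(c(0, 1, 0, 1, 0), window = 1), c(0, 1, 0, 1, 0))
  # tie in the window keeps the original center label
  expect_equal(smoothLabels(c(0, 0, 1, 1, 2), window = 5)[3], 1)
  expect_equal(smoothLabels(c(1, 1, 0, 0, 2), window = 5)[3], 0)
  expect_error(smoothLabels(c(1, 2), window = 4), "odd")
  expect_length(smoothLabels(integer(0)), 0L)
})

test_that("transition counting matches hand counts and conserves changes", {
  tm <- transitionMatrix(c(0, 0, 1, 1, 0), 2)
  expect_equal(unname(transitionCounts(tm)), rbind(c(0L, 1L), c(1L, 0L)))
  expect_equal(sum(transitionCounts(tm)), 2L)  # number of label changes
  tmc <- transitionMatrix(rep(1, 50), 3)
  expect_true(all(transitionCounts(tmc) == 0L))
  withSelf <- transitionMatrix(c(0, 0, 1, 1, 0), 2, includeSelf = TRUE)
  expect_equal(sum(transitionCounts(withSelf)), 4L)
  expect_equal(diag(transitionCounts(withSelf)), setNames(c(1L, 1L), 0:1))
  expect_error(transitionMatrix(c(0, 5), 3), "0 .. k-1")
  set.seed(12)
  lab <- sample(0:3, 500, replace = TRUE)
  expect_equal(sum(transitionCounts(transitionMatrix(lab, 4))),
               sum(diff(lab) != 0))
})

test_that("occupancy fractions are label frequencies summing to one", {
  expect_equal(unname(clusterOccupancy(c(0, 0, 1, 1), 3)), c(0.5, 0.5, 0))
  expect_equal(unname(clusterOccupancy(rep(2, 7), 3)), c(0, 0, 1))
  set.seed(13)
  lab <- sample(0:9, 1000, replace = TRUE)
  expect_equal(sum(clusterOccupancy(lab, 10)), 1)
  expect_error(clusterOccupancy(integer(0), 3), "empty")
})

test_that("include-self transition rows equal occupancy counts minus the final frame", {
  set.seed(14)
  lab <- sample(0:4, 400, replace = TRUE)
  tm <- transitionMatrix(lab, 5, includeSelf = TRUE)
  rs <- rowSums(transitionCounts(tm))
  occCounts <- tabulate(lab + 1L, 5)
  corr <- integer(5); corr[lab[length(lab)] + 1L] <- 1L
  expect_equal(unname(rs), occCounts - corr)
})

test_that("distance moved is arena-calibrated and scale invariant", {
  # stationary
  tr <- handTrack(cbind(rep(100, 20), rep(100, 20)))
  expect_equal(distanceMoved(tr), 0)
  # tracing the full 11 cm arena width once with exact corners
  n <- 51
  path <- cbind(seq(0, 440, length.out = n), rep(140, n))
  tr2 <- handTrack(path)
  expect_equal(distanceMoved(tr2), 11, tolerance = 1e-6)
  # doubling all pixel coordinates (corners included) changes nothing
  tr3 <- handTrack(path * 2, corners = rbind(c(0, 0), c(880, 0),
                                             c(880, 560), c(0, 560)))
  expect_equal(distanceMoved(tr3), distanceMoved(tr2), tolerance = 1e-9)
  expect_error(distanceMoved(tr2, part = "whisker"), "missing part")
  degen <- handTrack(path, corners = matrix(5, 4, 2))
  expect_error(distanceMoved(degen), "degenerate")
})

test_that("low-confidence frames are bridged by linear interpolation", {
  n <- 11
  path <- cbind(seq(0, 100, length.out = n), rep(140, n))
  tr <- handTrack(path)
  # corrupt the middle frame but mark it low-confidence
  tr@x[6, "body_center"] <- 4000
  tr@confidence[6, "body_center"] <- 0.1
  d <- distanceMoved(tr)
  clean <- distanceMoved(handTrack(path))
  expect_equal(d, clean, tolerance = 1e-9)
})
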