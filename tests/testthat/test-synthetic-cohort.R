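test_that("a 2-group x 5-timepoint design with 8 per group emits 80 sessions", {
  design <- cohortDesign(nPerGroup = 8, sessionLengthFrames = 60,
                         frontFrames = 0, seed = 3)
  cohort <- simulateCohort(design, renderFront = FALSE)
  expect_equal(length(cohort$sessions), 80L)
  expect_equal(nrow(cohort$manifest), 80L)
  # animal ids unique per animal, repeated across timepoints
  expect_equal(length(unique(cohort$manifest$animal_id)), 16L)
  expect_true(all(table(cohort$manifest$animal_id) == 5L))
})

test_that("cohorts are reproducible from the master seed", {
  design <- cohortDesign(nPerGroup = 2, timepoints = c("0h", "4h"),
                         sessionLengthFrames = 80, frontFrames = 0, seed = 11)
  c1 <- simulateCohort(design, renderFront = FALSE)
  c2 <- simulateCohort(design, renderFront = FALSE)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$sessions[[3]]$track@x, c2$sessions[[3]]$track@x)
  expect_identical(c1$sessions[[3]]$states, c2$sessions[[3]]$states)
})

test_that("a null design gives groups equal means within Monte Carlo error", {
  TP <- c("0h", "4h")
  design <- cohortDesign(
    nPerGroup = 12, timepoints = TP,
    mgsElevation = matrix(0.5, 2, 2),
    locomotionMultiplier = matrix(1, 2, 2),
    sessionLengthFrames = 400, frontFrames = 0, seed = 21)
  cohort <- simulateCohort(design, renderFront = FALSE)
  phMean <- function(s) mean(unlist(s$phenotype[mgsComponents()]))
  path <- function(s) {
    bc <- partCoords(s$track, "body_center")
    sum(sqrt(diff(bc$x)^2 + diff(bc$y)^2))
  }
  grp <- vapply(cohort$sessions, `[[`, "", "group")
  mgs <- vapply(cohort$sessions, phMean, numeric(1))
  dst <- vapply(cohort$sessions, path, numeric(1))
  expect_true(abs(mean(mgs[grp == "M"]) - mean(mgs[grp == "B+M"])) < 0.25)
  expect_true(abs(mean(dst[grp == "M"]) - mean(dst[grp == "B+M"])) /
                mean(dst) < 0.25)
})

test_that("a 3x locomotion multiplier raises path length in the target cell", {
  design <- cohortDesign(nPerGroup = 8, timepoints = c("0h", "4h"),
                         sessionLengthFrames = 3000, frontFrames = 0,
                         seed = 31)
  # default effect table: B+M at 4h has multiplier 3
  expect_equal(design$locomotionMultiplier["B+M", "4h"], 3)
  cohort <- simulateCohort(design, renderFront = FALSE)
  path <- function(s) {
    bc <- partCoords(s$track, "body_center")
    sum(sqrt(diff(bc$x)^2 + diff(bc$y)^2))
  }
  man <- cohort$manifest
  dst <- vapply(cohort$sessions, path, numeric(1))
  at4 <- man$timepoint == "4h"
  mB <- mean(dst[at4 & man$group == "B+M"])
  mM <- mean(dst[at4 & man$group == "M"])
  expect_gt(mB, mM)
  # and no group difference at baseline
  at0 <- man$timepoint == "0h"
  expect_lt(abs(mean(dst[at0 & man$group == "B+M"]) -
                  mean(dst[at0 & man$group == "M"])) / mean(dst[at0]), 0.3)
})

test_that("MGS elevation raises true component scores at the peak timepoint", {
  design <- cohortDesign(nPerGroup = 10, timepoints = c("0h", "4h"),
                         sessionLengthFrames = 60, frontFrames = 0, seed = 41)
  cohort <- simulateCohort(design, renderFront = FALSE)
  phMean <- function(s) mean(unlist(s$phenotype[mgsComponents()]))
  tp <- vapply(cohort$sessions, `[[`, "", "timepoint")
  mgs <- vapply(cohort$sessions, phMean, numeric(1))
  expect_gt(mean(mgs[tp == "4h"]), mean(mgs[tp == "0h"]))
})

test_that("effect tables with unknown group labels are rejected", {
  bad <- matrix(1, 2, 5, dimnames = list(c("M", "XYZ"),
                                         c("0h", "4h", "24h", "48h", "72h")))
  expect_error(cohortDesign(locomotionMultiplier = bad), "unknown group")
  expect_error(cohortDesign(nPerGroup = 0), "nPerGroup")
})

test_that("written cohorts round-trip through the directory tree", {
  dir <- tempfile("cohort")
  design <- cohortDesign(nPerGroup = 1, timepoints = "0h",
                         sessionLengthFrames = 50, frontFrames = 4,
                         renderSize = 64, seed = 51)
  cohort <- simulateCohort(design)
  manifest <- writeCohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), 2L)
  tr <- readPoseTrack(manifest$pose_path[1])
  expect_equal(tr@x, cohort$sessions[[1]]$track@x, tolerance = 1e-12,
               ignore_attr = TRUE)
  truth <- jsonlite::read_json(manifest$truth_path[1], simplifyVector = TRUE)
  expect_equal(truth$states, cohort$sessions[[1]]$states)
  pngs <- list.files(manifest$frames_dir[1], pattern = "png$")
  expect_length(pngs, 4L)
})
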