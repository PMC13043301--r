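test_that("frame means exclude NR and are undefined when all five are NR", {
  expect_equal(frameMeanMgs(c("1", "1", "0", "2", "NR")), 1.0)
  expect_equal(frameMeanMgs(rep("0", 5)), 0.0)
  expect_true(is.na(frameMeanMgs(rep("NR", 5))))
  expect_error(frameMeanMgs(c("0", "1")), "5 components")
})

test_that("video means average the defined frame means", {
  recs <- data.frame(frame_index = c(0L, 300L, 600L),
                     timestamp_s = c(0, 10, 20),
                     orbital = c("1", "1", "NR"), nose = c("1", "0", "NR"),
                     cheek = c("1", "0", "NR"), ear = c("1", "1", "NR"),
                     whisker = c("1", "0", "NR"),
                     frame_mean = c(1.0, 0.4, NA),
                     n_rateable = c(5L, 5L, 0L), stringsAsFactors = FALSE)
  ses <- new("GrimaceSession", records = recs, videoMean = 0.7,
             metadata = list())
  expect_equal(videoMeanMgs(ses), 0.7)  # all-NR frame excluded
  expect_equal(videoMeanMgs(ses, pooling = "components"), mean(c(1,1,1,1,1,
                                                                 1,0,0,1,0)))
  one <- new("GrimaceSession", records = recs[1, ], videoMean = 1.0,
             metadata = list())
  expect_equal(videoMeanMgs(one), 1.0)
  allNr <- new("GrimaceSession", records = recs[3, ], videoMean = NA_real_,
               metadata = list())
  expect_true(is.na(videoMeanMgs(allNr)))
})

test_that("scoreSession recovers ground truth through stub backends", {
  # 60-frame synthetic session at 10 fps with 2-s segments (20 frames each);
  # one sharp frame per segment, ground-truth-backed stub backends
  comps <- c(orbital = "1", nose = "0", cheek = "2", ear = "0", whisker = "1")
  ph <- facePhenotype(orbital = 1, nose = 0, cheek = 2, ear = 0, whisker = 1)
  sched <- function(i) {
    if (i %% 20 == 7) renderConfig(width = 80, height = 80)
    else renderConfig(width = 80, height = 80, blurSigma = 4)
  }
  ses <- simulateFrontSession(ph, sched, nFrames = 60, fps = 10, seed = 21)
  q <- vapply(ses$truth, `[[`, 0, "quality")
  stats <- computeNormStats(ses$frames[1:5])
  out <- scoreSession(ses$frames, quality = q,
                      detector = stubDetector(ses$truth[[8]]$box),
                      classifier = stubClassifier(comps), stats = stats,
                      segmentConfig = segmentSelectionConfig(intervalS = 2),
                      fps = 10, side = 48)
  recs <- sessionRecords(out)
  expect_equal(recs$frame_index, c(7L, 27L, 47L))
  expect_equal(recs$timestamp_s, c(0.7, 2.7, 4.7))
  for (ci in mgsComponents())
    expect_true(all(recs[[ci]] == comps[ci]))
  expect_equal(recs$frame_mean, rep(0.8, 3))
  expect_equal(out@videoMean, 0.8)
  # record indices equal the selector output exactly
  expect_identical(recs$frame_index,
                   selectBySegments(q, segmentSelectionConfig(intervalS = 2,
                                                              fps = 10)))
})

test_that("an all-blurred session yields a valid empty result", {
  ses <- simulateFrontSession(facePhenotype(),
                              renderConfig(width = 80, height = 80,
                                           blurSigma = 5),
                              nFrames = 40, fps = 10, seed = 22)
  q <- vapply(ses$truth, `[[`, 0, "quality")
  expect_true(all(q < 4.25))
  out <- scoreSession(ses$frames, quality = q,
                      detector = stubDetector(ses$truth[[1]]$box),
                      classifier = stubClassifier(rep("0", 5)),
                      stats = list(mean = 0.3, std = 0.2),
                      segmentConfig = segmentSelectionConfig(intervalS = 2),
                      fps = 10, side = 48)
  expect_equal(nrow(sessionRecords(out)), 0L)
  expect_true(is.na(out@videoMean))
})

test_that("no-detection frames are dropped and logged, not fatal", {
  ses <- simulateFrontSession(facePhenotype(),
                              renderConfig(width = 80, height = 80),
                              nFrames = 20, fps = 10, seed = 23)
  q <- vapply(ses$truth, `[[`, 0, "quality")
  out <- scoreSession(ses$frames, quality = q,
                      detector = function(image) list(),
                      classifier = stubClassifier(rep("0", 5)),
                      stats = list(mean = 0.3, std = 0.2),
                      segmentConfig = segmentSelectionConfig(intervalS = 1),
                      fps = 10, side = 48)
  expect_equal(nrow(sessionRecords(out)), 0L)
  expect_gt(length(sessionMetadata(out)$dropped_frames), 0L)
})

test_that("the three session CSVs round-trip losslessly", {
  comps <- c(orbital = "1", nose = "NR", cheek = "0", ear = "2",
             whisker = "1")
  recs <- data.frame(frame_index = c(3L, 33L), timestamp_s = c(0.1, 1.1),
                     orbital = "1", nose = "NR", cheek = "0", ear = "2",
                     whisker = "1",
                     frame_mean = frameMeanMgs(comps),
                     n_rateable = 4L, stringsAsFactors = FALSE)
  ses <- new("GrimaceSession", records = recs,
             videoMean = mean(recs$frame_mean),
             metadata = list(n_frames = 60L, fps = 30))
  kp <- simulateKeypointSession(defaultRegimeModel(), nFrames = 40, seed = 3)
  dir <- tempfile("session")
  paths <- writeSessionOutputs(ses, kp$track, dir)
  expect_length(list.files(dir, pattern = "\\.csv$"), 3L)

  back <- readGrimaceCsv(paths["grimace"])
  expect_equal(back$frame_index, recs$frame_index)
  expect_equal(back$frame_mean, recs$frame_mean)
  expect_equal(back$nose, recs$nose)

  ts <- read.csv(paths["timestamps"])
  expect_equal(nrow(ts), 60L + 40L)
  expect_equal(ts$timestamp_s[ts$camera == "front"], (0:59) / 30)

  tr <- readPoseTrack(paths["pose"])
  expect_equal(tr@x, kp$track@x, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tr@confidence, kp$track@confidence, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("an empty session writes a header-only grimace CSV", {
  ses <- new("GrimaceSession",
             records = data.frame(frame_index = integer(0),
                                  timestamp_s = numeric(0),
                                  orbital = character(0), nose = character(0),
                                  cheek = character(0), ear = character(0),
                                  whisker = character(0),
                                  frame_mean = numeric(0),
                                  n_rateable = integer(0)),
             videoMean = NA_real_, metadata = list(n_frames = 10L, fps = 30))
  kp <- simulateKeypointSession(defaultRegimeModel(), nFrames = 5, seed = 4)
  dir <- tempfile("empty")
  paths <- writeSessionOutputs(ses, kp$track, dir)
  lines <- readLines(paths["grimace"])
  expect_length(lines, 1L)
  expect_match(lines, "frame_index,timestamp_s,orbital")
})

test_that("undefined means are serialized as empty fields, never 0", {
  recs <- data.frame(frame_index = 0L, timestamp_s = 0,
                     orbital = "NR", nose = "NR", cheek = "NR", ear = "NR",
                     whisker = "NR", frame_mean = NA_real_, n_rateable = 0L,
                     stringsAsFactors = FALSE)
  ses <- new("GrimaceSession", records = recs, videoMean = NA_real_,
             metadata = list(n_frames = 1L, fps = 30))
  kp <- simulateKeypointSession(defaultRegimeModel(), nFrames = 5, seed = 5)
  dir <- tempfile("nr")
  paths <- writeSessionOutputs(ses, kp$track, dir)
  lines <- readLines(paths["grimace"])
  expect_match(lines[2], "NR,NR,NR,NR,NR,,0")
  expect_true(is.na(readGrimaceCsv(paths["grimace"])$frame_mean))
})

test_that("pose CSV parsing validates the three-row header dialect", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("scorer,s,s,s,s,s",
               "bodyparts,nose,nose,nose,left_ear,left_ear",
               "coords,x,y,likelihood,x,y",
               "0,1,2,0.9,3,4"), tmp)
  expect_error(readPoseTrack(tmp), "multiple of 3")
  writeLines(c("scorer,s,s,s,s,s,s",
               "bodyparts,nose,nose,nose,left_ear,left_ear,left_ear",
               "coords,x,y,likelihood,x,likelihood,y",
               "0,1,2,0.9,3,4,0.5"), tmp)
  expect_error(readPoseTrack(tmp), "left_ear")
  writeLines(c("scorer,s,s,s",
               "bodyparts,nose,nose,nose",
               "coords,x,y,likelihood",
               "0,1,2,0.9", "1,2,3,0.8"), tmp)
  tr <- readPoseTrack(tmp)
  expect_equal(nFrames(tr), 2L)
  expect_equal(trackParts(tr), "nose")
  expect_equal(partCoords(tr, "nose")$x, c(1, 2))
})
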