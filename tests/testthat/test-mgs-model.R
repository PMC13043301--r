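test_that("detectFace returns the highest-confidence candidate", {
  gt <- Box(10, 10, 50, 50)
  det <- detectFace(stubDetector(gt), matrix(0, 64, 64))
  expect_equal(det$box@x0, 10)
  expect_equal(det$confidence, 0.99)
  two <- function(image) list(list(box = Box(0, 0, 1, 1), confidence = 0.6),
                              list(box = Box(5, 5, 9, 9), confidence = 0.9))
  best <- detectFace(two, matrix(0, 4, 4))
  expect_equal(best$confidence, 0.9)
  expect_equal(best$box@x0, 5)
  # zero candidates signal a non-exceptional no-detection
  expect_null(detectFace(function(image) list(), matrix(0, 4, 4)))
  expect_error(detectFace(function(image) stop("GPU on fire"), matrix(0, 4, 4)),
               "backend failed.*GPU")
})

test_that("classifyComponents normalizes logits per head and decodes by argmax", {
  flat <- classifyComponents(function(x) matrix(1, 5, 4), array(0, c(8, 8, 3)))
  expect_equal(unname(flat), matrix(0.25, 5, 4))
  set.seed(6)
  p <- classifyComponents(function(x) matrix(rnorm(20), 5, 4),
                          array(0, c(8, 8, 3)))
  expect_equal(rowSums(p), setNames(rep(1, 5), mgsComponents()))
  expect_true(all(p >= 0))
  # logits favoring NR on the whisker head decode to NR
  lg <- matrix(0, 5, 4); lg[5, 4] <- 9
  dec <- decodeComponents(classifyComponents(function(x) lg,
                                             array(0, c(8, 8, 3))))
  expect_equal(unname(dec["whisker"]), "NR")
  expect_equal(unname(dec["orbital"]), "0")  # tie -> lower class index
  expect_error(classifyComponents(function(x) matrix(0, 4, 4), NULL), "5 x 4")
})

test_that("composite cross-entropy has its closed-form anchors", {
  uni <- matrix(0.25, 5, 4)
  expect_equal(compositeCrossEntropy(uni, rep("0", 5)), 5 * log(4))
  onehot <- matrix(0, 5, 4); onehot[cbind(1:5, c(1, 2, 3, 4, 1))] <- 1
  expect_equal(compositeCrossEntropy(onehot, c("0", "1", "2", "NR", "0")), 0)
  expect_error(compositeCrossEntropy(uni, rep("3", 5)), "targets")
  expect_error(compositeCrossEntropy(matrix(0.25, 4, 4), rep("0", 4)),
               "5 x 4")
  # loss dominates every per-head loss
  set.seed(8)
  for (i in 1:20) {
    p <- softmaxRowsForTest(matrix(rnorm(20), 5, 4))
    tg <- sample(mgsClasses(), 5, replace = TRUE)
    total <- compositeCrossEntropy(p, tg)
    perHead <- -log(p[cbind(1:5, match(tg, mgsClasses()))])
    expect_gte(total + 1e-12, max(perHead))
  }
})

test_that("the learning-rate schedule decays by 0.1 every five epochs", {
  expect_equal(scheduledLr(0.001, 0), 0.001)
  expect_equal(scheduledLr(0.001, 4), 0.001)
  expect_equal(scheduledLr(0.001, 5), 1e-4)
  expect_equal(scheduledLr(0.001, 10), 1e-5)
  expect_equal(scheduledLr(1e-4, 10), 1e-6)
  # both schedules keep a constant heads/backbone ratio
  for (e in 0:19)
    expect_equal(scheduledLr(0.001, e) / scheduledLr(0.0001, e), 10)
  expect_error(scheduledLr(0.001, -1), "epoch")
})

test_that("leave-one-animal-out folds partition the corpus without leakage", {
  frames <- data.frame(animal_id = rep(sprintf("m%02d", 1:31), each = 3),
                       frame_index = 1)
  folds <- makeLoaoFolds(frames)
  expect_length(folds, 31L)
  valAll <- integer(0)
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0L)
    expect_false(f$animal %in% frames$animal_id[f$train])
    expect_true(all(frames$animal_id[f$validation] == f$animal))
    valAll <- c(valAll, f$validation)
  }
  expect_equal(sort(valAll), seq_len(nrow(frames)))
  expect_error(makeLoaoFolds(data.frame(x = 1)), "animal_id")
  expect_error(makeLoaoFolds(data.frame(animal_id = c("a", NA))), "missing")
})

test_that("k-fold animal assignment keeps animals whole", {
  ids <- rep(sprintf("m%02d", 1:12), times = sample(2:5, 12, replace = TRUE))
  folds <- makeAnimalFolds(ids, k = 4, seed = 2)
  expect_length(folds, 4L)
  val <- unlist(lapply(folds, `[[`, "validation"))
  expect_equal(sort(val), seq_along(ids))
  for (f in folds)
    expect_length(intersect(unique(ids[f$train]), f$animals), 0L)
  expect_error(makeAnimalFolds(ids, k = 13), "between 2")
})

test_that("content augmentation triples fully neighbored sets and copies targets", {
  frames <- data.frame(animal_id = "a", video_id = "v",
                       frame_index = c(5L, 10L, 20L),
                       orbital = c("0", "1", "2"), nose = "1", cheek = "0",
                       ear = "NR", whisker = "1", stringsAsFactors = FALSE)
  aug <- contentAugment(frames, function(v, i) i >= 0 && i < 100)
  expect_equal(nrow(aug), 9L)
  expect_equal(sum(aug$augmented), 6L)
  for (ci in mgsComponents()) {
    for (src in seq_len(nrow(frames))) {
      nb <- aug[aug$frame_index %in% (frames$frame_index[src] + c(-1, 1)), ]
      expect_true(all(nb[[ci]] == frames[[ci]][src]))
    }
  }
  # a labeled frame at video index 0 has no predecessor: 2 items
  edge <- data.frame(animal_id = "a", video_id = "v", frame_index = 0L,
                     orbital = "0", stringsAsFactors = FALSE)
  aug2 <- contentAugment(edge, function(v, i) i >= 0 && i < 100)
  expect_equal(nrow(aug2), 2L)
  expect_equal(sort(aug2$frame_index), c(0L, 1L))
})

test_that("training configuration validates the epoch selection", {
  cfg <- trainingConfig()
  expect_equal(cfg$epochs, 20L)
  expect_equal(cfg$batch, 16L)
  expect_equal(cfg$momentum, 0.95)
  expect_equal(cfg$selectedEpoch, 10L)
  expect_error(trainingConfig(epochs = 5, selectedEpoch = 10),
               "selectedEpoch")
})
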