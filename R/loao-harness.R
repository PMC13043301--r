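## Desk-scale corpus generation and leave-one-animal-out training/evaluation
## around the reference backbone.

#' Generate a labeled synthetic training corpus
#'
#' Renders, for each synthetic animal, a short front-camera "video" with a
#' fixed, well-separated face phenotype and mild render jitter (yaw, blur,
#' pixel noise), and labels every third frame so that each labeled frame has
#' both temporal neighbors available for content augmentation. By default
#' animal \code{i}'s score for component \code{c} is \code{(i + c) mod 3},
#' so every (component, score) pair occurs in several animals and
#' leave-one-animal-out folds always have training support for the held-out
#' phenotype.
#'
#' @param nAnimals number of synthetic animals.
#' @param framesPerAnimal labeled frames per animal.
#' @param renderSize canvas side in pixels.
#' @param seed master seed.
#' @param phenotypes optional list of [facePhenotype()] (one per animal)
#'   overriding the default assignment.
#' @return list of class \code{"mgsCorpus"}: \code{labels} (data.frame:
#'   animal_id, video_id, frame_index, orbital..whisker), \code{frames}
#'   (list of per-video frame lists), \code{boxes} (parallel per-frame
#'   ground-truth boxes) and \code{hasFrame} (a \code{function(video_id,
#'   frame_index)} for [contentAugment()]).
#' @export
makeMgsTrainingCorpus <- function(nAnimals = 6, framesPerAnimal = 40,
                                  renderSize = 96, seed = 1,
                                  phenotypes = NULL) {
  if (is.null(phenotypes)) {
    phenotypes <- lapply(seq_len(nAnimals), function(i) {
      sc <- (i + 0:4) %% 3
      facePhenotype(orbital = sc[1], nose = sc[2], cheek = sc[3],
                    ear = sc[4], whisker = sc[5])
    })
  }
  stopifnot(length(phenotypes) == nAnimals)
  videoSeeds <- withSeed(seed, sample.int(.Machine$integer.max, nAnimals))
  frames <- list(); boxes <- list(); labelRows <- list()
  for (a in seq_len(nAnimals)) {
    vid <- sprintf("video_%02d", a)
    nF <- 3L * framesPerAnimal
    renderSchedule <- withSeed(videoSeeds[a], {
      yaws <- runif(nF, -3, 3)
      blurs <- runif(nF, 0, 0.4)
      lapply(seq_len(nF), function(i)
        renderConfig(width = renderSize, height = renderSize,
                     headYaw = yaws[i], blurSigma = blurs[i]))
    })
    ses <- simulateFrontSession(phenotypes[[a]], renderSchedule, nF,
                                seed = videoSeeds[a])
    frames[[vid]] <- ses$frames
    boxes[[vid]] <- lapply(ses$truth, `[[`, "box")
    labeled <- seq(1L, nF - 2L, by = 3L)  # 0-based, neighbors always exist
    comps <- ses$truth[[1]]$components
    labelRows[[a]] <- data.frame(
      animal_id = sprintf("animal_%02d", a), video_id = vid,
      frame_index = labeled,
      orbital = comps["orbital"], nose = comps["nose"],
      cheek = comps["cheek"], ear = comps["ear"],
      whisker = comps["whisker"], stringsAsFactors = FALSE,
      row.names = NULL)
  }
  labels <- do.call(rbind, labelRows)
  hasFrame <- local({
    lens <- vapply(frames, length, integer(1))
    function(video_id, frame_index)
      video_id %in% names(lens) && frame_index >= 0 &&
        frame_index < lens[[video_id]]
  })
  structure(list(labels = labels, frames = frames, boxes = boxes,
                 hasFrame = hasFrame, seed = seed),
            class = "mgsCorpus")
}

#' Materialize labeled rows of a corpus as training items
#'
#' @param corpus an \code{"mgsCorpus"}.
#' @param rows data.frame of labeled rows (subset of \code{corpus$labels},
#'   possibly content-augmented).
#' @return list of items for [trainMgs()].
#' @export
corpusItems <- function(corpus, rows) {
  lapply(seq_len(nrow(rows)), function(i) {
    vid <- rows$video_id[i]
    fi <- rows$frame_index[i]
    list(image = corpus$frames[[vid]][[fi + 1L]],
         box = corpus$boxes[[vid]][[fi + 1L]],
         targets = setNames(as.character(rows[i, mgsComponents()]),
                            mgsComponents()),
         animal_id = rows$animal_id[i], video_id = vid, frame_index = fi)
  })
}

#' Leave-one-animal-out training and evaluation
#'
#' For every fold, applies content augmentation to the training rows
#' (validation rows are never augmented), trains the reference backbone with
#' [trainMgs()] and scores the held-out animal's frames with the
#' deterministic validation path. Per-component accuracy is pooled over all
#' held-out frames of all folds.
#'
#' @param corpus an \code{"mgsCorpus"} from [makeMgsTrainingCorpus()].
#' @param config a [trainingConfig()].
#' @param seed training seed (per-fold seeds are derived from it).
#' @param poolGrid,hidden reference backbone size.
#' @return list with \code{accuracy} (named numeric(5), per-component
#'   held-out accuracy), \code{predictions} (data.frame of held-out
#'   predictions vs targets) and \code{folds} (per-fold training history).
#' @export
runLoaoTraining <- function(corpus, config = trainingConfig(), seed = 1,
                            poolGrid = 14, hidden = 48) {
  folds <- makeLoaoFolds(corpus$labels)
  foldSeeds <- withSeed(seed, sample.int(.Machine$integer.max, length(folds)))
  preds <- list()
  histories <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    trainRows <- contentAugment(corpus$labels[fold$train, , drop = FALSE],
                                corpus$hasFrame)
    items <- corpusItems(corpus, trainRows)
    backbone <- referenceBackbone(inputSide = config$inputSide,
                                  poolGrid = poolGrid, hidden = hidden,
                                  seed = foldSeeds[f])
    model <- trainMgs(items, config, seed = foldSeeds[f],
                      backbone = backbone)
    valRows <- corpus$labels[fold$validation, , drop = FALSE]
    valItems <- corpusItems(corpus, valRows)
    X <- validationFeatures(valItems, model$stats, config$inputSide, poolGrid)
    decoded <- decodeLogitsBatch(backboneForward(model$net, X)$logits)
    truth <- as.matrix(valRows[, mgsComponents()])
    preds[[f]] <- data.frame(animal_id = fold$animal,
                             component = rep(mgsComponents(),
                                             each = nrow(valRows)),
                             predicted = as.character(decoded),
                             target = as.character(truth),
                             stringsAsFactors = FALSE)
    histories[[f]] <- model$history
  }
  predictions <- do.call(rbind, preds)
  accuracy <- vapply(mgsComponents(), function(cp) {
    sub <- predictions[predictions$component == cp, ]
    mean(sub$predicted == sub$target)
  }, numeric(1))
  list(accuracy = accuracy, predictions = predictions, folds = histories)
}
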