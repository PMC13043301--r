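## MGS classifier contracts: detection, classification, the composite loss,
## the learning-rate schedule, animal-disjoint folds and temporal content
## augmentation. Backends are pluggable callables so that heavy published
## backbones and the shipped desk-scale reference backbone share one
## surface.

#' Detect the mouse face in a frame
#'
#' Runs a detector backend and returns its highest-confidence candidate.
#' "No detection" is a signaled, non-exceptional outcome (\code{NULL});
#' session scoring skips such frames.
#'
#' @param backend a \code{function(image)} returning a list of candidates,
#'   each a list with a [Box-class] \code{box} and a \code{confidence} in
#'   \code{[0, 1]} (an empty list means no detection).
#' @param image grayscale frame (numeric matrix).
#' @return list with \code{box} and \code{confidence}, or \code{NULL} if the
#'   backend found nothing.
#' @export
detectFace <- function(backend, image) {
  cands <- tryCatch(backend(image),
                    error = function(e) stop("face detector backend failed: ",
                                             conditionMessage(e), call. = FALSE))
  if (is.null(cands) || length(cands) == 0L) return(NULL)
  if (!is.null(cands$box)) cands <- list(cands)  # single candidate
  conf <- vapply(cands, function(c) as.numeric(c$confidence), numeric(1))
  best <- cands[[which.max(conf)]]
  list(box = best$box, confidence = as.numeric(best$confidence))
}

## Row-wise softmax with the usual max-shift for stability.
softmaxRows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Classify the five MGS components of a preprocessed face crop
#'
#' Runs a classifier backend (which emits one 4-way logit vector per
#' component head) and converts the logits to per-head class probabilities.
#'
#' @param backend a \code{function(input)} returning a 5 x 4 numeric matrix
#'   of logits (rows = components, columns = classes 0/1/2/NR).
#' @param input model input as produced by [normalizeAndResize()].
#' @return 5 x 4 probability matrix with rows summing to 1, rownames
#'   [mgsComponents()] and colnames [mgsClasses()].
#' @export
classifyComponents <- function(backend, input) {
  logits <- tryCatch(backend(input),
                     error = function(e) stop("MGS classifier backend failed: ",
                                              conditionMessage(e), call. = FALSE))
  logits <- as.matrix(logits)
  if (!all(dim(logits) == c(5L, 4L)))
    stop("classifier backend must return a 5 x 4 logit matrix, got ",
         paste(dim(logits), collapse = " x "))
  probs <- softmaxRows(logits)
  dimnames(probs) <- list(mgsComponents(), mgsClasses())
  probs
}

#' Decode per-head probabilities to component scores
#'
#' Per-head argmax; ties break to the lower class index (0 < 1 < 2 < NR).
#'
#' @param probs 5 x 4 probability (or logit) matrix.
#' @return named character(5) of component scores in
#'   \code{{"0","1","2","NR"}}.
#' @export
decodeComponents <- function(probs) {
  out <- mgsClasses()[apply(probs, 1L, which.max)]
  names(out) <- mgsComponents()
  out
}

#' Composite cross-entropy over the five component heads
#'
#' The training loss is the sum of the per-head cross-entropies:
#' \eqn{L = \sum_h -\log p_h(y_h)}. It is non-negative and zero exactly when
#' every head puts probability one on its target. Uniform predictions give
#' \code{5 * log(4)}.
#'
#' @param probs 5 x 4 matrix of per-head class probabilities (or logits with
#'   \code{fromLogits = TRUE}); row order [mgsComponents()], column order
#'   [mgsClasses()].
#' @param targets character/factor vector of 5 target classes.
#' @param fromLogits apply a per-row softmax first.
#' @param eps probability floor guarding \code{log(0)}.
#' @return numeric(1) loss.
#' @export
compositeCrossEntropy <- function(probs, targets, fromLogits = FALSE,
                                  eps = 1e-12) {
  probs <- as.matrix(probs)
  if (!all(dim(probs) == c(5L, 4L)))
    stop("expected a 5 x 4 matrix (5 heads, 4 classes)")
  targets <- as.character(targets)
  if (length(targets) != 5L)
    stop("expected 5 targets, one per head")
  ti <- match(targets, mgsClasses())
  if (any(is.na(ti)))
    stop("targets must be one of: ", paste(mgsClasses(), collapse = ", "))
  if (fromLogits) probs <- softmaxRows(probs)
  -sum(log(pmax(probs[cbind(1:5, ti)], eps)))
}

#' Decayed learning rate schedule
#'
#' \code{lr = baseLr * decay^floor(epoch / every)} with 0-based epochs, i.e.
#' the rate decays by \code{decay} every \code{every} epochs. Both parameter
#' groups (backbone and heads) share the schedule, so their ratio is
#' constant across training.
#'
#' @param baseLr base learning rate.
#' @param epoch 0-based epoch index (>= 0).
#' @param decay multiplicative decay factor.
#' @param every decay period in epochs.
#' @return numeric learning rate.
#' @examples
#' scheduledLr(0.001, 10)  # 0.001 * 0.01
#' @export
scheduledLr <- function(baseLr, epoch, decay = 0.1, every = 5) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  baseLr * decay^(epoch %/% every)
}

#' Leave-one-animal-out cross-validation folds
#'
#' One fold per distinct animal: the fold's validation set is all of that
#' animal's frames and its training set is everything else, so no animal
#' ever appears on both sides. Folds partition the corpus.
#'
#' @param frames data.frame of labeled frames with an \code{animal_id}
#'   column (no NAs).
#' @return named list of folds, each a list with \code{animal},
#'   \code{train} and \code{validation} (integer row indices into
#'   \code{frames}).
#' @export
makeLoaoFolds <- function(frames) {
  if (!"animal_id" %in% names(frames))
    stop("labeled frames must carry an animal_id column")
  ids <- frames$animal_id
  if (any(is.na(ids)) || any(ids == ""))
    stop("every frame must carry a non-missing animal_id")
  animals <- unique(ids)
  folds <- lapply(animals, function(a) {
    val <- which(ids == a)
    list(animal = a, train = setdiff(seq_along(ids), val), validation = val)
  })
  names(folds) <- animals
  folds
}

#' Animal-disjoint k-fold assignment
#'
#' Generalizes the leave-one-animal-out rule to k folds (as used for the
#' face-detector cross-validation): animals are assigned whole to folds, so
#' no animal's frames are split across folds.
#'
#' @param animalIds character vector of per-frame animal ids.
#' @param k number of folds (2 <= k <= number of distinct animals).
#' @param seed shuffle seed for the animal-to-fold assignment.
#' @return list of k folds, each with \code{animals}, \code{train} and
#'   \code{validation} indices.
#' @export
makeAnimalFolds <- function(animalIds, k, seed = 1) {
  animals <- unique(animalIds)
  if (k < 2 || k > length(animals))
    stop("k must be between 2 and the number of distinct animals")
  shuffled <- withSeed(seed, sample(animals))
  assign <- rep_len(seq_len(k), length(shuffled))
  lapply(seq_len(k), function(f) {
    hold <- shuffled[assign == f]
    val <- which(animalIds %in% hold)
    list(animals = hold, train = setdiff(seq_along(animalIds), val),
         validation = val)
  })
}

#' Temporal content augmentation of a labeled training set
#'
#' Adds, for each labeled frame, the frames immediately preceding and
#' following it (same video) with identical MGS targets — under the
#' assumption that the score varies little within 1/30 s — tripling a fully
#' neighbored training set. Missing neighbors (e.g. at video boundaries) are
#' skipped, not duplicated. Validation sets must never be augmented.
#'
#' @param frames data.frame of labeled frames with at least
#'   \code{video_id} and \code{frame_index} columns (plus target columns,
#'   which are copied verbatim).
#' @param hasFrame \code{function(video_id, frame_index)} returning TRUE if
#'   that frame exists in the frame store.
#' @return data.frame with the augmented rows appended; a logical
#'   \code{augmented} column marks the added neighbors.
#' @export
contentAugment <- function(frames, hasFrame) {
  if (!all(c("video_id", "frame_index") %in% names(frames)))
    stop("frames must have video_id and frame_index columns")
  if (nrow(frames) == 0L) {
    frames$augmented <- logical(0)
    return(frames)
  }
  out <- list(transform(frames, augmented = FALSE))
  for (delta in c(-1L, 1L)) {
    nb <- frames
    nb$frame_index <- nb$frame_index + delta
    keep <- mapply(hasFrame, nb$video_id, nb$frame_index)
    nb <- nb[keep, , drop = FALSE]
    if (nrow(nb)) out[[length(out) + 1L]] <- transform(nb, augmented = TRUE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Training configuration for the MGS classifier
#'
#' Defaults are the published schedule: 20 epochs, batch 16, SGD momentum
#' 0.95, weight decay 0, base learning rates 1e-4 (backbone) and 1e-3
#' (heads) decayed by 0.1 every 5 epochs, with the network state after
#' epoch 10 selected. \code{hidden} and \code{dropout} describe the
#' published head stack (2048/1024 units, input dropout 0.4/0.2) and are
#' carried in the config snapshot for full-scale backends; the shipped
#' reference backbone uses its own, much smaller, hidden layer.
#'
#' @param epochs,batch,momentum,weightDecay,lrBackbone,lrHeads,lrDecay,lrEvery
#'   optimizer settings.
#' @param selectedEpoch epoch whose state is returned (<= epochs).
#' @param hidden,dropout published head-stack description.
#' @param inputSide classifier input side in pixels.
#' @param augment an [augmentationParams()] list applied to training items.
#' @return a validated list of class \code{"trainingConfig"}.
#' @export
trainingConfig <- function(epochs = 20, batch = 16, momentum = 0.95,
                           weightDecay = 0, lrBackbone = 1e-4,
                           lrHeads = 1e-3, lrDecay = 0.1, lrEvery = 5,
                           selectedEpoch = 10, hidden = c(2048, 1024),
                           dropout = c(0.4, 0.2), inputSide = 224,
                           augment = augmentationParams()) {
  if (selectedEpoch > epochs)
    stop("selectedEpoch must be <= epochs")
  if (epochs < 1 || batch < 1) stop("epochs and batch must be >= 1")
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 momentum = momentum, weightDecay = weightDecay,
                 lrBackbone = lrBackbone, lrHeads = lrHeads,
                 lrDecay = lrDecay, lrEvery = lrEvery,
                 selectedEpoch = as.integer(selectedEpoch), hidden = hidden,
                 dropout = dropout, inputSide = as.integer(inputSide),
                 augment = augment),
            class = "trainingConfig")
}
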