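## Desk-scale reference backbone for the MGS classifier.
##
## The published system fine-tunes a pretrained vision transformer; those
## weights are a pluggable heavy backend. For tests and synthetic studies
## the package ships a deliberately tiny trainable network: block-mean
## pooling of the normalized input to a grid of intensity features, one
## tanh hidden layer (the "backbone" parameter group) and five 4-way linear
## heads (the "heads" group). Training uses the published optimizer
## settings: SGD with momentum 0.95, weight decay 0, two base learning
## rates decayed by 0.1 every five epochs, batch 16, stochastic + content
## augmentation on training items only.

## Block-mean pooling of a (side x side [x 3]) input to a grid x grid
## feature vector. Channels are identical for grayscale inputs, so channel 1
## is used.
poolFeatures <- function(input, grid) {
  m <- if (is.matrix(input)) input else input[, , 1L]
  n <- nrow(m); p <- ncol(m)
  rg <- ceiling(seq_len(n) * grid / n)
  cg <- ceiling(seq_len(p) * grid / p)
  s <- rowsum(m, rg)
  s <- rowsum(t(s), cg)
  cnt <- outer(tabulate(cg, grid), tabulate(rg, grid))
  as.numeric(s / cnt)
}

#' Initialize the tiny reference backbone
#'
#' @param inputSide input image side in pixels.
#' @param poolGrid pooling grid (features = poolGrid^2).
#' @param hidden hidden layer width.
#' @param seed initialization seed.
#' @return list of class \code{"mgsBackbone"} with parameter groups
#'   \code{backbone} (W1, b1) and \code{heads} (W2, b2).
#' @export
referenceBackbone <- function(inputSide = 224, poolGrid = 14, hidden = 48,
                              seed = 1) {
  d <- poolGrid^2
  withSeed(seed, {
    structure(list(
      inputSide = inputSide, poolGrid = poolGrid, hidden = hidden,
      backbone = list(W1 = matrix(rnorm(d * hidden, 0, 1 / sqrt(d)), d, hidden),
                      b1 = numeric(hidden)),
      heads = list(W2 = matrix(rnorm(hidden * 20, 0, 1 / sqrt(hidden)),
                               hidden, 20),
                   b2 = numeric(20))),
      class = "mgsBackbone")
  })
}

## Forward pass: X (batch x d) -> list(H, logits (batch x 20)).
backboneForward <- function(net, X) {
  H <- tanh(sweep(X %*% net$backbone$W1, 2L, net$backbone$b1, "+"))
  logits <- sweep(H %*% net$heads$W2, 2L, net$heads$b2, "+")
  list(H = H, logits = logits)
}

## Composite softmax cross-entropy over the 5 heads for a batch, plus the
## gradient w.r.t. the logits (averaged over the batch).
headLossGrad <- function(logits, targetIdx) {
  B <- nrow(logits)
  G <- matrix(0, B, 20L)
  loss <- 0
  for (h in 1:5) {
    cols <- (4L * h - 3L):(4L * h)
    P <- softmaxRows(logits[, cols, drop = FALSE])
    sel <- cbind(seq_len(B), targetIdx[, h])
    loss <- loss - sum(log(pmax(P[sel], 1e-12)))
    P[sel] <- P[sel] - 1
    G[, cols] <- P
  }
  list(loss = loss / B, grad = G / B)
}

## Decode a (batch x 20) logit matrix to a batch x 5 character matrix.
decodeLogitsBatch <- function(logits) {
  out <- matrix("", nrow(logits), 5L, dimnames = list(NULL, mgsComponents()))
  for (h in 1:5) {
    cols <- (4L * h - 3L):(4L * h)
    out[, h] <- mgsClasses()[max.col(logits[, cols, drop = FALSE],
                                     ties.method = "first")]
  }
  out
}

itemTargetIdx <- function(items) {
  t(vapply(items, function(it) {
    ti <- match(as.character(it$targets), mgsClasses())
    if (length(ti) != 5L || any(is.na(ti)))
      stop("each item needs 5 targets from: ",
           paste(mgsClasses(), collapse = ", "))
    ti
  }, integer(5)))
}

## Deterministic validation features for a list of items.
validationFeatures <- function(items, stats, side, poolGrid,
                               expandFraction = 0.05) {
  t(vapply(items, function(it) {
    poolFeatures(validationPreprocess(it$image, it$box, stats, side = side,
                                      expandFraction = expandFraction),
                 poolGrid)
  }, numeric(poolGrid^2)))
}

#' Train the MGS classifier on labeled face frames
#'
#' Desk-scale training harness implementing the published procedure around a
#' trainable backend: SGD with momentum and zero weight decay, distinct base
#' learning rates for the backbone and head parameter groups sharing one
#' decayed schedule ([scheduledLr()]), shuffled batches, stochastic
#' augmentation ([sampleTrainingAugmentation()]) on every training
#' presentation, deterministic validation preprocessing, and selection of
#' the network state after \code{selectedEpoch} epochs. Content augmentation
#' (temporal neighbors) is the caller's responsibility via
#' [contentAugment()] so that validation sets are never augmented.
#'
#' @param items training items: a list, each element a list with
#'   \code{image} (matrix), \code{box} ([Box-class]), \code{targets}
#'   (character(5)) and ids (\code{animal_id}, \code{video_id},
#'   \code{frame_index}).
#' @param config a [trainingConfig()].
#' @param seed training seed (shuffling and augmentation draws).
#' @param backbone an initialized [referenceBackbone()]; defaults to one
#'   matched to \code{config$inputSide}.
#' @param valItems optional validation items (never augmented); per-epoch
#'   per-component accuracy is recorded when supplied.
#' @param stats normalization statistics; computed from the training items'
#'   padded/squared/cropped patches when NULL.
#' @return list of class \code{"mgsModel"}: the selected-epoch network,
#'   \code{stats}, \code{config}, \code{seed}, \code{selectedEpoch} and a
#'   \code{history} data.frame (epoch, lr_backbone, lr_heads, train_loss,
#'   and val_acc_* columns when validation items were given).
#' @export
trainMgs <- function(items, config = trainingConfig(), seed = 1,
                     backbone = NULL, valItems = NULL, stats = NULL) {
  if (length(items) == 0L) stop("training set is empty")
  if (is.null(backbone))
    backbone <- referenceBackbone(inputSide = config$inputSide, seed = seed)
  if (is.null(stats)) {
    patches <- lapply(items, function(it)
      cropWithPadding(it$image, squareBox(expandBox(it$box, 0.05))))
    stats <- computeNormStats(patches)
  }
  targetIdx <- itemTargetIdx(items)
  grid <- backbone$poolGrid
  side <- config$inputSide
  valX <- NULL
  valTargets <- NULL
  if (!is.null(valItems) && length(valItems)) {
    valX <- validationFeatures(valItems, stats, side, grid)
    valTargets <- t(vapply(valItems, function(it) as.character(it$targets),
                           character(5)))
  }

  net <- backbone
  vel <- list(W1 = net$backbone$W1 * 0, b1 = net$backbone$b1 * 0,
              W2 = net$heads$W2 * 0, b2 = net$heads$b2 * 0)
  history <- vector("list", config$epochs)
  selected <- NULL

  withSeed(seed, {
    for (epoch in seq_len(config$epochs)) {
      lrB <- scheduledLr(config$lrBackbone, epoch - 1L, config$lrDecay,
                         config$lrEvery)
      lrH <- scheduledLr(config$lrHeads, epoch - 1L, config$lrDecay,
                         config$lrEvery)
      ord <- sample(length(items))
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = config$batch)) {
        idx <- ord[start:min(start + config$batch - 1L, length(ord))]
        X <- t(vapply(idx, function(i) {
          it <- items[[i]]
          poolFeatures(sampleTrainingAugmentation(it$image, it$box, stats,
                                                  config$augment,
                                                  side = side),
                       grid)
        }, numeric(grid^2)))
        fw <- backboneForward(net, X)
        lg <- headLossGrad(fw$logits, targetIdx[idx, , drop = FALSE])
        losses <- c(losses, lg$loss)
        dW2 <- crossprod(fw$H, lg$grad) + config$weightDecay * net$heads$W2
        db2 <- colSums(lg$grad)
        dH <- (lg$grad %*% t(net$heads$W2)) * (1 - fw$H^2)
        dW1 <- crossprod(X, dH) + config$weightDecay * net$backbone$W1
        db1 <- colSums(dH)
        vel$W2 <- config$momentum * vel$W2 - lrH * dW2
        vel$b2 <- config$momentum * vel$b2 - lrH * db2
        vel$W1 <- config$momentum * vel$W1 - lrB * dW1
        vel$b1 <- config$momentum * vel$b1 - lrB * db1
        net$heads$W2 <- net$heads$W2 + vel$W2
        net$heads$b2 <- net$heads$b2 + vel$b2
        net$backbone$W1 <- net$backbone$W1 + vel$W1
        net$backbone$b1 <- net$backbone$b1 + vel$b1
      }
      row <- data.frame(epoch = epoch, lr_backbone = lrB, lr_heads = lrH,
                        train_loss = mean(losses))
      if (!is.null(valX)) {
        pred <- decodeLogitsBatch(backboneForward(net, valX)$logits)
        acc <- colMeans(pred == valTargets)
        names(acc) <- paste0("val_acc_", mgsComponents())
        row <- cbind(row, as.data.frame(as.list(acc)))
      }
      history[[epoch]] <- row
      if (epoch == config$selectedEpoch) selected <- net
    }
  })
  if (is.null(selected)) selected <- net  # selectedEpoch == epochs
  structure(list(net = selected, stats = stats, config = config,
                 seed = as.integer(seed),
                 selectedEpoch = config$selectedEpoch,
                 history = do.call(rbind, history)),
            class = "mgsModel")
}

#' Predict MGS component probabilities for one face
#'
#' Applies the deterministic validation preprocessing and the trained
#' reference backbone.
#'
#' @param model an \code{"mgsModel"} from [trainMgs()].
#' @param image grayscale frame (numeric matrix).
#' @param box detected face [Box-class].
#' @return 5 x 4 probability matrix (see [classifyComponents()]).
#' @export
predictMgs <- function(model, image, box) {
  classifyComponents(mgsClassifierBackend(model),
                     validationPreprocess(image, box, model$stats,
                                          side = model$config$inputSide))
}

#' Wrap a trained model as a classifier backend
#'
#' @param model an \code{"mgsModel"}.
#' @return \code{function(input)} returning the 5 x 4 logit matrix, suitable
#'   for [classifyComponents()] and [scoreSession()].
#' @export
mgsClassifierBackend <- function(model) {
  net <- model$net
  grid <- net$poolGrid
  function(input) {
    x <- matrix(poolFeatures(input, grid), nrow = 1L)
    logits <- backboneForward(net, x)$logits
    matrix(logits, 5L, 4L, byrow = TRUE,
           dimnames = list(mgsComponents(), mgsClasses()))
  }
}
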