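# Shared fixtures and independent oracles used across the suite.

# Detector backend that always returns one fixed box.
stubDetector <- function(box, confidence = 0.99) {
  force(box)
  function(image) list(list(box = box, confidence = confidence))
}

# Classifier backend emitting near-one-hot logits for fixed component scores.
stubClassifier <- function(components) {
  idx <- match(as.character(components), mgsClasses())
  logits <- matrix(-10, 5, 4)
  logits[cbind(1:5, idx)] <- 10
  function(input) logits
}

# Independent per-pixel crop oracle: walks the patch grid pixel by pixel.
cropOracle <- function(image, x0, y0, x1, y1, fill = 0) {
  gx0 <- floor(x0); gy0 <- floor(y0)
  gx1 <- ceiling(x1); gy1 <- ceiling(y1)
  out <- matrix(fill, gy1 - gy0, gx1 - gx0)
  for (r in seq_len(nrow(out))) {
    for (c in seq_len(ncol(out))) {
      sy <- gy0 + r - 1L   # 0-based source pixel
      sx <- gx0 + c - 1L
      if (sy >= 0 && sy < nrow(image) && sx >= 0 && sx < ncol(image))
        out[r, c] <- image[sy + 1L, sx + 1L]
    }
  }
  out
}

# Independent spacing-rule oracle: explicit while-loop max search instead of
# a sort, same tie policy (highest confidence, then lowest index).
spacingOracle <- function(confidence, minConfidence = 0.5, minGap = 80,
                          maxFrames = 5) {
  idx0 <- seq_along(confidence) - 1L
  pool <- which(confidence >= minConfidence)
  chosen <- integer(0)
  while (length(pool) > 0L && length(chosen) < maxFrames) {
    best <- pool[1L]
    for (j in pool) if (confidence[j] > confidence[best]) best <- j
    pool <- setdiff(pool, best)
    if (all(abs(idx0[best] - chosen) >= minGap))
      chosen <- c(chosen, idx0[best])
  }
  sort(chosen)
}

# Row softmax for building valid probability fixtures in tests.
softmaxRowsForTest <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# Majority-map cluster labels onto true states, then adjusted Rand index.
majorityMappedARI <- function(labels, truth) {
  mapped <- labels
  for (cl in unique(labels)) {
    sel <- labels == cl
    mapped[sel] <- as.integer(names(which.max(table(truth[sel]))))
  }
  mclust::adjustedRandIndex(mapped, truth)
}

# Small keypoint track built by hand: a body part moving along `path`
# (two-column matrix) inside exactly known arena corners.
handTrack <- function(path, corners = rbind(c(0, 0), c(440, 0),
                                            c(440, 280), c(0, 280)),
                      confidence = 1, fps = 30) {
  n <- nrow(path)
  parts <- trackPartSchema()
  X <- matrix(0, n, length(parts), dimnames = list(NULL, parts))
  Y <- matrix(0, n, length(parts), dimnames = list(NULL, parts))
  for (p in parts[1:6]) {
    X[, p] <- path[, 1]
    Y[, p] <- path[, 2]
  }
  # give the head parts a fixed offset so angles/areas are well defined
  X[, "nose"] <- X[, "nose"] + 6
  X[, "left_ear"] <- X[, "left_ear"] + 3
  Y[, "left_ear"] <- Y[, "left_ear"] + 2
  X[, "right_ear"] <- X[, "right_ear"] + 3
  Y[, "right_ear"] <- Y[, "right_ear"] - 2
  X[, "tail_base"] <- X[, "tail_base"] - 6
  X[, "spine_mid"] <- X[, "spine_mid"] - 3
  for (k in 1:4) {
    X[, 6 + k] <- corners[k, 1]
    Y[, 6 + k] <- corners[k, 2]
  }
  C <- matrix(confidence, n, length(parts))
  KeypointTrack(x = X, y = Y, confidence = C, parts = parts, fps = fps)
}
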