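## Frame-quality scoring contract and the two best-frame selection rules.

#' Map a raw network output to the 0--6 quality scale
#'
#' The frame-quality network emits a single raw score through a sigmoid
#' activation; the normalized value is multiplied by 6 to return it to the
#' original 0--6 annotation scale: \code{q = 6 * plogis(r)}.
#'
#' @param raw numeric vector of raw (pre-sigmoid) scores; must be finite.
#' @return numeric vector of quality values in \code{(0, 6)}, strictly
#'   increasing in \code{raw}.
#' @examples
#' qualityFromRaw(0)  # 3.0, the logistic midpoint
#' @export
qualityFromRaw <- function(raw) {
  if (any(!is.finite(raw))) stop("raw scores must be finite")
  6 * plogis(raw)
}

#' Segment-based frame selection configuration
#'
#' Defaults are the published rule: one frame per 10-s segment at 30 fps,
#' kept only if its predicted quality reaches 4.25.
#'
#' @param intervalS segment length in seconds (> 0).
#' @param threshold minimum quality score in \code{[0, 6]}.
#' @param fps frames per second.
#' @return a validated list of class \code{"segmentSelectionConfig"}.
#' @export
segmentSelectionConfig <- function(intervalS = 10, threshold = 4.25, fps = 30) {
  if (!is.finite(intervalS) || intervalS <= 0) stop("intervalS must be > 0")
  if (!is.finite(threshold) || threshold < 0 || threshold > 6)
    stop("threshold must lie in [0, 6]")
  if (!is.finite(fps) || fps <= 0) stop("fps must be > 0")
  structure(list(intervalS = intervalS, threshold = threshold, fps = fps),
            class = "segmentSelectionConfig")
}

#' Spacing-based frame selection configuration
#'
#' Defaults are the published rule: candidate frames need confidence at
#' least 0.5, selected frames must be at least 80 frames apart, and no more
#' than 5 frames are chosen per video.
#'
#' @param minConfidence eligibility gate in \code{[0, 1]}.
#' @param minGapFrames minimum pairwise frame-index difference (>= 0).
#' @param maxFrames maximum number of selected frames (>= 1).
#' @return a validated list of class \code{"spacingSelectionConfig"}.
#' @export
spacingSelectionConfig <- function(minConfidence = 0.5, minGapFrames = 80,
                                   maxFrames = 5) {
  if (minGapFrames < 0) stop("minGapFrames must be >= 0")
  if (maxFrames < 1) stop("maxFrames must be >= 1")
  if (minConfidence < 0 || minConfidence > 1)
    stop("minConfidence must lie in [0, 1]")
  structure(list(minConfidence = minConfidence, minGapFrames = minGapFrames,
                 maxFrames = maxFrames),
            class = "spacingSelectionConfig")
}

#' Select the best frame of every fixed-length video segment
#'
#' Splits the recording into consecutive segments of
#' \code{round(intervalS * fps)} frames (the final partial segment is scored
#' like any other) and, from each segment, selects the frame with the highest
#' predicted quality — ties broken to the lowest frame index — provided that
#' quality reaches the threshold. An empty selection (every frame below
#' threshold) is a valid, non-error outcome.
#'
#' @param series a [QualitySeries-class] or numeric vector of quality values.
#' @param config a [segmentSelectionConfig()].
#' @return integer vector of selected 0-based frame indices, sorted
#'   ascending; at most one per segment.
#' @export
selectBySegments <- function(series, config = segmentSelectionConfig()) {
  if (is(series, "QualitySeries")) {
    q <- series@quality
    config$fps <- series@fps
  } else {
    q <- as.numeric(series)
  }
  n <- length(q)
  if (n == 0L) return(integer(0))
  segLen <- max(1L, as.integer(round(config$intervalS * config$fps)))
  seg <- (seq_len(n) - 1L) %/% segLen
  picks <- vapply(split(seq_len(n), seg), function(idx) {
    best <- idx[which.max(q[idx])]   # which.max ties -> lowest index
    if (q[best] >= config$threshold) best else NA_integer_
  }, integer(1))
  unname(sort(picks[!is.na(picks)])) - 1L
}

#' Select high-confidence frames under a spacing constraint
#'
#' Greedy selection by descending confidence (ties broken to the lower frame
#' index): a frame is accepted if its confidence reaches
#' \code{minConfidence} and it lies at least \code{minGapFrames} frames from
#' every previously accepted frame; selection stops after \code{maxFrames}
#' acceptances.
#'
#' @param confidence numeric vector of per-frame confidences in
#'   \code{[0, 1]} (frame 0 first).
#' @param config a [spacingSelectionConfig()].
#' @return integer vector of selected 0-based frame indices, sorted
#'   ascending.
#' @export
selectWithSpacing <- function(confidence, config = spacingSelectionConfig()) {
  n <- length(confidence)
  if (n == 0L) return(integer(0))
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE))
    stop("confidences must lie in [0, 1]")
  eligible <- which(!is.na(confidence) & confidence >= config$minConfidence)
  if (!length(eligible)) return(integer(0))
  ord <- eligible[order(-confidence[eligible], eligible)]
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) >= config$maxFrames) break
    if (all(abs(accepted - i) >= config$minGapFrames))
      accepted <- c(accepted, i)
  }
  sort(accepted) - 1L
}

#' Eligibility gate from front-camera keypoint confidences
#'
#' Frames where any of the nose or ear keypoints has confidence below the
#' threshold are excluded from frame selection.
#'
#' @param confidences matrix or data.frame with one row per frame and
#'   columns \code{nose}, \code{left_ear}, \code{right_ear} (extra columns
#'   are ignored), or a [KeypointTrack-class].
#' @param threshold confidence threshold (default 0.5).
#' @return logical vector, TRUE where the frame is eligible.
#' @export
gateByKeypointConfidence <- function(confidences, threshold = 0.5) {
  if (is(confidences, "KeypointTrack"))
    confidences <- confidences@confidence
  need <- c("nose", "left_ear", "right_ear")
  missing <- setdiff(need, colnames(confidences))
  if (length(missing))
    stop("missing keypoint column(s): ", paste(missing, collapse = ", "))
  m <- as.matrix(confidences[, need, drop = FALSE])
  if (nrow(m) == 0L) return(logical(0))
  apply(m, 1L, min) >= threshold
}
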