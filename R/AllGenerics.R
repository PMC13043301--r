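#' MGS component names
#'
#' The five facial action units of the mouse grimace scale, in the fixed
#' order used throughout the package.
#'
#' @return character(5): orbital, nose, cheek, ear, whisker.
#' @export
mgsComponents <- function() c("orbital", "nose", "cheek", "ear", "whisker")

#' MGS class labels
#'
#' The four per-component classes: scores 0, 1, 2 and "NR" (not rateable).
#' NR is a first-class category, not missing data.
#'
#' @return character(4).
#' @export
mgsClasses <- function() c("0", "1", "2", "NR")

#' @rdname nFrames
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname framesPerSecond
#' @export
setGeneric("framesPerSecond", function(object) standardGeneric("framesPerSecond"))

#' Number of frames
#'
#' @param object a [QualitySeries-class] or [KeypointTrack-class].
#' @return integer(1) frame count.
#' @rdname nFrames
#' @export
setMethod("nFrames", "QualitySeries", function(object) length(object@quality))

#' @rdname nFrames
setMethod("nFrames", "KeypointTrack", function(object) nrow(object@x))

#' Frame rate accessor
#'
#' @param object a [QualitySeries-class] or [KeypointTrack-class].
#' @return numeric(1) frames per second.
#' @rdname framesPerSecond
#' @export
setMethod("framesPerSecond", "QualitySeries", function(object) object@fps)

#' @rdname framesPerSecond
setMethod("framesPerSecond", "KeypointTrack", function(object) object@fps)

#' Quality values accessor
#'
#' @param object a [QualitySeries-class].
#' @return numeric vector of per-frame quality values in \code{[0, 6]}.
#' @export
qualityValues <- function(object) {
  stopifnot(is(object, "QualitySeries"))
  object@quality
}

#' Part names of a keypoint track
#'
#' @param object a [KeypointTrack-class].
#' @return character vector of part names.
#' @export
trackParts <- function(object) {
  stopifnot(is(object, "KeypointTrack"))
  object@parts
}

#' Coordinates of one part of a keypoint track
#'
#' @param object a [KeypointTrack-class].
#' @param part part name.
#' @return data.frame with columns \code{x}, \code{y}, \code{confidence}.
#' @export
partCoords <- function(object, part) {
  stopifnot(is(object, "KeypointTrack"))
  if (!part %in% object@parts)
    stop("unknown part '", part, "'; track has: ",
         paste(object@parts, collapse = ", "))
  data.frame(x = object@x[, part], y = object@y[, part],
             confidence = object@confidence[, part])
}

#' Records of a scored grimace session
#'
#' @param object a [GrimaceSession-class].
#' @return data.frame of per-frame records.
#' @export
sessionRecords <- function(object) {
  stopifnot(is(object, "GrimaceSession"))
  object@records
}

#' Session metadata accessor
#'
#' @param object a [GrimaceSession-class].
#' @return list of metadata.
#' @export
sessionMetadata <- function(object) {
  stopifnot(is(object, "GrimaceSession"))
  object@metadata
}

#' Transition counts accessor
#'
#' @param object a [TransitionMatrix-class].
#' @return integer matrix of counts.
#' @export
transitionCounts <- function(object) {
  stopifnot(is(object, "TransitionMatrix"))
  object@counts
}

#' Cluster centroids accessor
#'
#' @param object a [ClusterModel-class].
#' @return numeric matrix (k x expanded dimension).
#' @export
clusterCenters <- function(object) {
  stopifnot(is(object, "ClusterModel"))
  object@centers
}

## ---- show methods -----------------------------------------------------

setMethod("show", "Box", function(object) {
  cat(sprintf("Box [%.2f, %.2f) x [%.2f, %.2f)  (%.2f x %.2f px)\n",
              object@x0, object@x1, object@y0, object@y1,
              object@x1 - object@x0, object@y1 - object@y0))
})

setMethod("show", "QualitySeries", function(object) {
  q <- object@quality
  cat(sprintf("QualitySeries: %d frames @ %g fps", length(q), object@fps))
  if (length(q))
    cat(sprintf("; quality %.2f-%.2f (mean %.2f)", min(q), max(q), mean(q)))
  cat("\n")
})

setMethod("show", "KeypointTrack", function(object) {
  cat(sprintf("KeypointTrack: %d frames @ %g fps, %d parts\n",
              nrow(object@x), object@fps, length(object@parts)))
  cat("  parts:", paste(object@parts, collapse = ", "), "\n")
})

setMethod("show", "GrimaceSession", function(object) {
  cat(sprintf("GrimaceSession: %d scored frame(s)\n", nrow(object@records)))
  vm <- object@videoMean
  cat("  video mean MGS:",
      if (length(vm) && !is.na(vm)) sprintf("%.3f", vm) else "undefined (no rateable frames)",
      "\n")
  if (!is.null(object@metadata$animal_id))
    cat("  animal:", object@metadata$animal_id,
        if (!is.null(object@metadata$timepoint))
          paste0("@ ", object@metadata$timepoint), "\n")
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d, %d raw features x window %d (dim %d)\n",
              object@k, length(object@featureNames),
              2L * object@halfwidth + 1L, ncol(object@centers)))
  if (length(object@sampleIds))
    cat("  fitted on", length(object@sampleIds), "recording(s), seed",
        object@seed, "\n")
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix: %d clusters, %d transitions (%s)\n",
              nrow(object@counts), sum(object@counts),
              if (object@includeSelf) "self-transitions included"
              else "self-transitions excluded"))
})

setMethod("show", "FlowComparison", function(object) {
  cat(sprintf("FlowComparison: statistic = %.4f, permutation p = %.4g (%d permutations)\n",
              object@statistic, object@pValue, object@nPermutations))
})
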