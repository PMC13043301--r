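#' Axis-aligned bounding box in pixel coordinates
#'
#' Half-open box \code{[x0, x1) x [y0, y1)} with the origin at the top-left
#' of the image, x increasing rightward and y downward. Coordinates are
#' continuous and may lie outside the image bounds (cropping zero-pads).
#'
#' @slot x0,y0,x1,y1 numeric(1) box boundaries, \code{x1 > x0}, \code{y1 > y0}.
#' @export
setClass("Box", representation(x0 = "numeric", y0 = "numeric",
                               x1 = "numeric", y1 = "numeric"))

setValidity("Box", function(object) {
  v <- c(object@x0, object@y0, object@x1, object@y1)
  if (length(v) != 4L || !all(is.finite(v)))
    return("box coordinates must be four finite numbers")
  if (object@x1 <= object@x0 || object@y1 <= object@y0)
    return("box must have positive width and height (x1 > x0, y1 > y0)")
  TRUE
})

#' Construct a bounding box
#'
#' @param x0,y0 top-left corner (pixels).
#' @param x1,y1 bottom-right corner (pixels, exclusive).
#' @return A [Box-class] object.
#' @examples
#' Box(0, 0, 100, 80)
#' @export
Box <- function(x0, y0, x1, y1) {
  new("Box", x0 = as.numeric(x0), y0 = as.numeric(y0),
      x1 = as.numeric(x1), y1 = as.numeric(y1))
}

#' Per-frame video quality scores on the 0--6 scale
#'
#' Holds one quality value per frame of a front-camera recording, on the
#' continuous 0 (unusable) to 6 (ideal) scale used by the frame-quality
#' network, together with the recording frame rate. Frame indices are
#' 0-based throughout the package.
#'
#' @slot quality numeric vector, each value in \code{[0, 6]}.
#' @slot fps numeric(1), frames per second (> 0).
#' @export
setClass("QualitySeries", representation(quality = "numeric", fps = "numeric"))

setValidity("QualitySeries", function(object) {
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    return("fps must be a single positive number")
  q <- object@quality
  if (length(q) && (any(!is.finite(q)) || any(q < 0) || any(q > 6)))
    return("all quality values must be finite and in [0, 6]")
  TRUE
})

#' Construct a quality series
#'
#' @param quality numeric vector of per-frame quality values in \code{[0, 6]}.
#' @param fps frames per second (default 30).
#' @return A [QualitySeries-class] object.
#' @export
QualitySeries <- function(quality = numeric(), fps = 30) {
  new("QualitySeries", quality = as.numeric(quality), fps = as.numeric(fps))
}

#' Top-camera keypoint track
#'
#' Frames x parts coordinates with per-point confidence, as produced by
#' markerless pose estimation. The default part schema is six mouse parts
#' (\code{nose, left_ear, right_ear, body_center, tail_base, spine_mid})
#' plus four arena corners (\code{arena_corner_1 .. arena_corner_4}), which
#' are expected to be approximately stationary and carry the pixel-to-cm
#' calibration.
#'
#' @slot x,y numeric matrices (frames x parts), pixel coordinates.
#' @slot confidence numeric matrix (frames x parts), values in \code{[0, 1]}.
#' @slot parts character vector of part names (column order of the matrices).
#' @slot fps numeric(1), frames per second.
#' @export
setClass("KeypointTrack",
         representation(x = "matrix", y = "matrix", confidence = "matrix",
                        parts = "character", fps = "numeric"))

setValidity("KeypointTrack", function(object) {
  p <- length(object@parts)
  dims <- list(dim(object@x), dim(object@y), dim(object@confidence))
  if (any(vapply(dims, function(d) d[2] != p, logical(1))))
    return("x, y and confidence must have one column per part")
  if (length(unique(vapply(dims, function(d) d[1], numeric(1)))) != 1L)
    return("x, y and confidence must have the same number of rows")
  cf <- object@confidence
  if (length(cf) && (any(!is.finite(cf)) || any(cf < 0) || any(cf > 1)))
    return("confidence values must be finite and in [0, 1]")
  if (length(object@fps) != 1L || object@fps <= 0)
    return("fps must be a single positive number")
  TRUE
})

#' Construct a keypoint track
#'
#' @param x,y numeric matrices (frames x parts) of pixel coordinates.
#' @param confidence numeric matrix (frames x parts) in \code{[0, 1]};
#'   defaults to all ones.
#' @param parts character vector of part names; defaults to the matrices'
#'   column names.
#' @param fps frames per second (default 30).
#' @return A [KeypointTrack-class] object.
#' @export
KeypointTrack <- function(x, y, confidence = NULL, parts = colnames(x),
                          fps = 30) {
  if (is.null(parts)) stop("part names are required (colnames or `parts`)")
  if (is.null(confidence))
    confidence <- matrix(1, nrow(x), ncol(x))
  colnames(x) <- colnames(y) <- colnames(confidence) <- parts
  new("KeypointTrack", x = as.matrix(x), y = as.matrix(y),
      confidence = as.matrix(confidence), parts = parts,
      fps = as.numeric(fps))
}

#' Scored grimace session
#'
#' Per-selected-frame MGS component scores for one recording, plus the
#' session-level aggregate. Each record holds the five component scores
#' (\code{"0"}, \code{"1"}, \code{"2"} or \code{"NR"} for not rateable), the
#' mean over rateable components (\code{NA} when all five are NR) and the
#' number of rateable components.
#'
#' @slot records data.frame with columns \code{frame_index, timestamp_s,
#'   orbital, nose, cheek, ear, whisker, frame_mean, n_rateable}, sorted by
#'   \code{frame_index}.
#' @slot videoMean numeric(1), mean of the defined frame means (\code{NA}
#'   when no frame has one).
#' @slot metadata list of session metadata (animal id, timepoint, config
#'   snapshot, dropped frames, ...).
#' @export
setClass("GrimaceSession",
         representation(records = "data.frame", videoMean = "numeric",
                        metadata = "list"))

setValidity("GrimaceSession", function(object) {
  need <- c("frame_index", "timestamp_s", mgsComponents(),
            "frame_mean", "n_rateable")
  if (!all(need %in% names(object@records)))
    return(paste("records must contain columns:", paste(need, collapse = ", ")))
  r <- object@records
  if (nrow(r) > 1L && is.unsorted(r$frame_index))
    return("records must be sorted by frame_index")
  fm <- r$frame_mean[!is.na(r$frame_mean)]
  if (length(fm) && (any(fm < 0) || any(fm > 2)))
    return("defined frame means must lie in [0, 2]")
  TRUE
})

#' Fitted behavioral cluster model
#'
#' k-means centroids in the normalized, temporally expanded feature space,
#' together with everything needed to reproduce the assignment on new
#' recordings: the per-column normalization statistics, the expansion
#' half-width, the feature names and the fitting seed.
#'
#' @slot centers numeric matrix (k x expanded dimension).
#' @slot k integer(1) number of clusters.
#' @slot normStats list with \code{center}, \code{scale} and \code{zeroVar}
#'   per raw feature column.
#' @slot halfwidth integer(1) temporal expansion half-width in frames.
#' @slot featureNames character vector of raw feature names.
#' @slot seed integer(1) seed used for the k-means++ fit.
#' @slot sampleIds character vector of recording ids used for fitting.
#' @export
setClass("ClusterModel",
         representation(centers = "matrix", k = "integer", normStats = "list",
                        halfwidth = "integer", featureNames = "character",
                        seed = "integer", sampleIds = "character"))

setValidity("ClusterModel", function(object) {
  if (nrow(object@centers) != object@k)
    return("centroid count must equal k")
  expected <- length(object@featureNames) * (2L * object@halfwidth + 1L)
  if (length(object@featureNames) && ncol(object@centers) != expected)
    return("centroid dimension must be n_features x window length")
  TRUE
})

#' Cluster-to-cluster transition counts for one recording
#'
#' k x k matrix of counts of consecutive-frame movements between behavior
#' clusters. Under the default convention self-transitions are excluded
#' (zero diagonal), matching "transitions between clusters".
#'
#' @slot counts non-negative integer matrix (k x k), rows = source cluster.
#' @slot includeSelf logical(1), whether the diagonal was counted.
#' @export
setClass("TransitionMatrix",
         representation(counts = "matrix", includeSelf = "logical"))

setValidity("TransitionMatrix", function(object) {
  m <- object@counts
  if (nrow(m) != ncol(m)) return("counts must be square")
  if (any(m < 0)) return("counts must be non-negative")
  if (!object@includeSelf && any(diag(m) != 0))
    return("self-transitions excluded but diagonal is non-zero")
  TRUE
})

#' Group comparison of behavior-flow transition structure
#'
#' Result of [flowCompare()]: the observed L1 statistic over mean transition
#' proportions, its permutation p-value, and per-transition one-tailed
#' two-sample z-tests.
#'
#' @slot statistic numeric(1) observed statistic (>= 0).
#' @slot pValue numeric(1) permutation p-value in (0, 1].
#' @slot zTable data.frame with one row per ordered cluster pair: the group
#'   mean proportions, z statistic and one-tailed p-value.
#' @slot nPermutations integer(1).
#' @slot seed integer(1) permutation seed.
#' @export
setClass("FlowComparison",
         representation(statistic = "numeric", pValue = "numeric",
                        zTable = "data.frame", nPermutations = "integer",
                        seed = "integer"))

setValidity("FlowComparison", function(object) {
  if (object@statistic < 0) return("statistic must be non-negative")
  if (object@pValue <= 0 || object@pValue > 1)
    return("permutation p-value must lie in (0, 1]")
  TRUE
})
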