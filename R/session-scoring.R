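## Per-session orchestration (selection -> detection -> crop -> classify ->
## aggregate) and the three session CSV outputs: grimace scores, frame
## timestamps and the pose track.

#' Mean MGS of one frame over its rateable components
#'
#' "Not rateable" components are excluded rather than imputed, keeping the
#' mean on the 0--2 scale; a frame whose five components are all NR has an
#' undefined mean (\code{NA}).
#'
#' @param components character(5) of component scores
#'   (\code{"0"/"1"/"2"/"NR"}).
#' @return numeric(1) mean, or \code{NA} if no component is rateable.
#' @examples
#' frameMeanMgs(c("1", "1", "0", "2", "NR"))  # 1.0
#' @export
frameMeanMgs <- function(components) {
  components <- as.character(components)
  if (length(components) != 5L) stop("expected 5 components")
  num <- suppressWarnings(as.numeric(components[components != "NR"]))
  if (!length(num)) return(NA_real_)
  mean(num)
}

#' Video-level mean MGS of a scored session
#'
#' Mean of the defined per-frame means; frames whose components are all NR
#' are excluded, and the video mean is undefined (\code{NA}) when no frame
#' has a defined mean. (The alternative pooling — averaging all component
#' scores across frames in one pass — is available via
#' \code{pooling = "components"}.)
#'
#' @param session a [GrimaceSession-class].
#' @param pooling \code{"frames"} (default: per-frame means first) or
#'   \code{"components"} (pool all rateable component scores).
#' @return numeric(1) or \code{NA}.
#' @export
videoMeanMgs <- function(session, pooling = c("frames", "components")) {
  pooling <- match.arg(pooling)
  r <- sessionRecords(session)
  if (pooling == "frames") {
    fm <- r$frame_mean[!is.na(r$frame_mean)]
    if (!length(fm)) return(NA_real_)
    return(mean(fm))
  }
  sc <- unlist(r[, mgsComponents()], use.names = FALSE)
  num <- suppressWarnings(as.numeric(sc[sc != "NR"]))
  if (!length(num)) return(NA_real_)
  mean(num)
}

## Build a GrimaceSession from a per-frame record data.frame.
grimaceSession <- function(records, metadata = list()) {
  if (nrow(records)) {
    records <- records[order(records$frame_index), , drop = FALSE]
    rownames(records) <- NULL
  }
  fm <- records$frame_mean[!is.na(records$frame_mean)]
  new("GrimaceSession", records = records,
      videoMean = if (length(fm)) mean(fm) else NA_real_,
      metadata = metadata)
}

emptyRecords <- function() {
  df <- data.frame(frame_index = integer(0), timestamp_s = numeric(0),
                   orbital = character(0), nose = character(0),
                   cheek = character(0), ear = character(0),
                   whisker = character(0), frame_mean = numeric(0),
                   n_rateable = integer(0), stringsAsFactors = FALSE)
  df
}

#' Score one front-camera session
#'
#' The full per-session MGS workflow: select frames (segment rule by
#' default, spacing rule via \code{selection = "spacing"}), detect the face
#' on each selected frame, apply the deterministic validation preprocessing,
#' classify the five components and aggregate. Frames with no face detection
#' are dropped and recorded in the session metadata. Zero selected frames is
#' a valid outcome yielding an empty session with an undefined video mean.
#'
#' @param frames list of grayscale frames (numeric matrices), frame 0 first.
#' @param quality per-frame quality for segment selection: a
#'   [QualitySeries-class], a numeric vector of 0--6 scores, or a
#'   \code{function(image)} returning a raw score that is mapped through
#'   [qualityFromRaw()].
#' @param detector face-detector backend (see [detectFace()]).
#' @param classifier MGS classifier backend (see [classifyComponents()]).
#' @param stats normalization statistics for [validationPreprocess()].
#' @param selection \code{"segments"} or \code{"spacing"}.
#' @param segmentConfig a [segmentSelectionConfig()].
#' @param spacingConfig a [spacingSelectionConfig()]; used with
#'   \code{selection = "spacing"}, in which case \code{confidence} must be
#'   given.
#' @param confidence per-frame confidence series in \code{[0, 1]} for the
#'   spacing rule.
#' @param fps frames per second (timestamps are \code{frame_index / fps}
#'   unless \code{timestamps} is supplied).
#' @param timestamps optional explicit per-frame timestamps (seconds).
#' @param side classifier input side.
#' @param metadata list merged into the session metadata.
#' @return a [GrimaceSession-class].
#' @export
scoreSession <- function(frames, quality = NULL, detector, classifier, stats,
                         selection = c("segments", "spacing"),
                         segmentConfig = segmentSelectionConfig(),
                         spacingConfig = spacingSelectionConfig(),
                         confidence = NULL, fps = 30, timestamps = NULL,
                         side = 224, metadata = list()) {
  selection <- match.arg(selection)
  n <- length(frames)
  if (selection == "segments") {
    if (is.function(quality)) {
      q <- qualityFromRaw(vapply(frames, quality, numeric(1)))
    } else if (is(quality, "QualitySeries")) {
      q <- qualityValues(quality)
      fps <- framesPerSecond(quality)
    } else {
      q <- as.numeric(quality)
    }
    if (length(q) != n)
      stop("quality series length (", length(q),
           ") does not match frame count (", n, ")")
    segmentConfig$fps <- fps
    picks <- selectBySegments(q, segmentConfig)
  } else {
    if (is.null(confidence))
      stop("spacing selection needs a per-frame confidence series")
    if (length(confidence) != n)
      stop("confidence series length does not match frame count")
    picks <- selectWithSpacing(confidence, spacingConfig)
  }

  rows <- list()
  dropped <- integer(0)
  for (i in picks) {
    frame <- frames[[i + 1L]]
    det <- tryCatch(detectFace(detector, frame),
                    error = function(e) stop("frame ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (is.null(det)) {
      dropped <- c(dropped, i)
      next
    }
    input <- validationPreprocess(frame, det$box, stats, side = side)
    probs <- tryCatch(classifyComponents(classifier, input),
                      error = function(e) stop("frame ", i, ": ",
                                               conditionMessage(e), call. = FALSE))
    comps <- decodeComponents(probs)
    ts <- if (!is.null(timestamps)) timestamps[i + 1L] else i / fps
    rows[[length(rows) + 1L]] <- data.frame(
      frame_index = i, timestamp_s = ts,
      orbital = comps["orbital"], nose = comps["nose"],
      cheek = comps["cheek"], ear = comps["ear"],
      whisker = comps["whisker"],
      frame_mean = frameMeanMgs(comps),
      n_rateable = sum(comps != "NR"), stringsAsFactors = FALSE)
  }
  records <- if (length(rows)) do.call(rbind, rows) else emptyRecords()
  meta <- c(metadata,
            list(selection = selection, fps = fps, n_frames = n,
                 dropped_frames = dropped,
                 config = if (selection == "segments")
                   unclass(segmentConfig) else unclass(spacingConfig)))
  grimaceSession(records, meta)
}

fmtNum <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- ""
  out
}

#' Write the three per-session CSV files
#'
#' Emits, into \code{dir}: \code{grimace.csv} (frame_index, timestamp_s, the
#' five components with NR written as \code{"NR"}, frame_mean with undefined
#' means as empty fields, n_rateable), \code{timestamps.csv} (frame_index,
#' camera, timestamp_s for both cameras) and \code{pose.csv} (the keypoint
#' dialect of [writePoseTrack()]). Numeric fields are written with full
#' precision so the write/read round trip is lossless.
#'
#' @param session a [GrimaceSession-class].
#' @param track the session's [KeypointTrack-class] (top camera).
#' @param dir output directory (created if needed).
#' @param frontFrames number of front-camera frames (defaults to the
#'   session metadata's \code{n_frames}).
#' @param fps front-camera frame rate (defaults to metadata).
#' @return character(3) of the written paths, invisibly.
#' @export
writeSessionOutputs <- function(session, track, dir,
                                frontFrames = NULL, fps = NULL) {
  stopifnot(is(session, "GrimaceSession"), is(track, "KeypointTrack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- sessionMetadata(session)
  if (is.null(frontFrames)) frontFrames <- meta$n_frames
  if (is.null(fps)) fps <- if (!is.null(meta$fps)) meta$fps else 30
  if (is.null(frontFrames))
    stop("front frame count unknown: supply frontFrames")

  r <- sessionRecords(session)
  g <- data.frame(frame_index = r$frame_index,
                  timestamp_s = fmtNum(r$timestamp_s),
                  orbital = r$orbital, nose = r$nose, cheek = r$cheek,
                  ear = r$ear, whisker = r$whisker,
                  frame_mean = fmtNum(r$frame_mean),
                  n_rateable = r$n_rateable, stringsAsFactors = FALSE)
  grimacePath <- file.path(dir, "grimace.csv")
  write.csv(g, grimacePath, row.names = FALSE, quote = FALSE)

  tsFront <- data.frame(frame_index = seq_len(frontFrames) - 1L,
                        camera = "front",
                        timestamp_s = fmtNum((seq_len(frontFrames) - 1L) / fps))
  nTop <- nFrames(track)
  tsTop <- data.frame(frame_index = seq_len(nTop) - 1L, camera = "top",
                      timestamp_s = fmtNum((seq_len(nTop) - 1L) /
                                             framesPerSecond(track)))
  tsPath <- file.path(dir, "timestamps.csv")
  write.csv(rbind(tsFront, tsTop), tsPath, row.names = FALSE, quote = FALSE)

  posePath <- file.path(dir, "pose.csv")
  writePoseTrack(track, posePath)
  invisible(c(grimace = grimacePath, timestamps = tsPath, pose = posePath))
}

#' Read a grimace CSV back into a record data.frame
#'
#' Inverse of the \code{grimace.csv} writer: empty frame-mean fields become
#' \code{NA}, component columns stay character.
#'
#' @param path path to a grimace CSV.
#' @return data.frame of records.
#' @export
readGrimaceCsv <- function(path) {
  df <- read.csv(path, colClasses = c(frame_index = "integer",
                                      timestamp_s = "numeric",
                                      orbital = "character",
                                      nose = "character",
                                      cheek = "character",
                                      ear = "character",
                                      whisker = "character",
                                      frame_mean = "character",
                                      n_rateable = "integer"))
  df$frame_mean <- suppressWarnings(as.numeric(df$frame_mean))
  df
}

#' Write a keypoint track in the three-row-header pose CSV dialect
#'
#' Row 1 names the scorer, row 2 repeats each body-part name three times,
#' row 3 cycles \code{x, y, likelihood}; data rows are indexed by frame.
#'
#' @param track a [KeypointTrack-class].
#' @param path output path.
#' @param scorer scorer label for the first header row.
#' @return \code{path}, invisibly.
#' @export
writePoseTrack <- function(track, path, scorer = "mgsflow_synthetic") {
  stopifnot(is(track, "KeypointTrack"))
  parts <- trackParts(track)
  nP <- length(parts)
  n <- nFrames(track)
  header1 <- c("scorer", rep(scorer, 3L * nP))
  header2 <- c("bodyparts", rep(parts, each = 3L))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), nP))
  body <- matrix("", n, 3L * nP)
  for (j in seq_len(nP)) {
    body[, 3L * j - 2L] <- fmtNum(track@x[, j])
    body[, 3L * j - 1L] <- fmtNum(track@y[, j])
    body[, 3L * j] <- fmtNum(track@confidence[, j])
  }
  lines <- c(paste(header1, collapse = ","),
             paste(header2, collapse = ","),
             paste(header3, collapse = ","),
             paste(seq_len(n) - 1L, apply(body, 1L, paste, collapse = ","),
                   sep = ","))
  if (n == 0L) lines <- lines[1:3]
  writeLines(lines, path)
  invisible(path)
}

#' Read a pose CSV in the three-row-header keypoint dialect
#'
#' @param path path to a pose CSV.
#' @param fps frame rate to attach (the dialect does not store it).
#' @return a [KeypointTrack-class] with parts ordered as in the header and
#'   the likelihood column mapped to confidence.
#' @export
readPoseTrack <- function(path, fps = 30) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("pose CSV must have three header rows")
  h1 <- strsplit(lines[1L], ",", fixed = TRUE)[[1]]
  h2 <- strsplit(lines[2L], ",", fixed = TRUE)[[1]]
  h3 <- strsplit(lines[3L], ",", fixed = TRUE)[[1]]
  if (h2[1L] != "bodyparts" || h3[1L] != "coords")
    stop("malformed pose header: expected 'bodyparts' and 'coords' rows")
  if (length(h2) != length(h3) || length(h2) != length(h1))
    stop("malformed pose header: row lengths differ")
  bp <- h2[-1L]; co <- h3[-1L]
  if (length(bp) %% 3L != 0L)
    stop("malformed pose header: column count not a multiple of 3")
  parts <- bp[seq(1L, length(bp), by = 3L)]
  for (j in seq_along(parts)) {
    cols <- (3L * j - 2L):(3L * j)
    if (length(unique(bp[cols])) != 1L)
      stop("malformed pose header: body part '", parts[j],
           "' does not span three columns")
    if (!identical(co[cols], c("x", "y", "likelihood")))
      stop("malformed pose header: expected x,y,likelihood for body part '",
           parts[j], "'")
  }
  n <- length(lines) - 3L
  nP <- length(parts)
  X <- matrix(0, n, nP); Y <- matrix(0, n, nP); C <- matrix(1, n, nP)
  if (n > 0L) {
    data <- do.call(rbind, lapply(lines[-(1:3)], function(l)
      as.numeric(strsplit(l, ",", fixed = TRUE)[[1]])))
    if (ncol(data) != 1L + 3L * nP)
      stop("pose data rows do not match the header layout")
    for (j in seq_len(nP)) {
      X[, j] <- data[, 3L * j - 1L]
      Y[, j] <- data[, 3L * j]
      C[, j] <- data[, 3L * j + 1L]
    }
  }
  KeypointTrack(x = X, y = Y, confidence = pmin(pmax(C, 0), 1), parts = parts,
                fps = fps)
}
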