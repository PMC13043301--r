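## Pose feature engineering: the 41-feature manifest, per-frame extraction
## and the normalize + temporal-expansion step that feeds clustering.

featureTypes <- c("point_acceleration", "point_speed", "pair_distance",
                  "border_distance", "pair_angle", "polygon_area",
                  "axis_angular_velocity")

manifestRow <- function(type, parts, name) {
  data.frame(type = type, parts = paste(parts, collapse = ";"), name = name,
             stringsAsFactors = FALSE)
}

#' Default 41-feature manifest
#'
#' The published pipeline computes 41 pose features — accelerations and
#' speeds of points, distances between point pairs and to the nearest arena
#' border, angles between point pairs, and areas spanned by multiple points.
#' The exact membership is configurable; this default fixes the documented
#' category composition: 6 point accelerations + 6 point speeds + 13 pair
#' distances + 6 border distances + 7 pair angles + 2 polygon areas + 1
#' body-axis angular velocity = 41, over the six mouse parts of
#' [trackPartSchema()].
#'
#' @return data.frame with columns \code{type}, \code{parts}
#'   (\code{";"}-separated part arguments) and \code{name}; 41 rows.
#' @export
defaultFeatureManifest <- function() {
  mouse <- trackPartSchema()[1:6]
  rows <- list()
  for (p in mouse) rows[[length(rows) + 1L]] <-
    manifestRow("point_acceleration", p, paste0("accel_", p))
  for (p in mouse) rows[[length(rows) + 1L]] <-
    manifestRow("point_speed", p, paste0("speed_", p))
  pairs <- list(c("nose", "left_ear"), c("nose", "right_ear"),
                c("nose", "body_center"), c("nose", "tail_base"),
                c("nose", "spine_mid"), c("left_ear", "right_ear"),
                c("left_ear", "body_center"), c("left_ear", "tail_base"),
                c("right_ear", "body_center"), c("right_ear", "tail_base"),
                c("body_center", "tail_base"), c("body_center", "spine_mid"),
                c("spine_mid", "tail_base"))
  for (pr in pairs) rows[[length(rows) + 1L]] <-
    manifestRow("pair_distance", pr, paste0("dist_", pr[1], "_", pr[2]))
  for (p in mouse) rows[[length(rows) + 1L]] <-
    manifestRow("border_distance", p, paste0("border_", p))
  # signed angle between segment (a1 -> a2) and segment (b1 -> b2)
  angles <- list(c("spine_mid", "nose", "tail_base", "spine_mid"),
                 c("body_center", "nose", "tail_base", "body_center"),
                 c("nose", "left_ear", "nose", "right_ear"),
                 c("nose", "left_ear", "body_center", "tail_base"),
                 c("nose", "right_ear", "body_center", "tail_base"),
                 c("body_center", "left_ear", "body_center", "tail_base"),
                 c("body_center", "right_ear", "body_center", "tail_base"))
  for (i in seq_along(angles)) rows[[length(rows) + 1L]] <-
    manifestRow("pair_angle", angles[[i]], paste0("angle_", i))
  rows[[length(rows) + 1L]] <-
    manifestRow("polygon_area", c("nose", "left_ear", "right_ear"),
                "area_head")
  rows[[length(rows) + 1L]] <-
    manifestRow("polygon_area",
                c("left_ear", "right_ear", "tail_base"), "area_body")
  rows[[length(rows) + 1L]] <-
    manifestRow("axis_angular_velocity", c("spine_mid", "nose"),
                "angvel_body_axis")
  do.call(rbind, rows)
}

partXY <- function(track, part) {
  if (!part %in% trackParts(track))
    stop("track is missing part '", part, "'")
  cbind(track@x[, part], track@y[, part])
}

## Centered second difference magnitude, replicated at both edges.
pointAcceleration <- function(p) {
  n <- nrow(p)
  nxt <- pmin(seq_len(n) + 1L, n)
  prv <- pmax(seq_len(n) - 1L, 1L)
  ax <- p[nxt, 1] - 2 * p[, 1] + p[prv, 1]
  ay <- p[nxt, 2] - 2 * p[, 2] + p[prv, 2]
  a <- sqrt(ax^2 + ay^2)
  a[1] <- a[2]; a[n] <- a[n - 1]
  a
}

pointSpeed <- function(p) {
  d <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  c(d[1], d)
}

wrapAngle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

## Arena rectangle estimated from the mean corner positions.
arenaBoundsFromTrack <- function(track) {
  corners <- paste0("arena_corner_", 1:4)
  if (!all(corners %in% trackParts(track)))
    stop("track is missing part '",
         setdiff(corners, trackParts(track))[1], "'")
  cx <- colMeans(track@x[, corners, drop = FALSE])
  cy <- colMeans(track@y[, corners, drop = FALSE])
  list(x0 = min(cx), x1 = max(cx), y0 = min(cy), y1 = max(cy),
       corners = cbind(cx, cy))
}

#' Extract per-frame pose features
#'
#' Computes one column per manifest entry: point accelerations (centered
#' second differences of position, magnitude), point speeds (first
#' differences), pairwise distances, distance to the nearest arena border
#' (from the corner keypoints), signed angles between two segment vectors,
#' shoelace polygon areas and the body-axis angular velocity. First/last
#' frames use replicated-difference padding so the output has one row per
#' frame.
#'
#' @param track a [KeypointTrack-class] with at least 3 frames.
#' @param manifest a manifest data.frame (default
#'   [defaultFeatureManifest()]).
#' @return numeric matrix (frames x features) with the manifest names as
#'   column names.
#' @export
extractFeatures <- function(track, manifest = defaultFeatureManifest()) {
  stopifnot(is(track, "KeypointTrack"))
  n <- nFrames(track)
  if (n < 3L) stop("need at least 3 frames for kinematic features")
  bounds <- NULL
  cols <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    type <- manifest$type[i]
    parts <- strsplit(manifest$parts[i], ";", fixed = TRUE)[[1]]
    cols[[i]] <- switch(
      type,
      point_acceleration = pointAcceleration(partXY(track, parts[1])),
      point_speed = pointSpeed(partXY(track, parts[1])),
      pair_distance = {
        a <- partXY(track, parts[1]); b <- partXY(track, parts[2])
        sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
      },
      border_distance = {
        if (is.null(bounds)) bounds <- arenaBoundsFromTrack(track)
        p <- partXY(track, parts[1])
        pmin(p[, 1] - bounds$x0, bounds$x1 - p[, 1],
             p[, 2] - bounds$y0, bounds$y1 - p[, 2])
      },
      pair_angle = {
        a1 <- partXY(track, parts[1]); a2 <- partXY(track, parts[2])
        b1 <- partXY(track, parts[3]); b2 <- partXY(track, parts[4])
        v1x <- a2[, 1] - a1[, 1]; v1y <- a2[, 2] - a1[, 2]
        v2x <- b2[, 1] - b1[, 1]; v2y <- b2[, 2] - b1[, 2]
        atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y)
      },
      polygon_area = {
        ps <- lapply(parts, partXY, track = track)
        m <- length(ps)
        area <- 0
        for (j in seq_len(m)) {
          a <- ps[[j]]; b <- ps[[j %% m + 1L]]
          area <- area + a[, 1] * b[, 2] - b[, 1] * a[, 2]
        }
        abs(area) / 2
      },
      axis_angular_velocity = {
        a <- partXY(track, parts[1]); b <- partXY(track, parts[2])
        phi <- atan2(b[, 2] - a[, 2], b[, 1] - a[, 1])
        d <- wrapAngle(diff(phi))
        c(d[1], d)
      },
      stop("unknown feature type: ", type))
  }
  out <- do.call(cbind, cols)
  colnames(out) <- manifest$name
  out
}

#' Z-score features and expand them over a temporal window
#'
#' Normalizes each feature column to mean 0 / sd 1 over the fitting corpus
#' (statistics are stored for reuse on new recordings; zero-variance columns
#' are passed through as zeros with a warning) and concatenates, for every
#' frame, the window \code{frame - halfwidth .. frame + halfwidth} (edges
#' padded by replication), giving an expanded width of
#' \code{ncol(features) * (2 * halfwidth + 1)} — 41 x 31 = 1,271 under the
#' defaults.
#'
#' @param features numeric matrix (frames x features).
#' @param halfwidth window half-width in frames (default 15).
#' @param stats optional list with \code{center} and \code{scale} from a
#'   previous fit; computed from \code{features} when NULL.
#' @return list with \code{expanded} (matrix) and \code{stats}.
#' @export
normalizeAndExpand <- function(features, halfwidth = 15, stats = NULL) {
  features <- as.matrix(features)
  if (ncol(features) < 1L) stop("need at least one feature column")
  if (halfwidth < 0) stop("halfwidth must be >= 0")
  if (is.null(stats)) {
    center <- colMeans(features)
    scale <- apply(features, 2L, sd)
    zero <- !is.finite(scale) | scale == 0
    if (any(zero)) {
      warning("zero-variance feature column(s) passed through as zeros: ",
              paste(colnames(features)[zero], collapse = ", "))
      scale[zero] <- 1
    }
    stats <- list(center = center, scale = scale, zeroVar = zero)
  }
  z <- sweep(sweep(features, 2L, stats$center, "-"), 2L, stats$scale, "/")
  if (any(stats$zeroVar)) z[, stats$zeroVar] <- 0
  n <- nrow(z)
  h <- as.integer(halfwidth)
  blocks <- lapply(-h:h, function(off) {
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    z[idx, , drop = FALSE]
  })
  expanded <- do.call(cbind, blocks)
  colnames(expanded) <- paste0(rep(colnames(z), 2L * h + 1L), "_t",
                               rep(-h:h, each = ncol(z)))
  list(expanded = expanded, stats = stats, halfwidth = h,
       featureNames = colnames(features))
}
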