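## Procedural grimace-face generator.
##
## Faces are drawn from geometric primitives (ellipses, rectangles, line
## strokes) on a grayscale canvas; no photographs are involved. Each MGS
## component score controls one monotone geometric trait with a linear
## mapping over a documented range, so downstream classifiers have a
## recoverable signal and tests can measure the trait directly.

#' Ground-truth face phenotype for the synthetic renderer
#'
#' @param orbital,nose,cheek,ear,whisker integer component scores in
#'   \code{{0, 1, 2}}.
#' @param rateable logical(5), one flag per component in the order of
#'   [mgsComponents()]; FALSE renders the component's region occluded and
#'   marks its ground-truth score as \code{"NR"}.
#' @param implant draw a head implant (gray block on top of the head).
#' @param wetFur darken streaks on the lower face.
#' @return a validated list of class \code{"facePhenotype"}.
#' @export
facePhenotype <- function(orbital = 0, nose = 0, cheek = 0, ear = 0,
                          whisker = 0, rateable = rep(TRUE, 5),
                          implant = FALSE, wetFur = FALSE) {
  scores <- c(orbital = orbital, nose = nose, cheek = cheek, ear = ear,
              whisker = whisker)
  if (any(!scores %in% 0:2))
    stop("component scores must be 0, 1 or 2")
  if (length(rateable) != 5L || !is.logical(rateable))
    stop("rateable must be 5 logical flags")
  structure(list(orbital = orbital, nose = nose, cheek = cheek, ear = ear,
                 whisker = whisker, rateable = rateable,
                 implant = isTRUE(implant), wetFur = isTRUE(wetFur)),
            class = "facePhenotype")
}

#' Render configuration for the synthetic face generator
#'
#' @param width,height canvas size in pixels (>= 64; default 256 x 256, with
#'   1280 x 1024 available for full-scale frames).
#' @param headYaw head rotation away from the camera, degrees.
#' @param blurSigma Gaussian motion-blur sigma in pixels (>= 0).
#' @param brightness multiplicative brightness factor (> 0).
#' @param backgroundLevel background intensity in \code{[0, 1]}.
#' @return a validated list of class \code{"renderConfig"}.
#' @export
renderConfig <- function(width = 256, height = 256, headYaw = 0,
                         blurSigma = 0, brightness = 1,
                         backgroundLevel = 0.25) {
  v <- c(width, height, headYaw, blurSigma, brightness, backgroundLevel)
  if (any(!is.finite(v))) stop("render parameters must be finite")
  if (width < 64 || height < 64) stop("canvas must be at least 64 x 64")
  if (blurSigma < 0) stop("blurSigma must be >= 0")
  if (brightness <= 0) stop("brightness must be > 0")
  if (backgroundLevel < 0 || backgroundLevel > 1)
    stop("backgroundLevel must lie in [0, 1]")
  structure(list(width = width, height = height, headYaw = headYaw,
                 blurSigma = blurSigma, brightness = brightness,
                 backgroundLevel = backgroundLevel),
            class = "renderConfig")
}

## Evaluate expr with a temporary RNG state seeded by `seed`.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Continuous pixel coordinates: pixel (row r, col c) has center
## (x = c - 0.5, y = r - 0.5), matching the half-open Box convention.
drawEllipse <- function(img, cx, cy, rx, ry, value, add = FALSE) {
  rows <- max(1L, floor(cy - ry)):min(nrow(img), ceiling(cy + ry + 1))
  cols <- max(1L, floor(cx - rx)):min(ncol(img), ceiling(cx + rx + 1))
  if (!length(rows) || !length(cols)) return(img)
  py <- rows - 0.5
  px <- cols - 0.5
  mask <- outer(((py - cy) / ry)^2, ((px - cx) / rx)^2, "+") <= 1
  sub <- img[rows, cols, drop = FALSE]
  sub[mask] <- if (add) sub[mask] + value else value
  img[rows, cols] <- sub
  img
}

drawRect <- function(img, x0, y0, x1, y1, value) {
  rows <- max(1L, floor(y0 + 1)):min(nrow(img), ceiling(y1))
  cols <- max(1L, floor(x0 + 1)):min(ncol(img), ceiling(x1))
  if (length(rows) && length(cols)) img[rows, cols] <- value
  img
}

drawSegment <- function(img, x0, y0, x1, y1, value, halfwidth = 0.7) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  t <- seq(0, 1, length.out = max(2L, ceiling(len * 2)))
  px <- x0 + t * (x1 - x0)
  py <- y0 + t * (y1 - y0)
  for (dx in c(-halfwidth, 0, halfwidth)) {
    r <- round(py + 0.5)
    c <- round(px + dx + 0.5)
    ok <- r >= 1 & r <= nrow(img) & c >= 1 & c <= ncol(img)
    img[cbind(r[ok], c[ok])] <- value
  }
  img
}

#' Ground-truth frame quality from blur and head yaw
#'
#' The 0--6 quality scale rates suitability for MGS scoring (face visible,
#' facing the camera, not motion-blurred). The synthetic ground truth
#' factorizes as \code{q = 6 * f(blur) * g(yaw)} with documented
#' piecewise-linear maps: \code{f} falls linearly from 1 at sigma = 0 to 0 at
#' sigma = 6 px; \code{g} falls linearly from 1 at 0 degrees to 0 at 60
#' degrees of yaw. Both maps are non-increasing, so ground-truth quality is
#' monotone in blur and |yaw|, and a noiseless frontal render scores exactly
#' 6.
#'
#' @param blurSigma Gaussian blur sigma in pixels (>= 0).
#' @param headYaw head yaw in degrees.
#' @return quality value(s) in \code{[0, 6]}.
#' @export
qualityGroundTruth <- function(blurSigma, headYaw = 0) {
  f <- pmin(1, pmax(0, 1 - blurSigma / 6))
  g <- pmin(1, pmax(0, 1 - abs(headYaw) / 60))
  6 * f * g
}

#' Render a parametric grimace face
#'
#' Draws a procedural mouse face whose geometry encodes the five MGS
#' component scores linearly:
#' \itemize{
#'   \item orbital tightening shrinks the eye aperture (vertical semi-axis
#'     scaled by \code{1 - 0.4 * score});
#'   \item nose bulge brightens/enlarges a ridge above the nose
#'     (\code{+0.11 * score} intensity);
#'   \item cheek bulge brightens the cheek pads (\code{+0.10 * score});
#'   \item ear position pulls the ears down and back and flattens them
#'     (\code{0.14 * score} of the face height, width scaled by
#'     \code{1 - 0.18 * score});
#'   \item whisker change droops the whiskers (\code{22 * score} degrees)
#'     and draws them heavier.
#' }
#' Components flagged not-rateable are occluded with a background-level
#' rectangle. The render is a pure function of \code{(phenotype, render,
#' seed)}.
#'
#' @param phenotype a [facePhenotype()].
#' @param render a [renderConfig()].
#' @param seed integer seed for the pixel noise.
#' @return list with \code{image} (numeric matrix, rows = y, values in
#'   \code{[0, 1]}) and \code{truth}: a list with the ground-truth
#'   [Box-class] \code{box}, the 5 component scores as characters
#'   (\code{"NR"} where not rateable) in \code{components}, and the
#'   \code{quality} ground truth.
#' @export
renderFace <- function(phenotype, render = renderConfig(), seed = 1) {
  stopifnot(inherits(phenotype, "facePhenotype"),
            inherits(render, "renderConfig"))
  W <- render$width; H <- render$height
  withSeed(seed, {
    img <- matrix(render$backgroundLevel + rnorm(W * H, 0, 0.01), H, W)

    yawRad <- render$headYaw * pi / 180
    cx <- W / 2 + (render$headYaw / 60) * 0.15 * W
    cy <- H * 0.54
    fx <- 0.26 * W * max(0.5, cos(yawRad))
    fy <- 0.30 * H

    # head
    img <- drawEllipse(img, cx, cy, fx, fy, 0.72)

    # ears: ear-position score pulls them down/back and flattens them
    earDrop <- 0.14 * phenotype$ear * fy
    earRx <- 0.38 * fx * (1 - 0.18 * phenotype$ear)
    earRy <- 0.30 * fy
    earY <- cy - 0.82 * fy + earDrop
    img <- drawEllipse(img, cx - 0.95 * fx, earY, earRx, earRy, 0.55)
    img <- drawEllipse(img, cx + 0.95 * fx, earY, earRx, earRy, 0.55)

    # implant sits on top of the head, partially covering it
    if (phenotype$implant)
      img <- drawRect(img, cx - 0.35 * fx, cy - 1.18 * fy,
                      cx + 0.35 * fx, cy - 0.80 * fy, 0.92)

    # eyes: orbital tightening closes the aperture linearly
    eyeRy <- 0.13 * fy * (1 - 0.4 * phenotype$orbital)
    eyeY <- cy - 0.18 * fy
    img <- drawEllipse(img, cx - 0.42 * fx, eyeY, 0.16 * fx, eyeRy, 0.08)
    img <- drawEllipse(img, cx + 0.42 * fx, eyeY, 0.16 * fx, eyeRy, 0.08)

    # nose tip + nose-bulge ridge
    noseY <- cy + 0.55 * fy
    if (phenotype$nose > 0)
      img <- drawEllipse(img, cx, cy + 0.34 * fy, 0.16 * fx,
                         (0.08 + 0.05 * phenotype$nose) * fy,
                         0.11 * phenotype$nose, add = TRUE)
    img <- drawEllipse(img, cx, noseY, 0.08 * fx, 0.06 * fy, 0.15)

    # cheek pads
    if (phenotype$cheek > 0) {
      img <- drawEllipse(img, cx - 0.55 * fx, cy + 0.22 * fy, 0.20 * fx,
                         0.16 * fy, 0.10 * phenotype$cheek, add = TRUE)
      img <- drawEllipse(img, cx + 0.55 * fx, cy + 0.22 * fy, 0.20 * fx,
                         0.16 * fy, 0.10 * phenotype$cheek, add = TRUE)
    }

    # whiskers droop with the whisker-change score
    droop <- 22 * phenotype$whisker * pi / 180
    wLen <- 0.85 * fx
    for (side in c(-1, 1)) {
      x0 <- cx + side * 0.25 * fx
      y0 <- cy + 0.42 * fy
      for (a0 in c(-12, 0, 12) * pi / 180) {
        ang <- a0 + droop
        img <- drawSegment(img, x0, y0,
                           x0 + side * wLen * cos(ang), y0 + wLen * sin(ang),
                           0.25,
                           halfwidth = 0.5 + 0.4 * phenotype$whisker)
      }
    }

    if (phenotype$wetFur) {
      for (i in 1:4) {
        sx <- cx + runif(1, -0.6, 0.6) * fx
        img <- drawSegment(img, sx, cy + 0.1 * fy, sx + runif(1, -4, 4),
                           cy + 0.9 * fy, 0.45)
      }
    }

    # not-rateable components are occluded with background-level blocks
    occl <- render$backgroundLevel
    if (!phenotype$rateable[1])  # orbital: eye band
      img <- drawRect(img, cx - 0.65 * fx, eyeY - 0.22 * fy,
                      cx + 0.65 * fx, eyeY + 0.22 * fy, occl)
    if (!phenotype$rateable[2])  # nose region
      img <- drawRect(img, cx - 0.25 * fx, cy + 0.2 * fy,
                      cx + 0.25 * fx, cy + 0.7 * fy, occl)
    if (!phenotype$rateable[3])  # cheeks
      img <- drawRect(img, cx - 0.8 * fx, cy + 0.05 * fy,
                      cx + 0.8 * fx, cy + 0.4 * fy, occl)
    if (!phenotype$rateable[4])  # ears
      img <- drawRect(img, cx - 1.35 * fx, earY - 0.35 * fy,
                      cx + 1.35 * fx, earY + 0.35 * fy, occl)
    if (!phenotype$rateable[5])  # whisker field
      img <- drawRect(img, cx - 1.15 * fx, cy + 0.3 * fy,
                      cx + 1.15 * fx, cy + 0.95 * fy, occl)

    if (render$blurSigma > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = render$blurSigma))
    img <- pmin(pmax(img * render$brightness, 0), 1)

    # ground-truth box: union of head, ears, whisker tips and implant
    x0 <- cx - max(0.95 * fx + earRx, 0.25 * fx + wLen + 1)
    x1 <- cx + max(0.95 * fx + earRx, 0.25 * fx + wLen + 1)
    y0 <- min(earY - earRy, if (phenotype$implant) cy - 1.18 * fy else Inf,
              cy - fy)
    y1 <- cy + fy
    box <- Box(x0, y0, x1, y1)

    comps <- as.character(c(phenotype$orbital, phenotype$nose,
                            phenotype$cheek, phenotype$ear,
                            phenotype$whisker))
    comps[!phenotype$rateable] <- "NR"
    names(comps) <- mgsComponents()

    list(image = img,
         truth = list(box = box, components = comps,
                      quality = qualityGroundTruth(render$blurSigma,
                                                   render$headYaw)))
  })
}

## Resolve a schedule argument: a single object, a list of length n, or a
## function of the 0-based frame index.
resolveSchedule <- function(schedule, i, what) {
  if (is.function(schedule)) return(schedule(i))
  if (inherits(schedule, what)) return(schedule)
  if (is.list(schedule)) return(schedule[[i + 1L]])
  stop("schedule must be a ", what, ", a list of them, or a function(frame)")
}

#' Simulate a front-camera session with quality ground truth
#'
#' Renders a frame sequence from per-frame phenotype and render schedules.
#' Timestamps are \code{frame_index / fps}; the per-frame quality ground
#' truth follows the blur/yaw schedule via [qualityGroundTruth()].
#'
#' @param phenotypeSchedule a [facePhenotype()], a list of them (one per
#'   frame), or a \code{function(frame0)} returning one.
#' @param renderSchedule a [renderConfig()], list, or function, analogous.
#' @param nFrames number of frames (>= 0).
#' @param fps frames per second (> 0).
#' @param seed integer master seed; per-frame render seeds are derived from
#'   it.
#' @return list with \code{frames} (list of matrices), \code{truth} (list of
#'   per-frame ground-truth lists) and \code{timestamps} (seconds).
#' @export
simulateFrontSession <- function(phenotypeSchedule, renderSchedule,
                                 nFrames, fps = 30, seed = 1) {
  if (!is.finite(nFrames) || nFrames < 0)
    stop("nFrames must be >= 0")
  if (!is.finite(fps) || fps <= 0) stop("fps must be > 0")
  nFrames <- as.integer(nFrames)
  if (nFrames == 0L)
    return(list(frames = list(), truth = list(), timestamps = numeric(0)))
  frameSeeds <- withSeed(seed, sample.int(.Machine$integer.max, nFrames))
  frames <- vector("list", nFrames)
  truth <- vector("list", nFrames)
  for (i in seq_len(nFrames)) {
    ph <- resolveSchedule(phenotypeSchedule, i - 1L, "facePhenotype")
    rc <- resolveSchedule(renderSchedule, i - 1L, "renderConfig")
    r <- renderFace(ph, rc, seed = frameSeeds[i])
    frames[[i]] <- r$image
    truth[[i]] <- r$truth
  }
  list(frames = frames, truth = truth,
       timestamps = (seq_len(nFrames) - 1) / fps)
}
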