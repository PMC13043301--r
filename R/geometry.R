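## Box geometry and the face-crop preprocessing pipelines.
##
## Images are plain numeric matrices (rows = y, columns = x) with intensities
## held as floats, nominally in [0, 1]. Boxes are continuous; cropping rounds
## to the pixel grid with floor(x0, y0) / ceil(x1, y1).

#' Expand a box outward about its center
#'
#' Each of the four boundaries moves outward by \code{fraction} of the
#' corresponding box dimension, so both dimensions scale by
#' \code{1 + 2 * fraction} and the center is preserved. This is the
#' "expanded by 5\%" step of the validation preprocessing under the
#' per-boundary reading; set \code{perDimension = TRUE} for the alternative
#' reading in which each *dimension* grows by \code{fraction} in total
#' (boundaries move by \code{fraction / 2}).
#'
#' @param box a [Box-class].
#' @param fraction non-negative expansion fraction (default 0.05).
#' @param perDimension if TRUE, interpret \code{fraction} per dimension
#'   rather than per boundary.
#' @return the expanded [Box-class].
#' @examples
#' expandBox(Box(0, 0, 100, 80), 0.05)  # -> (-5, -4, 105, 84)
#' @export
expandBox <- function(box, fraction = 0.05, perDimension = FALSE) {
  stopifnot(is(box, "Box"))
  if (!is.finite(fraction) || fraction < 0)
    stop("expansion fraction must be finite and >= 0")
  f <- if (perDimension) fraction / 2 else fraction
  w <- box@x1 - box@x0
  h <- box@y1 - box@y0
  Box(box@x0 - f * w, box@y0 - f * h, box@x1 + f * w, box@y1 + f * h)
}

#' Square a box by growing its smaller dimension about the center
#'
#' @param box a [Box-class].
#' @return a square [Box-class] with side \code{max(width, height)},
#'   containing the input and sharing its center.
#' @examples
#' squareBox(Box(0, 0, 100, 80))  # -> (0, -10, 100, 90)
#' @export
squareBox <- function(box) {
  stopifnot(is(box, "Box"))
  w <- box@x1 - box@x0
  h <- box@y1 - box@y0
  side <- max(w, h)
  cx <- (box@x0 + box@x1) / 2
  cy <- (box@y0 + box@y1) / 2
  Box(cx - side / 2, cy - side / 2, cx + side / 2, cy + side / 2)
}

## Round a continuous box to the integer pixel grid: floor for the top-left
## boundary, ceiling for the bottom-right (half-open convention).
roundBoxToGrid <- function(box) {
  c(x0 = floor(box@x0), y0 = floor(box@y0),
    x1 = ceiling(box@x1), y1 = ceiling(box@y1))
}

#' Crop a box out of an image with constant-fill padding
#'
#' The box is rounded to the pixel grid (floor for x0/y0, ceiling for x1/y1);
#' the returned patch has exactly the rounded dimensions. Pixels falling
#' outside the image are set to \code{fill} (zero padding by default), so
#' boxes may cross or lie entirely outside the image.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param box a [Box-class].
#' @param fill fill value for out-of-image pixels (default 0).
#' @return numeric matrix of the patch.
#' @export
cropWithPadding <- function(image, box, fill = 0) {
  stopifnot(is(box, "Box"))
  if (!is.matrix(image) || length(image) == 0L)
    stop("image must be a non-empty matrix")
  g <- roundBoxToGrid(box)
  w <- g["x1"] - g["x0"]
  h <- g["y1"] - g["y0"]
  patch <- matrix(fill, nrow = h, ncol = w)
  # 0-based pixel coordinates of the patch grid mapped into the image
  xs <- seq.int(g["x0"], g["x1"] - 1L)
  ys <- seq.int(g["y0"], g["y1"] - 1L)
  inX <- which(xs >= 0L & xs < ncol(image))
  inY <- which(ys >= 0L & ys < nrow(image))
  if (length(inX) && length(inY))
    patch[inY, inX] <- image[ys[inY] + 1L, xs[inX] + 1L]
  patch
}

#' Pooled intensity statistics over a training corpus
#'
#' Computes the pooled mean and population standard deviation of all pixel
#' values across a collection of (padded, squared, cropped) images. These
#' fixed statistics are used for input normalization at both training and
#' validation time.
#'
#' @param images list of numeric matrices.
#' @return list with elements \code{mean} and \code{std} (population
#'   convention, i.e. divisor n).
#' @examples
#' computeNormStats(list(matrix(0, 1, 1), matrix(1, 1, 1)))  # mean .5, std .5
#' @export
computeNormStats <- function(images) {
  if (!is.list(images) || length(images) == 0L)
    stop("need at least one image")
  v <- unlist(lapply(images, as.numeric), use.names = FALSE)
  if (!length(v)) stop("images are empty")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s <= 0)
    stop("zero variance: all pixels identical, cannot normalize")
  list(mean = m, std = s)
}

## Resize a matrix with EBImage; filter is "bilinear" or "none" (nearest).
resizeImage <- function(image, side, filter = c("bilinear", "none")) {
  filter <- match.arg(filter)
  out <- EBImage::resize(image, w = side, h = side, filter = filter)
  as.matrix(out)
}

#' Normalize a patch and resize it to the classifier input
#'
#' Applies fixed normalization \code{(pixel - mean) / std} (before any
#' resampling), resizes to \code{side x side} and broadcasts the grayscale
#' result into three identical channels, producing the
#' \code{side x side x 3} input expected by the MGS classifier.
#'
#' @param patch numeric matrix.
#' @param stats list with \code{mean} and \code{std} (see
#'   [computeNormStats()]); \code{std} must be > 0.
#' @param side output side length in pixels (default 224).
#' @param interpolation \code{"bilinear"} (default, the validation rule) or
#'   \code{"nearest"}.
#' @return numeric array \code{side x side x 3} with identical channels.
#' @export
normalizeAndResize <- function(patch, stats, side = 224,
                               interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!is.list(stats) || is.null(stats$std) || !is.finite(stats$std) ||
      stats$std <= 0)
    stop("invalid normalization stats: std must be a positive number")
  z <- (patch - stats$mean) / stats$std
  r <- resizeImage(z, side,
                   filter = if (interpolation == "bilinear") "bilinear" else "none")
  array(rep(r, 3L), dim = c(side, side, 3L))
}

#' Deterministic validation preprocessing of a face crop
#'
#' The fixed pipeline applied to every frame at scoring/validation time:
#' expand the detected box by 5\% about its center, square it by growing the
#' smaller dimension, crop with zero padding, normalize with the fixed corpus
#' statistics and resize bilinearly to \code{side x side x 3}.
#'
#' @inheritParams normalizeAndResize
#' @param image full grayscale frame (numeric matrix).
#' @param box detected face [Box-class].
#' @param expandFraction boundary expansion fraction (default 0.05).
#' @param perDimension see [expandBox()].
#' @return numeric array \code{side x side x 3}.
#' @export
validationPreprocess <- function(image, box, stats, side = 224,
                                 expandFraction = 0.05, perDimension = FALSE) {
  b <- squareBox(expandBox(box, expandFraction, perDimension = perDimension))
  patch <- cropWithPadding(image, b, fill = 0)
  normalizeAndResize(patch, stats, side = side, interpolation = "bilinear")
}

#' Training-time augmentation parameters
#'
#' Defaults are the published training pipeline: box jitter of up to
#' \eqn{\pm}10\% per boundary with probability 0.5 (otherwise the fixed 5\%
#' expansion), horizontal flip with probability 0.5, brightness
#' \eqn{\pm}15\% and contrast \eqn{\pm}5\%, rotation by a uniform angle in
#' \eqn{[-10^\circ, 10^\circ]} with probability 0.25 (bilinear resampling)
#' or 0.25 (nearest), and a final resize that is bilinear or nearest with
#' probability 0.5 each.
#'
#' @param flipP horizontal flip probability.
#' @param brightnessRange half-width of the multiplicative brightness range.
#' @param contrastRange half-width of the contrast range (about the patch
#'   mean).
#' @param jitterP probability of the per-boundary jitter branch.
#' @param jitterMax maximum per-boundary jitter fraction.
#' @param expandFraction expansion used when the jitter branch is not taken.
#' @param rotBilinearP,rotNearestP probabilities of the two rotation
#'   branches (their sum must be <= 1; the remainder applies no rotation).
#' @param rotMaxDeg maximum absolute rotation angle in degrees.
#' @param resizeNearestP probability that the final resize uses nearest-pixel
#'   interpolation instead of bilinear.
#' @return a validated list of class \code{"augmentationParams"}.
#' @export
augmentationParams <- function(flipP = 0.5, brightnessRange = 0.15,
                               contrastRange = 0.05, jitterP = 0.5,
                               jitterMax = 0.10, expandFraction = 0.05,
                               rotBilinearP = 0.25, rotNearestP = 0.25,
                               rotMaxDeg = 10, resizeNearestP = 0.5) {
  p <- list(flipP = flipP, brightnessRange = brightnessRange,
            contrastRange = contrastRange, jitterP = jitterP,
            jitterMax = jitterMax, expandFraction = expandFraction,
            rotBilinearP = rotBilinearP, rotNearestP = rotNearestP,
            rotMaxDeg = rotMaxDeg, resizeNearestP = resizeNearestP)
  probs <- c(flipP, jitterP, rotBilinearP, rotNearestP, resizeNearestP)
  if (any(!is.finite(unlist(p))))
    stop("augmentation parameters must be finite")
  if (any(probs < 0 | probs > 1))
    stop("augmentation probabilities must lie in [0, 1]")
  if (rotBilinearP + rotNearestP > 1)
    stop("rotation branch probabilities must sum to at most 1")
  if (brightnessRange < 0 || contrastRange < 0 || jitterMax < 0 ||
      expandFraction < 0 || rotMaxDeg < 0)
    stop("ranges must be non-negative")
  class(p) <- "augmentationParams"
  p
}

## Rotate about the patch center with zero-filled corners, keeping the
## patch dimensions.
rotatePatch <- function(patch, angle, filter = c("bilinear", "none")) {
  filter <- match.arg(filter)
  out <- EBImage::rotate(patch, angle, filter = filter,
                         output.dim = c(nrow(patch), ncol(patch)),
                         bg.col = 0)
  as.matrix(out)
}

#' Draw one stochastic training augmentation of a labeled face crop
#'
#' Applies, in order: per-boundary box jitter (probability
#' \code{jitterP}, up to \eqn{\pm}\code{jitterMax} per boundary) or the fixed
#' 5\% expansion; squaring; crop with zero padding; horizontal flip;
#' brightness and contrast adjustment (contrast about the patch mean, then
#' clipped back to \code{[0, 1]}); the three-way rotation branch; fixed
#' normalization; and the final resize (bilinear or nearest). The draw is a
#' pure function of R's RNG state, so \code{set.seed()} before the call makes
#' it reproducible.
#'
#' With all stochastic branches disabled
#' (\code{jitterP = 0, flipP = 0, brightnessRange = 0, contrastRange = 0,
#' rotBilinearP = 0, rotNearestP = 0, resizeNearestP = 0}) the output equals
#' [validationPreprocess()].
#'
#' @inheritParams validationPreprocess
#' @param params an [augmentationParams()] list.
#' @param details if TRUE, attach an \code{"augmentation"} attribute
#'   recording the sampled branch decisions.
#' @return numeric array \code{side x side x 3} (channels identical).
#' @export
sampleTrainingAugmentation <- function(image, box, stats,
                                       params = augmentationParams(),
                                       side = 224, details = FALSE) {
  if (!inherits(params, "augmentationParams"))
    params <- do.call(augmentationParams, params)
  w <- box@x1 - box@x0
  h <- box@y1 - box@y0
  jittered <- runif(1) < params$jitterP
  b <- if (jittered) {
    d <- runif(4, -params$jitterMax, params$jitterMax)
    Box(box@x0 - d[1] * w, box@y0 - d[3] * h,
        box@x1 + d[2] * w, box@y1 + d[4] * h)
  } else {
    expandBox(box, params$expandFraction)
  }
  patch <- cropWithPadding(image, squareBox(b), fill = 0)

  flipped <- runif(1) < params$flipP
  if (flipped) patch <- patch[, rev(seq_len(ncol(patch))), drop = FALSE]

  bright <- runif(1, 1 - params$brightnessRange, 1 + params$brightnessRange)
  contr <- runif(1, 1 - params$contrastRange, 1 + params$contrastRange)
  patch <- patch * bright
  m <- mean(patch)
  patch <- (patch - m) * contr + m
  patch <- pmin(pmax(patch, 0), 1)

  u <- runif(1)
  rotation <- "none"
  angle <- 0
  if (u < params$rotBilinearP) {
    rotation <- "bilinear"
  } else if (u < params$rotBilinearP + params$rotNearestP) {
    rotation <- "nearest"
  }
  if (rotation != "none") {
    angle <- runif(1, -params$rotMaxDeg, params$rotMaxDeg)
    patch <- rotatePatch(patch, angle,
                         filter = if (rotation == "bilinear") "bilinear" else "none")
  }

  nearestResize <- runif(1) < params$resizeNearestP
  out <- normalizeAndResize(patch, stats, side = side,
                            interpolation = if (nearestResize) "nearest" else "bilinear")
  if (details)
    attr(out, "augmentation") <- list(jittered = jittered, flipped = flipped,
                                      brightness = bright, contrast = contr,
                                      rotation = rotation, angle = angle,
                                      resize = if (nearestResize) "nearest" else "bilinear")
  out
}

#' Read or write normalization statistics as a JSON sidecar
#'
#' @param stats list with \code{mean} and \code{std}.
#' @param path file path.
#' @return \code{readNormStats} returns the stats list; \code{writeNormStats}
#'   returns \code{path} invisibly.
#' @export
writeNormStats <- function(stats, path) {
  jsonlite::write_json(list(mean = stats$mean, std = stats$std), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNormStats
#' @export
readNormStats <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(s$std) || s$std <= 0) stop("invalid stats sidecar: ", path)
  list(mean = as.numeric(s$mean), std = as.numeric(s$std))
}
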