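## Arena-calibrated locomotion and the behavior-flow group comparison.

#' Distance moved in centimeters
#'
#' Sums the per-frame Euclidean displacement of a tracked part, converting
#' pixels to centimeters with an affine scale estimated from the four arena
#' corner keypoints and the physical arena floor (11 x 7 cm internally).
#' Frames where the part's confidence falls below the threshold are bridged
#' by linear interpolation of its coordinates.
#'
#' @param track a [KeypointTrack-class] containing the part and the four
#'   arena corners.
#' @param part tracked part (default \code{"body_center"}).
#' @param widthCm,depthCm physical arena floor dimensions.
#' @param confidenceThreshold frames below this confidence are interpolated.
#' @return numeric(1) distance in cm.
#' @export
distanceMoved <- function(track, part = "body_center", widthCm = 11,
                          depthCm = 7, confidenceThreshold = 0.5) {
  stopifnot(is(track, "KeypointTrack"))
  if (!part %in% trackParts(track))
    stop("track is missing part '", part, "'")
  b <- arenaBoundsFromTrack(track)
  co <- b$corners  # tl, tr, br, bl
  wPx <- (sqrt(sum((co[2, ] - co[1, ])^2)) +
            sqrt(sum((co[3, ] - co[4, ])^2))) / 2
  hPx <- (sqrt(sum((co[4, ] - co[1, ])^2)) +
            sqrt(sum((co[3, ] - co[2, ])^2))) / 2
  if (!is.finite(wPx) || !is.finite(hPx) || wPx < 1e-6 || hPx < 1e-6)
    stop("degenerate arena corners: cannot calibrate")
  sx <- widthCm / wPx
  sy <- depthCm / hPx
  p <- partCoords(track, part)
  n <- nrow(p)
  if (n < 2L) return(0)
  low <- p$confidence < confidenceThreshold
  if (any(low) && !all(low)) {
    idx <- seq_len(n)
    p$x[low] <- approx(idx[!low], p$x[!low], xout = idx[low], rule = 2)$y
    p$y[low] <- approx(idx[!low], p$y[!low], xout = idx[low], rule = 2)$y
  }
  sum(sqrt((diff(p$x) * sx)^2 + (diff(p$y) * sy)^2))
}

asProportionRow <- function(tm, offDiag) {
  m <- if (is(tm, "TransitionMatrix")) transitionCounts(tm) else as.matrix(tm)
  tot <- sum(m)
  p <- if (tot > 0) m / tot else m * 0
  as.numeric(p)[offDiag]
}

#' Compare behavior-flow transition structure between two groups
#'
#' Each animal's transition counts are normalized to proportions (divide by
#' the animal's total transitions). The observed statistic is the L1
#' distance between the group mean proportion matrices over all ordered
#' cluster pairs \eqn{i \ne j}; its null distribution is obtained by
#' shuffling animal group labels. Per-transition one-tailed two-sample
#' z-tests on the proportions are reported alongside, as used for the
#' per-transition annotations.
#'
#' @param groupA,groupB lists of [TransitionMatrix-class] (or raw count
#'   matrices) sharing k and the self-transition convention; at least 2
#'   animals per group.
#' @param nPermutations number of label permutations (default 999).
#' @param seed permutation seed.
#' @param alternative direction of the per-transition z-tests:
#'   \code{"greater"} tests group A > group B.
#' @return a [FlowComparison-class].
#' @export
flowCompare <- function(groupA, groupB, nPermutations = 999, seed = 1,
                        alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2L || nB < 2L)
    stop("need at least 2 animals per group")
  first <- groupA[[1]]
  k <- if (is(first, "TransitionMatrix")) nrow(transitionCounts(first))
       else nrow(as.matrix(first))
  ks <- vapply(c(groupA, groupB), function(tm)
    if (is(tm, "TransitionMatrix")) nrow(transitionCounts(tm))
    else nrow(as.matrix(tm)), integer(1))
  if (any(ks != k)) stop("all transition matrices must share k")
  convs <- vapply(c(groupA, groupB), function(tm)
    if (is(tm, "TransitionMatrix")) tm@includeSelf else NA, logical(1))
  if (length(unique(convs[!is.na(convs)])) > 1L)
    stop("transition matrices mix self-transition conventions")
  offDiag <- as.numeric(diag(k)) == 0

  P <- rbind(t(vapply(groupA, asProportionRow, numeric(sum(offDiag)),
                      offDiag = offDiag)),
             t(vapply(groupB, asProportionRow, numeric(sum(offDiag)),
                      offDiag = offDiag)))
  isA <- c(rep(TRUE, nA), rep(FALSE, nB))
  statOf <- function(a) sum(abs(colMeans(P[a, , drop = FALSE]) -
                                  colMeans(P[!a, , drop = FALSE])))
  observed <- statOf(isA)
  permGE <- withSeed(seed, {
    sum(vapply(seq_len(nPermutations), function(i)
      statOf(sample(isA)) >= observed, logical(1)))
  })
  p <- (1 + permGE) / (1 + nPermutations)

  mA <- colMeans(P[isA, , drop = FALSE])
  mB <- colMeans(P[!isA, , drop = FALSE])
  vA <- apply(P[isA, , drop = FALSE], 2L, var)
  vB <- apply(P[!isA, , drop = FALSE], 2L, var)
  se <- sqrt(vA / nA + vB / nB)
  z <- ifelse(se > 0, (mA - mB) / se,
              ifelse(mA == mB, 0, sign(mA - mB) * Inf))
  pz <- if (alternative == "greater") pnorm(z, lower.tail = FALSE)
        else pnorm(z)
  ij <- which(matrix(offDiag, k, k), arr.ind = TRUE)
  zTable <- data.frame(from = ij[, 1] - 1L, to = ij[, 2] - 1L,
                       mean_A = mA, mean_B = mB, z = z,
                       p_one_tailed = pz, row.names = NULL)
  new("FlowComparison", statistic = observed, pValue = p, zTable = zTable,
      nPermutations = as.integer(nPermutations), seed = as.integer(seed))
}
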