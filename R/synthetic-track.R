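## Regime-switching keypoint trajectory generator.
##
## Behavior is modeled as a first-order Markov chain over named kinematic
## regimes; each regime sets the speed, turning-rate and posture-scale
## distributions of a simple body model (six mouse parts rigidly arranged
## along the heading, plus four stationary arena corners).

#' Regime-switching kinematic model
#'
#' @param stateNames character vector of regime names.
#' @param speedMean,speedSd per-state speed (px/frame; means >= 0).
#' @param turnMean,turnSd per-state turning rate (rad/frame).
#' @param postureScale per-state body elongation factor (1 = normal; < 1
#'   foreshortened, e.g. rearing).
#' @param transition S x S row-stochastic transition matrix (rows sum to 1
#'   within 1e-9).
#' @param noiseSd per-part coordinate jitter (px).
#' @return a validated list of class \code{"regimeModel"}.
#' @export
regimeModel <- function(stateNames, speedMean, speedSd, turnMean, turnSd,
                        postureScale, transition, noiseSd = 0.5) {
  S <- length(stateNames)
  lens <- lengths(list(speedMean, speedSd, turnMean, turnSd, postureScale))
  if (any(lens != S))
    stop("per-state kinematic vectors must have one entry per state")
  if (any(speedMean < 0)) stop("speed means must be >= 0")
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(S, S)))
    stop("transition matrix must be S x S")
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9))
    stop("each transition row must be non-negative and sum to 1 (within 1e-9)")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  structure(list(stateNames = stateNames, speedMean = speedMean,
                 speedSd = speedSd, turnMean = turnMean, turnSd = turnSd,
                 postureScale = postureScale, transition = transition,
                 noiseSd = noiseSd),
            class = "regimeModel")
}

#' Default four-regime model
#'
#' Immobility, locomotion bursts, rotation and a rearing proxy
#' (foreshortened posture), with sticky transitions. Speeds are in px/frame
#' at the default 40 px/cm arena calibration and 30 fps (locomotion ~= 4.5
#' cm/s).
#'
#' @return a [regimeModel()].
#' @export
defaultRegimeModel <- function() {
  regimeModel(
    stateNames = c("immobility", "locomotion", "rotation", "rearing"),
    speedMean = c(0.0, 6.0, 1.5, 0.3),
    speedSd = c(0.0, 1.5, 0.5, 0.2),
    turnMean = c(0.0, 0.0, 0.35, 0.0),
    turnSd = c(0.05, 0.30, 0.10, 0.05),
    postureScale = c(1.0, 1.0, 1.0, 0.55),
    transition = rbind(c(0.95, 0.03, 0.01, 0.01),
                       c(0.05, 0.90, 0.03, 0.02),
                       c(0.05, 0.05, 0.88, 0.02),
                       c(0.06, 0.02, 0.02, 0.90)),
    noiseSd = 0.5)
}

#' Well-separated four-regime model for pipeline-recovery checks
#'
#' A deliberately separable configuration of the same four regimes as
#' [defaultRegimeModel()]: long dwell times (~100 frames, well beyond the
#' 31-frame expansion window), widely spaced speeds, a loud rotation regime
#' and a moderate rearing posture change, with low keypoint noise. This is
#' the construction used to validate that the clustering stage can recover
#' regime states when they are kinematically distinct; the default model is
#' the more realistic cohort generator.
#'
#' @return a [regimeModel()].
#' @export
separableRegimeModel <- function() {
  regimeModel(
    stateNames = c("immobility", "locomotion", "rotation", "rearing"),
    speedMean = c(0.0, 10.0, 4.0, 0.3),
    speedSd = c(0.0, 1.0, 0.4, 0.1),
    turnMean = c(0.0, 0.0, 0.9, 0.0),
    turnSd = c(0.02, 0.15, 0.08, 0.02),
    postureScale = c(1.0, 1.0, 1.0, 0.7),
    transition = rbind(c(0.990, 0.004, 0.003, 0.003),
                       c(0.005, 0.990, 0.003, 0.002),
                       c(0.005, 0.003, 0.990, 0.002),
                       c(0.005, 0.003, 0.002, 0.990)),
    noiseSd = 0.2)
}

#' Apply a locomotion multiplier to a regime model
#'
#' Models drug-induced hyperactivity: the locomotion state's speed mean and
#' sd are multiplied by \code{m}, and the odds of transitioning *into* the
#' locomotion state are multiplied by \code{m} (rows renormalized), so a
#' hyperactive animal both moves faster and spends more time moving.
#' \code{m = 1} returns the model unchanged.
#'
#' @param model a [regimeModel()].
#' @param m positive multiplier.
#' @param state name of the locomotion state (default "locomotion").
#' @return the modified [regimeModel()].
#' @export
applyLocomotionMultiplier <- function(model, m, state = "locomotion") {
  stopifnot(inherits(model, "regimeModel"))
  if (!is.finite(m) || m <= 0) stop("locomotion multiplier must be > 0")
  j <- match(state, model$stateNames)
  if (is.na(j)) stop("model has no state named '", state, "'")
  model$speedMean[j] <- model$speedMean[j] * m
  model$speedSd[j] <- model$speedSd[j] * m
  tr <- model$transition
  tr[, j] <- tr[, j] * m
  tr <- tr / rowSums(tr)
  model$transition <- tr
  model
}

#' Sample a state sequence from a regime model's Markov chain
#'
#' @param model a [regimeModel()].
#' @param nFrames sequence length (>= 1).
#' @param seed integer seed.
#' @param startState initial state index (1-based).
#' @return integer vector of state indices (1-based) of length
#'   \code{nFrames}.
#' @export
simulateStateSequence <- function(model, nFrames, seed = 1, startState = 1L) {
  stopifnot(inherits(model, "regimeModel"))
  nFrames <- as.integer(nFrames)
  if (nFrames < 1L) stop("nFrames must be >= 1")
  S <- length(model$stateNames)
  if (startState < 1L || startState > S) stop("invalid startState")
  cum <- t(apply(model$transition, 1L, cumsum))
  withSeed(seed, {
    u <- runif(nFrames - 1L)
    states <- integer(nFrames)
    states[1L] <- startState
    if (nFrames > 1L)
      for (t in 2:nFrames)
        states[t] <- sum(u[t - 1L] > cum[states[t - 1L], ]) + 1L
    states
  })
}

#' Arena geometry for the top camera
#'
#' The physical arena floor is 11 x 7 cm; the default calibration places it
#' at 40 px/cm in the top-camera image. Corner 1..4 are top-left, top-right,
#' bottom-right, bottom-left.
#'
#' @param widthCm,depthCm internal floor dimensions in cm.
#' @param pxPerCm nominal image scale.
#' @param originPx pixel position of the top-left corner.
#' @return list of class \code{"arenaGeometry"} with the corner coordinates
#'   and bounds.
#' @export
arenaGeometry <- function(widthCm = 11, depthCm = 7, pxPerCm = 40,
                          originPx = c(20, 20)) {
  if (widthCm <= 0 || depthCm <= 0 || pxPerCm <= 0)
    stop("arena dimensions must be positive")
  x0 <- originPx[1]; y0 <- originPx[2]
  x1 <- x0 + widthCm * pxPerCm
  y1 <- y0 + depthCm * pxPerCm
  structure(list(widthCm = widthCm, depthCm = depthCm, pxPerCm = pxPerCm,
                 x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                 corners = rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))),
            class = "arenaGeometry")
}

#' Part schema of synthetic keypoint tracks
#'
#' @return character vector: six mouse parts followed by four arena corners.
#' @export
trackPartSchema <- function() {
  c("nose", "left_ear", "right_ear", "body_center", "tail_base", "spine_mid",
    paste0("arena_corner_", 1:4))
}

#' Simulate a regime-switching keypoint session
#'
#' Draws a state sequence from the model's Markov chain, integrates a
#' heading/speed body trajectory (reflected at the arena walls), and places
#' the six mouse parts rigidly along the heading, scaled by the state's
#' posture factor. Arena corners are fixed at the arena rectangle with
#' sub-pixel jitter. All coordinates are clamped inside the arena.
#'
#' @param model a [regimeModel()].
#' @param arena an [arenaGeometry()].
#' @param nFrames number of frames (>= 2).
#' @param seed integer seed.
#' @param fps frames per second.
#' @param startState initial state (1-based index).
#' @return list with \code{track} (a [KeypointTrack-class]) and
#'   \code{states} (integer ground-truth state sequence).
#' @export
simulateKeypointSession <- function(model, arena = arenaGeometry(),
                                    nFrames = 3000, seed = 1, fps = 30,
                                    startState = 1L) {
  stopifnot(inherits(model, "regimeModel"), inherits(arena, "arenaGeometry"))
  nFrames <- as.integer(nFrames)
  if (nFrames < 2L) stop("nFrames must be >= 2")
  states <- simulateStateSequence(model, nFrames, seed = seed,
                                  startState = startState)
  margin <- 14
  parts <- trackPartSchema()
  withSeed(seed + 1L, {
    speeds <- pmax(0, rnorm(nFrames, model$speedMean[states],
                            model$speedSd[states]))
    dTheta <- rnorm(nFrames, model$turnMean[states], model$turnSd[states])
    theta <- cumsum(dTheta) + runif(1, 0, 2 * pi)
    px <- numeric(nFrames); py <- numeric(nFrames)
    px[1] <- runif(1, arena$x0 + margin, arena$x1 - margin)
    py[1] <- runif(1, arena$y0 + margin, arena$y1 - margin)
    for (t in 2:nFrames) {
      nx <- px[t - 1] + speeds[t] * cos(theta[t])
      ny <- py[t - 1] + speeds[t] * sin(theta[t])
      # reflect at the walls
      if (nx < arena$x0 + margin) nx <- 2 * (arena$x0 + margin) - nx
      if (nx > arena$x1 - margin) nx <- 2 * (arena$x1 - margin) - nx
      if (ny < arena$y0 + margin) ny <- 2 * (arena$y0 + margin) - ny
      if (ny > arena$y1 - margin) ny <- 2 * (arena$y1 - margin) - ny
      px[t] <- min(max(nx, arena$x0 + margin), arena$x1 - margin)
      py[t] <- min(max(ny, arena$y0 + margin), arena$y1 - margin)
    }
    ps <- model$postureScale[states]
    ux <- cos(theta); uy <- sin(theta)
    vx <- -uy; vy <- ux
    offsets <- list(nose = c(12, 0), left_ear = c(7, 5), right_ear = c(7, -5),
                    body_center = c(0, 0), tail_base = c(-12, 0),
                    spine_mid = c(-5, 0))
    n <- nFrames
    X <- matrix(0, n, length(parts))
    Y <- matrix(0, n, length(parts))
    for (j in seq_along(offsets)) {
      o <- offsets[[j]]
      X[, j] <- px + ps * (o[1] * ux + o[2] * vx)
      Y[, j] <- py + ps * (o[1] * uy + o[2] * vy)
    }
    if (model$noiseSd > 0) {
      X[, 1:6] <- X[, 1:6] + rnorm(6 * n, 0, model$noiseSd)
      Y[, 1:6] <- Y[, 1:6] + rnorm(6 * n, 0, model$noiseSd)
    }
    for (k in 1:4) {
      X[, 6 + k] <- arena$corners[k, 1] + rnorm(n, 0, 0.3)
      Y[, 6 + k] <- arena$corners[k, 2] + rnorm(n, 0, 0.3)
    }
    X <- pmin(pmax(X, arena$x0), arena$x1)
    Y <- pmin(pmax(Y, arena$y0), arena$y1)
    conf <- matrix(runif(n * length(parts), 0.92, 1), n, length(parts))
    track <- KeypointTrack(x = X, y = Y, confidence = conf, parts = parts,
                           fps = fps)
    list(track = track, states = states)
  })
}
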