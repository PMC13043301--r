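## Multi-group cohort generator: one front-camera session plus one
## top-camera keypoint session per animal x timepoint, with ground truth.

#' Cohort design for the synthetic study
#'
#' Mirrors the craniotomy analgesia-comparison design: two analgesia groups
#' ("M" = NSAID only, "B+M" = opioid + NSAID) recorded at five timepoints
#' around surgery. Effects are expressed as a per-group/timepoint additive
#' MGS elevation (expected component score added on top of the baseline) and
#' a per-group/timepoint locomotion multiplier (see
#' [applyLocomotionMultiplier()]); the default design gives both groups the
#' post-surgical MGS peak at 4 h that decays by 72 h, and gives the "B+M"
#' group a 3x locomotion multiplier at 4 h (opioid hyperactivity).
#'
#' @param nPerGroup animals per group (>= 1).
#' @param groups group labels.
#' @param timepoints ordered timepoint labels.
#' @param mgsElevation numeric matrix (groups x timepoints) of additive MGS
#'   elevations (>= 0); defaults to the post-surgical decay profile for all
#'   groups.
#' @param locomotionMultiplier numeric matrix (groups x timepoints) of
#'   positive multipliers; defaults to 1 everywhere except "B+M" at "4h".
#' @param sessionLengthFrames top-camera frames per session (default 18000,
#'   i.e. a 10-min recording at 30 fps).
#' @param frontFrames front-camera frames rendered per session (default
#'   300; rendering full-length front video is pointlessly expensive for a
#'   synthetic cohort).
#' @param fps frames per second (> 0).
#' @param renderSize canvas side for rendered faces (>= 64).
#' @param seed master seed; everything else is derived from it.
#' @return a validated list of class \code{"cohortDesign"}.
#' @export
cohortDesign <- function(nPerGroup = 8, groups = c("M", "B+M"),
                         timepoints = c("0h", "4h", "24h", "48h", "72h"),
                         mgsElevation = NULL, locomotionMultiplier = NULL,
                         sessionLengthFrames = 18000, frontFrames = 300,
                         fps = 30, renderSize = 128, seed = 1) {
  if (nPerGroup < 1) stop("nPerGroup must be >= 1")
  if (fps <= 0) stop("fps must be > 0")
  G <- length(groups); TP <- length(timepoints)
  if (is.null(mgsElevation)) {
    prof <- c(0, 0.8, 0.4, 0.15, 0)[seq_len(TP)]
    prof[is.na(prof)] <- 0
    mgsElevation <- matrix(rep(prof, each = G), G, TP,
                           dimnames = list(groups, timepoints))
  }
  if (is.null(locomotionMultiplier)) {
    locomotionMultiplier <- matrix(1, G, TP,
                                   dimnames = list(groups, timepoints))
    if ("B+M" %in% groups && "4h" %in% timepoints)
      locomotionMultiplier["B+M", "4h"] <- 3
  }
  mgsElevation <- as.matrix(mgsElevation)
  locomotionMultiplier <- as.matrix(locomotionMultiplier)
  for (m in list(mgsElevation, locomotionMultiplier)) {
    if (!all(dim(m) == c(G, TP)))
      stop("effect tables must be groups x timepoints matrices")
    if (!is.null(rownames(m)) && !all(rownames(m) %in% groups))
      stop("unknown group label in effect table: ",
           paste(setdiff(rownames(m), groups), collapse = ", "))
  }
  if (any(locomotionMultiplier <= 0))
    stop("locomotion multipliers must be > 0")
  if (any(mgsElevation < 0)) stop("MGS elevations must be >= 0")
  dimnames(mgsElevation) <- dimnames(locomotionMultiplier) <-
    list(groups, timepoints)
  structure(list(nPerGroup = as.integer(nPerGroup), groups = groups,
                 timepoints = timepoints, mgsElevation = mgsElevation,
                 locomotionMultiplier = locomotionMultiplier,
                 sessionLengthFrames = as.integer(sessionLengthFrames),
                 frontFrames = as.integer(frontFrames), fps = fps,
                 renderSize = renderSize, seed = as.integer(seed)),
            class = "cohortDesign")
}

## Draw a phenotype whose expected component score is `elev` above a small
## baseline; scores are integers clamped to {0, 1, 2}.
samplePhenotype <- function(elev, implant = FALSE) {
  mu <- 0.15 + elev
  sc <- pmin(2L, pmax(0L, as.integer(round(rnorm(5, mu, 0.35)))))
  facePhenotype(orbital = sc[1], nose = sc[2], cheek = sc[3], ear = sc[4],
                whisker = sc[5], implant = implant)
}

#' Simulate a full multi-group cohort
#'
#' Generates, for every animal x timepoint, a top-camera keypoint session
#' (with the true regime-state sequence) and a front-camera session (with
#' per-frame quality and component ground truth), applying the design's
#' group/timepoint effects. Reproducible from the design's master seed.
#'
#' @param design a [cohortDesign()].
#' @param model base [regimeModel()] before group effects.
#' @param arena an [arenaGeometry()].
#' @param renderFront if FALSE, skip rendering front-camera images (the true
#'   phenotype is still recorded); useful when only the pose stage is
#'   exercised.
#' @return list of class \code{"cohort"} with \code{design},
#'   \code{manifest} (data.frame: animal_id, group, timepoint, seed) and
#'   \code{sessions} (list; each has \code{animal_id}, \code{group},
#'   \code{timepoint}, \code{track}, \code{states}, \code{phenotype},
#'   \code{front}).
#' @export
simulateCohort <- function(design = cohortDesign(),
                           model = defaultRegimeModel(),
                           arena = arenaGeometry(), renderFront = TRUE) {
  stopifnot(inherits(design, "cohortDesign"))
  animals <- data.frame(group = rep(design$groups, each = design$nPerGroup),
                        stringsAsFactors = FALSE)
  animals$animal_id <- sprintf("a%02d_%s", seq_len(nrow(animals)),
                               gsub("[^A-Za-z0-9]", "", animals$group))
  grid <- expand.grid(idx = seq_len(nrow(animals)),
                      timepoint = design$timepoints,
                      stringsAsFactors = FALSE)
  nSess <- nrow(grid)
  seeds <- withSeed(design$seed, sample.int(.Machine$integer.max, nSess))
  sessions <- vector("list", nSess)
  for (s in seq_len(nSess)) {
    a <- animals[grid$idx[s], ]
    tp <- grid$timepoint[s]
    elev <- design$mgsElevation[a$group, tp]
    mult <- design$locomotionMultiplier[a$group, tp]
    m <- if (mult != 1) applyLocomotionMultiplier(model, mult) else model
    kp <- simulateKeypointSession(m, arena, design$sessionLengthFrames,
                                  seed = seeds[s], fps = design$fps)
    phenotype <- withSeed(seeds[s] %% 1000003L + s,
                          samplePhenotype(elev, implant = (tp != design$timepoints[1])))
    front <- NULL
    if (renderFront && design$frontFrames > 0) {
      rc <- renderConfig(width = design$renderSize,
                         height = design$renderSize)
      blurSchedule <- function(i) {
        # most frames usable, periodic blurred stretches
        if (i %% 10 < 3) renderConfig(width = design$renderSize,
                                      height = design$renderSize,
                                      blurSigma = 3) else rc
      }
      front <- simulateFrontSession(phenotype, blurSchedule,
                                    nFrames = design$frontFrames,
                                    fps = design$fps, seed = seeds[s])
    }
    sessions[[s]] <- list(animal_id = a$animal_id, group = a$group,
                          timepoint = tp, track = kp$track,
                          states = kp$states, phenotype = phenotype,
                          front = front, seed = seeds[s])
  }
  manifest <- data.frame(
    animal_id = vapply(sessions, `[[`, "", "animal_id"),
    group = vapply(sessions, `[[`, "", "group"),
    timepoint = vapply(sessions, `[[`, "", "timepoint"),
    seed = vapply(sessions, `[[`, 0L, "seed"),
    stringsAsFactors = FALSE)
  structure(list(design = design, manifest = manifest, sessions = sessions),
            class = "cohort")
}

#' Write a simulated cohort to a directory tree
#'
#' Emits one directory per session containing the pose CSV (three-row-header
#' keypoint dialect), a ground-truth JSON sidecar (true states, phenotype,
#' per-frame quality) and, when front frames were rendered, a PNG frame
#' directory; plus a top-level \code{manifest.csv} with paths and seeds.
#'
#' @param cohort a cohort from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return the manifest data.frame (invisibly), with path columns added.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  manifest$pose_path <- NA_character_
  manifest$truth_path <- NA_character_
  manifest$frames_dir <- NA_character_
  for (s in seq_along(cohort$sessions)) {
    ses <- cohort$sessions[[s]]
    sdir <- file.path(dir, sprintf("%s_%s", ses$animal_id, ses$timepoint))
    dir.create(sdir, showWarnings = FALSE)
    posePath <- file.path(sdir, "pose.csv")
    writePoseTrack(ses$track, posePath)
    truth <- list(animal_id = ses$animal_id, group = ses$group,
                  timepoint = ses$timepoint, states = ses$states,
                  phenotype = unclass(ses$phenotype))
    if (!is.null(ses$front)) {
      truth$front_quality <- vapply(ses$front$truth, `[[`, 0, "quality")
      b <- ses$front$truth[[1]]$box
      truth$front_box <- list(x0 = b@x0, y0 = b@y0, x1 = b@x1, y1 = b@y1)
      truth$front_components <- as.list(ses$front$truth[[1]]$components)
    }
    truthPath <- file.path(sdir, "truth.json")
    jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA)
    framesDir <- NA_character_
    if (!is.null(ses$front)) {
      framesDir <- file.path(sdir, "frames")
      dir.create(framesDir, showWarnings = FALSE)
      for (i in seq_along(ses$front$frames))
        EBImage::writeImage(t(ses$front$frames[[i]]),
                            file.path(framesDir,
                                      sprintf("frame_%05d.png", i - 1L)))
    }
    manifest$pose_path[s] <- posePath
    manifest$truth_path[s] <- truthPath
    manifest$frames_dir[s] <- framesDir
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
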