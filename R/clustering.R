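## Behavioral clustering: k-means with k-means++ seeding over the expanded
## feature space, transfer assignment, label smoothing, transition matrices
## and occupancy. Cluster labels are 0-based (0 .. k-1) throughout.

## k-means++ seeding: first center uniform, subsequent centers with
## probability proportional to squared distance to the nearest chosen
## center (draws from the current RNG stream).
kmeansPlusPlusInit <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[centers[1L], ], "-")^2)
  for (j in 2:k) {
    if (all(d2 <= 0)) {
      cand <- setdiff(seq_len(n), centers[seq_len(j - 1L)])
      centers[j] <- cand[sample.int(length(cand), 1L)]
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[centers[j], ], "-")^2))
  }
  x[centers, , drop = FALSE]
}

#' Fit the behavioral cluster model
#'
#' k-means (Lloyd iterations, k-means++ seeding, fixed seed) over pooled
#' expanded feature rows from a sample of recordings. The published pipeline
#' fits on 18--20 recordings sampled per experiment and segments behavior
#' into ten clusters; \code{k = 10} is the default here.
#'
#' @param expanded expanded feature matrix ([normalizeAndExpand()]), or a
#'   list of such matrices that are pooled row-wise.
#' @param k number of clusters (default 10).
#' @param seed fit seed.
#' @param stats normalization statistics to store with the model (from
#'   [normalizeAndExpand()]); required for assigning new recordings.
#' @param featureNames raw feature names (stored).
#' @param halfwidth temporal half-width used for the expansion (stored).
#' @param sampleIds ids of the recordings used for fitting (stored).
#' @param iterMax Lloyd iteration cap.
#' @return a [ClusterModel-class]. The fitted 0-based labels of the pooled
#'   rows are attached as attribute \code{"labels"}.
#' @export
fitClusters <- function(expanded, k = 10, seed = 1, stats = list(),
                        featureNames = character(), halfwidth = 15,
                        sampleIds = character(), iterMax = 100) {
  if (is.list(expanded) && !is.matrix(expanded))
    expanded <- do.call(rbind, expanded)
  if (nrow(expanded) < k)
    stop("cannot fit ", k, " clusters on ", nrow(expanded), " rows")
  fit <- withSeed(seed, {
    init <- kmeansPlusPlusInit(expanded, k)
    kmeans(expanded, centers = init, iter.max = iterMax, algorithm = "Lloyd")
  })
  model <- new("ClusterModel", centers = fit$centers, k = as.integer(k),
               normStats = stats, halfwidth = as.integer(halfwidth),
               featureNames = featureNames, seed = as.integer(seed),
               sampleIds = as.character(sampleIds))
  attr(model, "labels") <- fit$cluster - 1L
  model
}

#' Assign cluster labels to expanded feature rows
#'
#' Default transfer rule is nearest-centroid (the exact k-means prediction,
#' consistent with the fit by construction). A trained transfer classifier
#' ([trainTransferClassifier()]) can be supplied instead, mirroring the
#' published pipeline's neural transfer of the clustering to recordings
#' outside the fitting sample.
#'
#' @param model a [ClusterModel-class].
#' @param expanded expanded feature matrix with the model's dimension.
#' @param classifier optional transfer classifier.
#' @return integer vector of 0-based labels in \code{0 .. k-1}.
#' @export
assignLabels <- function(model, expanded, classifier = NULL) {
  stopifnot(is(model, "ClusterModel"))
  expanded <- as.matrix(expanded)
  if (ncol(expanded) != ncol(model@centers))
    stop("expanded dimension ", ncol(expanded),
         " does not match the model's ", ncol(model@centers))
  if (!is.null(classifier)) {
    pred <- predict(classifier, expanded, type = "class")
    return(as.integer(pred))
  }
  C <- model@centers
  d2 <- outer(rowSums(expanded^2), rep(1, nrow(C))) -
    2 * expanded %*% t(C) +
    outer(rep(1, nrow(expanded)), rowSums(C^2))
  max.col(-d2, ties.method = "first") - 1L
}

#' Train a neural transfer classifier on clustering results
#'
#' Small single-hidden-layer softmax network (via \pkg{nnet}) mapping
#' expanded feature rows to the fitted cluster labels, used to transfer the
#' clustering to recordings outside the fitting sample.
#'
#' @param expanded expanded feature matrix of the fitting sample.
#' @param labels 0-based fitted labels.
#' @param size hidden layer width.
#' @param seed training seed.
#' @param maxit optimizer iterations.
#' @return an \pkg{nnet} classifier whose \code{predict(..., type =
#'   "class")} returns 0-based labels.
#' @export
trainTransferClassifier <- function(expanded, labels, size = 8, seed = 1,
                                    maxit = 200) {
  if (!requireNamespace("nnet", quietly = TRUE))
    stop("the transfer classifier needs the 'nnet' package")
  y <- factor(labels, levels = sort(unique(labels)))
  withSeed(seed,
           nnet::nnet(x = expanded, y = nnet::class.ind(y), size = size,
                      softmax = TRUE, maxit = maxit, trace = FALSE,
                      MaxNWts = 1e6))
}

#' Smooth a label sequence with a sliding mode filter
#'
#' Center-aligned window of odd length; each frame takes the modal label of
#' its window, with ties retaining the original center label when it attains
#' the maximal count (otherwise the smallest tied label). Edges use
#' truncated windows; window 1 is the identity.
#'
#' @param labels integer label sequence.
#' @param window odd window length (default 5).
#' @return smoothed integer label sequence of the same length.
#' @export
smoothLabels <- function(labels, window = 5) {
  if (window < 1 || window %% 2 == 0)
    stop("window must be odd and >= 1")
  n <- length(labels)
  if (n == 0L || window == 1L) return(labels)
  h <- (window - 1L) %/% 2L
  lv <- sort(unique(labels))
  code <- match(labels, lv)
  out <- integer(n)
  for (t in seq_len(n)) {
    w <- code[max(1L, t - h):min(n, t + h)]
    cnt <- tabulate(w, length(lv))
    mx <- max(cnt)
    if (cnt[code[t]] == mx) out[t] <- code[t]
    else out[t] <- which(cnt == mx)[1L]
  }
  lv[out]
}

#' Count cluster-to-cluster transitions
#'
#' Counts consecutive-frame label pairs \code{t -> t+1}. Under the default
#' convention only pairs with differing labels are counted ("transitions
#' between clusters"), leaving a zero diagonal; \code{includeSelf = TRUE}
#' counts every pair.
#'
#' @param labels integer 0-based label sequence with values in
#'   \code{0 .. k-1}.
#' @param k number of clusters.
#' @param includeSelf count self-transitions too.
#' @return a [TransitionMatrix-class] with k x k counts.
#' @export
transitionMatrix <- function(labels, k, includeSelf = FALSE) {
  labels <- as.integer(labels)
  if (length(labels) && (min(labels) < 0L || max(labels) >= k))
    stop("labels must lie in 0 .. k-1")
  counts <- matrix(0L, k, k,
                   dimnames = list(from = 0:(k - 1), to = 0:(k - 1)))
  if (length(labels) >= 2L) {
    from <- labels[-length(labels)]
    to <- labels[-1L]
    if (!includeSelf) {
      keep <- from != to
      from <- from[keep]; to <- to[keep]
    }
    if (length(from)) {
      tab <- table(factor(from, levels = 0:(k - 1)),
                   factor(to, levels = 0:(k - 1)))
      counts[] <- counts + as.integer(tab)
    }
  }
  new("TransitionMatrix", counts = counts, includeSelf = includeSelf)
}

#' Fraction of time spent in each cluster
#'
#' @param labels non-empty integer 0-based label sequence.
#' @param k number of clusters.
#' @return numeric(k) occupancy fractions summing to 1, named by cluster.
#' @export
clusterOccupancy <- function(labels, k) {
  labels <- as.integer(labels)
  if (!length(labels)) stop("empty label sequence")
  if (min(labels) < 0L || max(labels) >= k)
    stop("labels must lie in 0 .. k-1")
  setNames(tabulate(labels + 1L, k) / length(labels), 0:(k - 1))
}
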