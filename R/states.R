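## Connectivity-state decomposition: k-means over pooled windowed FC under
## correlation distance, validity-index k selection, and temporal state
## metrics with non-parametric group tests.

#' Correlation distance between two vectors
#'
#' `d = 1 - Pearson(u, v)`, in `[0, 2]`; invariant to affine rescaling of
#' either argument.
#'
#' @param u,v numeric vectors of equal length >= 2, neither constant.
#' @return The correlation distance.
#' @export
correlationDistance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (length(u) < 2L) stop("vectors must have length >= 2")
  if (sd(u) == 0 || sd(v) == 0) stop("correlation distance undefined for constant vectors")
  1 - cor(u, v)
}

## stack all subjects' window vectors; rows keep a subject map attribute
poolWindows <- function(wfcs) {
  stopifnot(length(wfcs) >= 1L)
  ids <- vapply(wfcs, subjectId, character(1))
  if (is.null(names(wfcs))) names(wfcs) <- ids
  mats <- lapply(wfcs, windowValues)
  pooled <- do.call(rbind, mats)
  attr(pooled, "subject") <- rep(names(wfcs), vapply(mats, nrow, integer(1)))
  pooled
}

.splitLabels <- function(labels, subjectMap) {
  split(labels, factor(subjectMap, levels = unique(subjectMap)))
}

#' k-means connectivity states
#'
#' Lloyd k-means on the pooled window-by-edge matrix of all subjects under
#' correlation distance, with arithmetic-mean centroid updates,
#' k-means++-style seeding, and the best of `nInit` restarts kept. The
#' objective (sum of within-cluster correlation distances) is non-increasing
#' over the iterations of each restart. Deterministic given `seed`.
#'
#' @param wfcs list of [WindowedFC-class] objects (or a pre-pooled numeric
#'   matrix with a `subject` attribute).
#' @param k number of states (2 <= k <= number of pooled windows).
#' @param seed optional integer seed.
#' @param nInit number of restarts (default 100).
#' @param maxIter Lloyd iteration cap per restart (default 500).
#' @return A [StateModel-class].
#' @export
kmeansStates <- function(wfcs, k, seed = NULL, nInit = 100L, maxIter = 500L) {
  pooled <- if (is.matrix(wfcs)) wfcs else poolWindows(wfcs)
  subjectMap <- attr(pooled, "subject")
  if (is.null(subjectMap)) subjectMap <- rep("pooled", nrow(pooled))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(pooled)) stop("k exceeds the number of pooled windows")
  if (!is.null(seed)) set.seed(seed)
  fit <- kmeans_corr_cpp(pooled, k, as.integer(nInit), as.integer(maxIter),
                         1e-10)
  labels <- fit$labels + 1L
  new("StateModel", k = k, centroids = fit$centroids,
      labels = .splitLabels(labels, subjectMap),
      objective = fit$objective,
      validity = data.frame(), distance = "correlation")
}

## ---- cluster-validity indices under a chosen geometry -------------------

## Dfull: full pairwise distance matrix; labels: integer vector
.silhouette <- function(Dfull, labels, k) {
  N <- length(labels)
  ind <- matrix(0, N, k)
  ind[cbind(seq_len(N), labels)] <- 1
  counts <- colSums(ind)
  sums <- Dfull %*% ind                       # N x k: summed distance to each cluster
  a <- sums[cbind(seq_len(N), labels)] / pmax(counts[labels] - 1, 1)
  meanOther <- sweep(sums, 2, counts, "/")
  meanOther[cbind(seq_len(N), labels)] <- Inf
  b <- apply(meanOther, 1, min)
  s <- (b - a) / pmax(a, b)
  s[counts[labels] == 1] <- 0                 # singleton convention
  mean(s)
}

.pairDist <- function(A, B, distance) {
  if (distance == "correlation") {
    1 - tcrossprod(.rowStandardize(A), .rowStandardize(B))
  } else {
    D <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    D[D < 0] <- 0
    D
  }
}

.rowStandardize <- function(X) {
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  nrm[nrm < 1e-12] <- 1e-12
  Xc / nrm
}

.validityIndices <- function(pooled, Dfull, labels, centroids, distance) {
  N <- nrow(pooled)
  k <- nrow(centroids)
  dToCent <- .pairDist(pooled, centroids, distance)
  withinD <- dToCent[cbind(seq_len(N), labels)]
  counts <- tabulate(labels, k)
  grand <- matrix(colMeans(pooled), 1)
  dCentGrand <- drop(.pairDist(centroids, grand, distance))
  B <- sum(counts * dCentGrand)
  W <- sum(withinD)
  ch <- (B / (k - 1)) / (W / (N - k))
  S <- vapply(seq_len(k), function(cc) mean(withinD[labels == cc]), numeric(1))
  M <- .pairDist(centroids, centroids, distance)
  db <- mean(vapply(seq_len(k), function(ii) {
    r <- (S[ii] + S[-ii]) / M[ii, seq_len(k)[-ii]]
    max(r)
  }, numeric(1)))
  c(silhouette = .silhouette(Dfull, labels, k),
    calinski_harabasz = ch,
    davies_bouldin = db)
}

## round half away from zero ("rounding backwards" of the simple average)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Select the number of connectivity states
#'
#' Fits [kmeansStates()] for every k in `kRange`, computes three
#' cluster-validity indices (silhouette, Calinski-Harabasz, Davies-Bouldin)
#' under the clustering's distance metric, takes the argmax of the first
#' two and the argmin of the third, and combines them by rounding the
#' simple average of the three per-index optima half away from zero
#' (configurable to `floor`).
#'
#' @param wfcs list of [WindowedFC-class] objects or pooled matrix.
#' @param kRange candidate k values (default 2:10).
#' @param seed optional integer seed governing all restarts.
#' @param nInit,maxIter passed to [kmeansStates()].
#' @param geometry geometry of the validity indices: `"euclidean"`
#'   (default; squared Euclidean scatter, the classical definitions of the
#'   Calinski-Harabasz and Davies-Bouldin indices and the convention of the
#'   common clustering-evaluation toolboxes) or `"correlation"` (the same
#'   indices with correlation distance substituted in every scatter term,
#'   matching the clustering metric).
#' @param combine rounding rule for the combined k: `"half-away"` or
#'   `"floor"`.
#' @return List with `validity` (data.frame of indices by k), `optima`
#'   (named per-index optimal k), `combinedK`, and `models` (list of
#'   [StateModel-class] by k, each carrying the validity table).
#' @export
selectK <- function(wfcs, kRange = 2:10, seed = NULL, nInit = 100L,
                    maxIter = 500L, geometry = c("euclidean", "correlation"),
                    combine = c("half-away", "floor")) {
  geometry <- match.arg(geometry)
  combine <- match.arg(combine)
  pooled <- if (is.matrix(wfcs)) wfcs else poolWindows(wfcs)
  subjectMap <- attr(pooled, "subject")
  if (max(kRange) > nrow(pooled)) stop("largest k exceeds the pooled window count")
  if (!is.null(seed)) set.seed(seed)

  Dfull <- if (geometry == "correlation") {
    1 - tcrossprod(.rowStandardize(pooled))
  } else {
    G <- tcrossprod(pooled)
    D <- outer(diag(G), diag(G), "+") - 2 * G
    D[D < 0] <- 0
    D
  }

  rows <- list()
  models <- list()
  for (k in kRange) {
    fit <- kmeans_corr_cpp(pooled, as.integer(k), as.integer(nInit),
                           as.integer(maxIter), 1e-10)
    labels <- fit$labels + 1L
    if (length(unique(labels)) < k) {
      warning("degenerate clustering at k = ", k, " (empty cluster); skipped")
      next
    }
    idx <- .validityIndices(pooled, Dfull, labels, fit$centroids, geometry)
    rows[[as.character(k)]] <- data.frame(k = k, t(idx))
    sm <- subjectMap
    if (is.null(sm)) sm <- rep("pooled", nrow(pooled))
    models[[as.character(k)]] <- new("StateModel", k = as.integer(k),
                                     centroids = fit$centroids,
                                     labels = .splitLabels(labels, sm),
                                     objective = fit$objective,
                                     validity = data.frame(),
                                     distance = "correlation")
  }
  if (!length(rows)) stop("no non-degenerate clustering in kRange")
  validity <- do.call(rbind, rows)
  rownames(validity) <- NULL
  optima <- c(
    silhouette = validity$k[which.max(validity$silhouette)],
    calinski_harabasz = validity$k[which.max(validity$calinski_harabasz)],
    davies_bouldin = validity$k[which.min(validity$davies_bouldin)]
  )
  avg <- mean(optima)
  combinedK <- if (combine == "half-away") as.integer(.roundHalfAway(avg))
               else as.integer(floor(avg))
  for (nm in names(models)) models[[nm]]@validity <- validity
  list(validity = validity, optima = optima, combinedK = combinedK,
       models = models)
}

#' Temporal state metrics of one label sequence
#'
#' Frequency (window count per state), mean dwell time (mean length of the
#' maximal runs of each state; 0 for an absent state), and the total number
#' of transitions (adjacent unequal pairs).
#'
#' @param labels integer label sequence with values in 1..k.
#' @param k number of states.
#' @return List with `frequency` and `dwellTime` (length-k vectors) and
#'   scalar `transitions`.
#' @examples
#' stateMetrics(c(1, 1, 1, 2, 2, 1), 2)
#' @export
stateMetrics <- function(labels, k) {
  labels <- as.integer(labels)
  if (!length(labels)) stop("empty label sequence")
  if (any(labels < 1L | labels > k)) stop("labels must lie in 1..", k)
  r <- rle(labels)
  frequency <- tabulate(labels, k)
  dwell <- numeric(k)
  for (s in seq_len(k)) {
    runs <- r$lengths[r$values == s]
    dwell[s] <- if (length(runs)) mean(runs) else 0
  }
  list(frequency = frequency, dwellTime = dwell,
       transitions = sum(diff(labels) != 0L))
}

#' Per-subject state metrics of a fitted state model
#'
#' @param model a [StateModel-class].
#' @return data.frame with one row per subject: `subject_id`,
#'   `dwell_<s>`, `freq_<s>` for each state, and `transitions`.
#' @export
cohortStateMetrics <- function(model) {
  stopifnot(is(model, "StateModel"))
  k <- model@k
  rows <- lapply(names(model@labels), function(id) {
    m <- stateMetrics(model@labels[[id]], k)
    out <- data.frame(subject_id = id)
    for (s in seq_len(k)) out[[paste0("dwell_", s)]] <- m$dwellTime[s]
    for (s in seq_len(k)) out[[paste0("freq_", s)]] <- m$frequency[s]
    out$transitions <- m$transitions
    out
  })
  do.call(rbind, rows)
}

#' Mann-Whitney U test (two-sided)
#'
#' Reports `U = min(U1, U2)`. The p value uses exact enumeration when
#' `n1 * n2 <= 400` and there are no ties, and the tie-corrected normal
#' approximation otherwise. When every value is tied across both groups the
#' test is undefined and `U = n1 n2 / 2`, `p = 1` is returned with a
#' warning.
#'
#' @param x,y numeric samples.
#' @return List with `U`, `p`, `n1`, `n2`.
#' @export
mannWhitneyU <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied across both groups; p set to 1")
    return(list(U = n1 * n2 / 2, p = 1, n1 = n1, n2 = n2))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 * n2 <= 400L) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  U1 <- unname(wt$statistic)
  list(U = min(U1, n1 * n2 - U1), p = wt$p.value, n1 = n1, n2 = n2)
}

.fmtMedianIQR <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%.4g (%.4g, %.4g)", q[2], q[1], q[3])
}

#' Group comparison of temporal state metrics
#'
#' Two-sided Mann-Whitney tests of each dwell-time, frequency and
#' transition column of [cohortStateMetrics()] output between the two
#' groups, with per-group "median (Q1, Q3)" summaries.
#'
#' @param metrics data.frame from [cohortStateMetrics()].
#' @param manifest data.frame with `subject_id` and `group`.
#' @return data.frame with one row per metric: the two group summaries,
#'   `U` and `p`.
#' @export
metricsGroupCompare <- function(metrics, manifest) {
  df <- merge(metrics, manifest[, c("subject_id", "group")], by = "subject_id")
  grp <- factor(df$group)
  if (nlevels(grp) != 2L) stop("exactly two groups required")
  if ("control" %in% levels(grp)) grp <- stats::relevel(grp, "control")
  gref <- levels(grp)[1]; gtest <- levels(grp)[2]
  cols <- setdiff(names(metrics), "subject_id")
  rows <- lapply(cols, function(cn) {
    x <- df[[cn]][grp == gtest]   # patient-like group first, as reported
    y <- df[[cn]][grp == gref]
    mw <- mannWhitneyU(x, y)
    data.frame(metric = cn,
               summary_test = .fmtMedianIQR(x),
               summary_ref = .fmtMedianIQR(y),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- c(paste0(gtest, "_median_iqr"), paste0(gref, "_median_iqr"))
  out
}
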