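## Regime-switching multivariate Gaussian cohort simulator. Two-group
## cohorts with known per-state covariances, Markov dwell structure,
## demographics and motion traces provide ground truth for every
## downstream stage.

#' Repair a matrix to the nearest unit-diagonal PSD correlation matrix
#'
#' Negative eigenvalues are clipped to zero, the matrix reconstructed and
#' rescaled back to unit diagonal. The sign pattern of the input should be
#' re-checked afterwards if it matters (see [buildStateCovariances()]).
#'
#' @param M symmetric matrix on correlation scale.
#' @return Unit-diagonal PSD matrix of the same dimension.
#' @export
repairCorrelation <- function(M) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  R <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(pmax(diag(R), .Machine$double.eps))
  R <- R / outer(d, d)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R
}

#' Build planted connectivity-state covariances from a parcellation
#'
#' Constructs one correlation-scale covariance per state from block targets
#' defined on the parcellation's network partition. The default two-state
#' configuration plants (1) a segregated state with weak positive
#' within-network blocks and weak negative between-network correlations, and
#' (2) an integrated state with moderate positive correlations throughout
#' except negative correlations between the designated default-mode-analog
#' network and all other networks. Each matrix is repaired to the nearest
#' PSD correlation matrix; the sign pattern is re-checked after repair and a
#' warning is raised if repair flipped any sign.
#'
#' @param parcellation a [Parcellation-class] with at least two networks.
#' @param patterns list of per-state specifications. Each element is a list
#'   with entries `within` (target correlation inside every network block),
#'   `between` (target between different networks) and optionally
#'   `dmnBetween` (target between the `dmnNetwork` and every other network,
#'   overriding `between` for those edges). All targets must satisfy |r| < 1.
#' @param dmnNetwork network label to treat as the default-mode analog;
#'   required (and checked for presence) whenever a pattern uses
#'   `dmnBetween`.
#' @return List of [StateCovariance-class] objects, one per pattern.
#' @examples
#' p <- makeParcellation(paste0("r", 1:6), rep(c("DMN", "VIS"), each = 3))
#' covs <- buildStateCovariances(p)
#' covs[[1]]
#' @export
buildStateCovariances <- function(parcellation,
                                  patterns = defaultStatePatterns(),
                                  dmnNetwork = "DMN") {
  stopifnot(is(parcellation, "Parcellation"))
  nets <- networkLabels(parcellation)
  if (length(unique(nets)) < 2L)
    stop("parcellation must contain at least 2 networks")
  R <- nROIs(parcellation)
  lapply(seq_along(patterns), function(s) {
    sp <- patterns[[s]]
    targets <- c(sp$within, sp$between, sp$dmnBetween)
    if (any(abs(targets) >= 1))
      stop("pattern targets must be correlations with |r| < 1")
    M <- matrix(sp$between, R, R)
    same <- outer(nets, nets, "==")
    M[same] <- sp$within
    if (!is.null(sp$dmnBetween)) {
      if (!dmnNetwork %in% nets)
        stop("parcellation has no network labeled '", dmnNetwork,
             "' (required by the dmnBetween pattern)")
      dmn <- nets == dmnNetwork
      cross <- outer(dmn, !dmn, "&") | outer(!dmn, dmn, "&")
      M[cross] <- sp$dmnBetween
    }
    diag(M) <- 1
    Mr <- repairCorrelation(M)
    flipped <- sign(Mr[lower.tri(Mr)]) != sign(M[lower.tri(M)]) &
      abs(M[lower.tri(M)]) > 1e-12
    if (any(flipped))
      warning(sprintf("PSD repair flipped the sign of %d edge target(s) in state %d",
                      sum(flipped), s))
    desc <- if (is.null(sp$description)) sprintf("state %d", s) else sp$description
    new("StateCovariance", stateId = as.integer(s), matrix = Mr,
        description = desc)
  })
}

#' Default two-state pattern specification
#'
#' State 1 ("segregated"): slight positive within-network connectivity
#' (+0.1) on a slightly negative background (-0.05). State 2 ("integrated"):
#' moderate positive connectivity (+0.3 within, +0.2 between) with the
#' default-mode-analog network anticorrelated with all others (-0.15).
#'
#' @return List of two pattern lists for [buildStateCovariances()].
#' @export
defaultStatePatterns <- function() {
  list(
    list(within = 0.1, between = -0.05,
         description = "segregated: weak within-network positivity, weak global negativity"),
    list(within = 0.3, between = 0.2, dmnBetween = -0.15,
         description = "integrated: moderate positivity, DMN-analog anticorrelated")
  )
}

## first-order Markov state sequence; stay[s] = P(stay | state s),
## leave mass spread uniformly over the other states
.markovLabels <- function(T, S, stay, initProb) {
  if (length(stay) == 1L) stay <- rep(stay, S)
  stopifnot(length(stay) == S)
  labels <- integer(T)
  labels[1] <- sample.int(S, 1L, prob = initProb)
  if (T > 1L && S > 1L) {
    u <- runif(T - 1L)
    pick <- runif(T - 1L) # used only on switches
    for (t in 2:T) {
      s <- labels[t - 1L]
      if (u[t - 1L] <= stay[s]) {
        labels[t] <- s
      } else {
        others <- seq_len(S)[-s]
        labels[t] <- others[ceiling(pick[t - 1L] * (S - 1L))]
      }
    }
  } else if (T > 1L) {
    labels[2:T] <- labels[1]
  }
  labels
}

## symmetric PSD square root via eigendecomposition (chol would fail on
## the semi-definite matrices the repair step can produce)
.covSqrt <- function(Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate one subject's regime-switching time series
#'
#' Draws a first-order Markov label sequence with the given stay
#' probability, jitters each state covariance with a symmetric Gaussian
#' perturbation of the off-diagonals (then repairs to PSD), and samples each
#' time point from a zero-mean multivariate normal under the current state's
#' covariance, plus isotropic observation noise. Identical seeds give
#' identical output.
#'
#' @param covs list of [StateCovariance-class] objects sharing dimension R.
#' @param T number of time points (>= 1).
#' @param stayProb probability of remaining in the current state per step;
#'   scalar or one value per state. `1.0` is accepted and yields a constant
#'   label sequence.
#' @param jitterSd SD of the per-subject off-diagonal perturbation.
#' @param noiseSd SD of the isotropic observation noise.
#' @param seed optional integer seed (set via [set.seed()] when given).
#' @param initialStateProb initial-state distribution (default uniform).
#' @return List with `signal` (T x R matrix, time in rows), `labels`
#'   (integer vector of length T) and `covariances` (the realized per-state
#'   jittered covariances).
#' @export
simulateSubject <- function(covs, T, stayProb, jitterSd = 0.02,
                            noiseSd = 0.2, seed = NULL,
                            initialStateProb = NULL) {
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1")
  S <- length(covs)
  dims <- vapply(covs, function(cv) nrow(cv@matrix), integer(1))
  if (length(unique(dims)) != 1L) stop("state covariances must share dimension")
  R <- dims[1]
  if (any(stayProb < 0 | stayProb > 1)) stop("stayProb must lie in [0, 1]")
  if (is.null(initialStateProb)) initialStateProb <- rep(1 / S, S)
  if (!is.null(seed)) set.seed(seed)

  realized <- lapply(covs, function(cv) {
    Sigma <- cv@matrix
    if (jitterSd > 0) {
      Z <- matrix(rnorm(R * R, sd = jitterSd), R, R)
      J <- (Z + t(Z)) / 2
      diag(J) <- 0
      Sigma <- repairCorrelation(Sigma + J)
    }
    Sigma
  })
  roots <- lapply(realized, .covSqrt)

  labels <- .markovLabels(T, S, stayProb, initialStateProb)
  signal <- matrix(0, T, R)
  for (s in seq_len(S)) {
    idx <- which(labels == s)
    if (length(idx))
      signal[idx, ] <- matrix(rnorm(length(idx) * R), length(idx), R) %*% roots[[s]]
  }
  if (noiseSd > 0)
    signal <- signal + matrix(rnorm(T * R, sd = noiseSd), T, R)
  list(signal = signal, labels = labels, covariances = realized)
}

#' Construct a cohort design
#'
#' Defaults emulate a small two-group dementia-versus-control resting-state
#' cohort: 17 patients vs 20 controls, 130 retained volumes at TR = 2 s,
#' and symmetric state persistence 0.9 in both groups.
#'
#' @param nPerGroup integer pair, subjects per group (patient-like first).
#' @param groups group labels.
#' @param R number of ROIs (used when simulating without a parcellation).
#' @param T time points per subject (post-discard).
#' @param TR seconds per volume.
#' @param stayProb named list (by group) of stay probabilities; scalars are
#'   shared across states.
#' @param initialStateProb initial-state simplex (default uniform over the
#'   number of planted states).
#' @param noiseSd,jitterSd observation-noise and subject-jitter scales.
#' @param patterns per-state pattern list (see [buildStateCovariances()]);
#'   alternatively a list named by group to give each group its own states.
#' @param seed integer base seed.
#' @return A [CohortDesign-class].
#' @export
cohortDesign <- function(nPerGroup = c(17L, 20L),
                         groups = c("patient", "control"),
                         R = 20L, T = 130L, TR = 2,
                         stayProb = list(patient = 0.9, control = 0.9),
                         initialStateProb = NULL,
                         noiseSd = 0.2, jitterSd = 0.02,
                         patterns = defaultStatePatterns(),
                         seed = 1L) {
  perGroup <- all(groups %in% names(patterns))
  nStates <- if (perGroup) length(patterns[[groups[1]]]) else length(patterns)
  if (is.null(initialStateProb)) initialStateProb <- rep(1 / nStates, nStates)
  new("CohortDesign",
      nPerGroup = as.integer(nPerGroup), groups = groups,
      R = as.integer(R), T = as.integer(T), TR = TR,
      stayProb = stayProb, initialStateProb = initialStateProb,
      noiseSd = noiseSd, jitterSd = jitterSd,
      patterns = patterns, seed = as.integer(seed))
}

## group demographics loosely matched to a small dementia cohort:
## patients older (mean 72, sd 5.7, clipped 60..82) and mostly male (13/17),
## controls (mean 68, sd 7.2, clipped 56..77) with 9/20 male
.drawDemographics <- function(group, n, isPatient) {
  if (isPatient) {
    age <- round(pmin(pmax(rnorm(n, 72, 5.7), 60), 82), 1)
    nMale <- round(n * 13 / 17)
  } else {
    age <- round(pmin(pmax(rnorm(n, 68, 7.2), 56), 77), 1)
    nMale <- round(n * 9 / 20)
  }
  sex <- sample(c(rep("M", nMale), rep("F", n - nMale)))
  data.frame(group = group, age = age, sex = sex, stringsAsFactors = FALSE)
}

## slow random-walk motion trace, small amplitude; translations mm,
## rotations degrees
.simulateMotion <- function(T) {
  steps <- matrix(rnorm(T * 6, sd = c(rep(0.02, 3), rep(0.015, 3))[rep(1:6, each = T)]),
                  T, 6)
  apply(steps, 2, cumsum)
}

#' Simulate a two-group cohort
#'
#' Simulates every subject of the design (per-subject seed = base seed +
#' subject index, so cohorts are reproducible under subsetting), draws
#' demographics, and optionally writes the on-disk cohort layout: one
#' time-series TSV and one 6-column motion file per subject, a manifest TSV
#' and a ground-truth JSON with the latent label sequences.
#'
#' @param design a [CohortDesign-class].
#' @param parcellation optional [Parcellation-class] defining the network
#'   blocks of the planted covariances; when missing, a generic parcellation
#'   of `design@R` ROIs in 4 equal networks (first one the DMN analog) is
#'   used.
#' @param dir output directory; `NULL` keeps the cohort in memory only.
#' @param dmnNetwork DMN-analog label passed to [buildStateCovariances()].
#' @return List with `manifest` (data.frame), `signals` (named list of
#'   T x R matrices), `motion` (named list), `labels` (named list of latent
#'   state sequences), `covariances` (planted state covariances by group)
#'   and `dir`.
#' @export
simulateCohort <- function(design, parcellation = NULL, dir = NULL,
                           dmnNetwork = "DMN") {
  stopifnot(is(design, "CohortDesign"))
  if (is.null(parcellation)) {
    nets <- c("DMN", "SMN", "VIS", "FPN")
    ## equal-ish contiguous blocks in a fixed network order
    lab <- rep(nets, each = ceiling(design@R / 4))[seq_len(design@R)]
    parcellation <- makeParcellation(paste0("roi_", seq_len(design@R)), lab)
  }
  if (nROIs(parcellation) != design@R)
    stop("parcellation size does not match design R")

  perGroupPatterns <- all(design@groups %in% names(design@patterns))
  covsByGroup <- lapply(setNames(design@groups, design@groups), function(g) {
    pat <- if (perGroupPatterns) design@patterns[[g]] else design@patterns
    buildStateCovariances(parcellation, pat, dmnNetwork = dmnNetwork)
  })

  set.seed(design@seed)
  demo <- do.call(rbind, lapply(1:2, function(gi)
    .drawDemographics(design@groups[gi], design@nPerGroup[gi], gi == 1L)))
  nTotal <- sum(design@nPerGroup)
  ids <- sprintf("sub-%03d", seq_len(nTotal))
  manifest <- data.frame(subject_id = ids, demo, stringsAsFactors = FALSE)

  signals <- motion <- labels <- vector("list", nTotal)
  names(signals) <- names(motion) <- names(labels) <- ids
  for (s in seq_len(nTotal)) {
    g <- manifest$group[s]
    sim <- simulateSubject(covsByGroup[[g]], design@T,
                           stayProb = design@stayProb[[g]],
                           jitterSd = design@jitterSd,
                           noiseSd = design@noiseSd,
                           seed = design@seed + s,
                           initialStateProb = design@initialStateProb)
    colnames(sim$signal) <- roiIds(parcellation)
    signals[[s]] <- sim$signal
    labels[[s]] <- sim$labels
    motion[[s]] <- .simulateMotion(design@T)
  }

  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir)
    for (s in seq_len(nTotal)) {
      writeTimeseries(signals[[s]], file.path(dir, paste0(ids[s], "_timeseries.tsv")))
      writeMotion(motion[[s]], file.path(dir, paste0(ids[s], "_motion.txt")))
    }
    writeManifest(manifest, file.path(dir, "manifest.tsv"))
    gt <- list(
      design = list(nPerGroup = design@nPerGroup, groups = design@groups,
                    R = design@R, T = design@T, TR = design@TR,
                    stayProb = design@stayProb,
                    noiseSd = design@noiseSd, jitterSd = design@jitterSd,
                    seed = design@seed),
      labels = labels
    )
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(manifest = manifest, signals = signals, motion = motion,
       labels = labels, covariances = covsByGroup, dir = dir,
       parcellation = parcellation)
}
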