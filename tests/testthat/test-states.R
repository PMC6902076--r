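test_that("correlation distance has the defining properties", {
  u <- c(1, 3, 2, 5, 4)
  expect_equal(correlationDistance(u, u), 0)
  expect_equal(correlationDistance(u, -u + 10), 2)
  expect_equal(correlationDistance(u, 3 * u + 7), 0)  # magnitude invariance
  expect_error(correlationDistance(u, rep(1, 5)), "constant")
  expect_error(correlationDistance(u, u[1:3]), "equal length")
})

test_that("k-means recovers well-separated planted patterns", {
  set.seed(20)
  E <- 40
  c1 <- rnorm(E)
  c2 <- -0.5 * c1 + rnorm(E, sd = 0.5)   # far in correlation distance
  n <- 150
  truth <- rep(1:2, each = n)
  X <- rbind(
    matrix(rep(c1, n), n, E, byrow = TRUE),
    matrix(rep(c2, n), n, E, byrow = TRUE)
  ) + matrix(rnorm(2 * n * E, sd = 0.15), 2 * n, E)
  wfc <- makeWfc(X)
  model <- kmeansStates(list(wfc), 2, seed = 1, nInit = 10)
  lab <- stateLabels(model)[[1]]
  acc <- max(mean(lab == truth), mean(lab == 3 - truth))
  expect_gte(acc, 0.99)

  # centroids are the means of their member vectors
  for (s in 1:2) {
    expect_equal(centroids(model)[s, ], colMeans(X[lab == s, , drop = FALSE]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # objective equals the recomputed sum of within-cluster distances
  obj <- sum(vapply(seq_len(nrow(X)), function(i)
    correlationDistance(X[i, ], centroids(model)[lab[i], ]), numeric(1)))
  expect_equal(clusterObjective(model), obj, tolerance = 1e-8)
})

test_that("k-means edge cases: k = rows, determinism, bad k", {
  set.seed(21)
  X <- matrix(rnorm(8 * 10), 8, 10)
  wfc <- makeWfc(X)
  all_own <- kmeansStates(list(wfc), 8, seed = 2, nInit = 5)
  expect_equal(clusterObjective(all_own), 0, tolerance = 1e-10)
  expect_equal(sort(unique(stateLabels(all_own)[[1]])), 1:8)

  m1 <- kmeansStates(list(wfc), 3, seed = 9, nInit = 5)
  m2 <- kmeansStates(list(wfc), 3, seed = 9, nInit = 5)
  expect_identical(stateLabels(m1), stateLabels(m2))
  expect_identical(centroids(m1), centroids(m2))

  expect_error(kmeansStates(list(wfc), 1), ">= 2")
  expect_error(kmeansStates(list(wfc), 9), "exceeds")
})

test_that("the combined-k rounding rule averages the per-index optima", {
  roundHalf <- dynconn:::.roundHalfAway
  expect_equal(roundHalf(mean(c(2, 2, 2))), 2)
  expect_equal(roundHalf(mean(c(2, 3, 4))), 3)
  expect_equal(roundHalf(2.5), 3)       # half away from zero
  expect_equal(roundHalf(3.5), 4)
  expect_equal(floor(mean(c(2, 3, 3))), 2)  # the configurable floor variant
})

test_that("k selection recovers the planted number of states", {
  # two strongly separated synthetic patterns
  set.seed(22)
  E <- 30
  c1 <- rnorm(E); c2 <- -c1
  X <- rbind(
    matrix(rep(c1, 100), 100, E, byrow = TRUE),
    matrix(rep(c2, 100), 100, E, byrow = TRUE)
  ) + matrix(rnorm(200 * E, sd = 0.2), 200, E)
  ks <- selectK(list(makeWfc(X)), kRange = 2:6, seed = 3, nInit = 10)
  expect_equal(ks$combinedK, 2L)
  expect_equal(unname(ks$optima["silhouette"]), 2)
  expect_true(all(c("silhouette", "calinski_harabasz", "davies_bouldin")
                  %in% names(ks$validity)))
})

test_that("k selection is not hard-wired to two states", {
  # three-state cohorts from the same generator. The three planted
  # covariances are mutually near-orthogonal block patterns with strong
  # amplitude and long dwells: sliding-window estimation noise
  # (sd ~ 1/sqrt(w-3) per edge) and state-mixing inside windows otherwise
  # dominate the between-state separation.
  p <- toyParcellation(4, 5, networks = c("DMN", "VIS", "SMN", "FPN"))
  net <- networkLabels(p)
  blockCov <- function(within, pairsPos, posval, base = -0.1) {
    M <- matrix(base, 20, 20)
    M[outer(net, net, "==")] <- within
    for (pr in pairsPos) {
      m <- outer(net == pr[1], net == pr[2]) | outer(net == pr[2], net == pr[1])
      M[m] <- posval
    }
    diag(M) <- 1
    repairCorrelation(M)
  }
  covs <- list(
    new("StateCovariance", stateId = 1L,
        matrix = blockCov(0.65, list(), 0), description = "within-only"),
    new("StateCovariance", stateId = 2L,
        matrix = blockCov(0.15, list(c("DMN", "VIS"), c("SMN", "FPN")), 0.65),
        description = "DMN-VIS / SMN-FPN coupled"),
    new("StateCovariance", stateId = 3L,
        matrix = blockCov(0.15, list(c("DMN", "SMN"), c("VIS", "FPN")), 0.65),
        description = "DMN-SMN / VIS-FPN coupled"))
  hits <- 0
  nSeeds <- 10
  for (rep in seq_len(nSeeds)) {
    wfcs <- lapply(1:12, function(s) {
      sim <- simulateSubject(covs, T = 130, stayProb = 0.97, jitterSd = 0.02,
                             noiseSd = 0.2, seed = 4000 + rep * 100 + s)
      slidingFC(sim$signal, 20, 1, paste0("s", s))
    })
    set.seed(4000 + rep)
    ks <- selectK(wfcs, kRange = 2:6, nInit = 15)
    if (ks$combinedK == 3L) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * nSeeds)
})

test_that("state metrics enumerate runs, frequencies and transitions", {
  m <- stateMetrics(c(1, 1, 1, 2, 2, 1), 2)
  expect_equal(m$frequency, c(4, 2))
  expect_equal(m$dwellTime, c(2, 2))   # runs of state 1: (3, 1); state 2: (2)
  expect_equal(m$transitions, 2)

  allOne <- stateMetrics(rep(1L, 111), 2)
  expect_equal(allOne$frequency, c(111, 0))
  expect_equal(allOne$dwellTime, c(111, 0))
  expect_equal(allOne$transitions, 0)

  expect_error(stateMetrics(c(1, 3), 2), "1\\.\\.2")

  # exact identities for k = 2 over random sequences
  set.seed(23)
  for (rep in 1:50) {
    labs <- sample(1:2, 111, replace = TRUE)
    m <- stateMetrics(labs, 2)
    expect_equal(sum(m$frequency), 111)
    runs <- rle(labs)
    expect_equal(m$transitions, length(runs$lengths) - 1)
    for (s in 1:2) {
      nRuns <- sum(runs$values == s)
      if (nRuns > 0)
        expect_equal(m$frequency[s], m$dwellTime[s] * nRuns)
    }
  }
})

test_that("state relabeling permutes metrics consistently", {
  labs <- c(1L, 1L, 2L, 3L, 3L, 3L, 2L)
  m <- stateMetrics(labs, 3)
  perm <- c(2L, 3L, 1L)    # relabel s -> perm[s]
  m2 <- stateMetrics(perm[labs], 3)
  expect_equal(m2$frequency[perm], m$frequency)
  expect_equal(m2$dwellTime[perm], m$dwellTime)
  expect_equal(m2$transitions, m$transitions)
})

test_that("Mann-Whitney U reporting follows the min-U convention", {
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  r2 <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$U, 3 * 3 / 2)
  expect_gt(r2$p, 0.9)
  expect_warning(r3 <- mannWhitneyU(c(2, 2, 2), c(2, 2)), "tied")
  expect_equal(r3$p, 1)
  # exact p agrees with the closed form for tiny samples
  expect_equal(mannWhitneyU(c(1, 2), c(3, 4))$p, 2 / choose(4, 2))
})

test_that("the dwell U-test has power at the prescribed stay probabilities", {
  # ground-truth label sequences (dwell in TRs): isolates the power of the
  # Mann-Whitney dwell comparison from windowed state estimation
  p <- toyParcellation(2, 2)
  hits <- 0
  nRep <- 100
  for (rep in seq_len(nRep)) {
    design <- cohortDesign(
      nPerGroup = c(17L, 20L), R = 4L, T = 130L,
      stayProb = list(patient = 0.95, control = 0.80),
      seed = 10000 + rep * 101L)
    sim <- simulateCohort(design, parcellation = p)
    dwell <- vapply(sim$labels, function(l) stateMetrics(l, 2)$dwellTime[1],
                    numeric(1))
    grp <- sim$manifest$group
    pv <- mannWhitneyU(dwell[grp == "patient"], dwell[grp == "control"])$p
    if (pv < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * nRep)
})

test_that("group comparison of metrics produces the expected table", {
  labsA <- list(rep(1L, 10), c(rep(1L, 8), rep(2L, 2)))
  labsB <- list(rep(c(1L, 2L), 5), c(rep(2L, 6), rep(1L, 4)))
  model <- new("StateModel", k = 2L,
               centroids = matrix(0, 2, 3),
               labels = setNames(c(labsA, labsB), sprintf("s%02d", 1:4)),
               objective = 0, validity = data.frame(),
               distance = "correlation")
  metrics <- cohortStateMetrics(model)
  expect_equal(nrow(metrics), 4)
  expect_equal(metrics$freq_1 + metrics$freq_2, rep(10, 4))

  manifest <- makeManifest(2, 2)
  out <- metricsGroupCompare(metrics, manifest)
  expect_setequal(out$metric,
                  c("dwell_1", "dwell_2", "freq_1", "freq_2", "transitions"))
  expect_true(all(out$p >= 0 & out$p <= 1))
  expect_true(all(grepl("\\(", out[[2]])))   # median (Q1, Q3) format
})
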