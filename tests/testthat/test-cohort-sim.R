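test_that("planted block covariances match their targets and stay PSD", {
  p <- toyParcellation(2, 3)
  covs <- buildStateCovariances(p, list(list(within = 0.1, between = -0.05)))
  M <- covs[[1]]@matrix
  expected <- matrix(-0.05, 6, 6)
  expected[1:3, 1:3] <- 0.1
  expected[4:6, 4:6] <- 0.1
  diag(expected) <- 1
  # already PSD: repair must leave it unchanged
  expect_equal(M, expected, tolerance = 1e-12)
  expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)

  ident <- buildStateCovariances(p, list(list(within = 0, between = 0)))
  expect_equal(ident[[1]]@matrix, diag(6))
})

test_that("integrated state anticorrelates the DMN-analog with all others", {
  p <- toyParcellation(4, 3)
  covs <- buildStateCovariances(p)
  expect_length(covs, 2)
  M <- covs[[2]]@matrix
  net <- networkLabels(p)
  dmn <- net == "DMN"
  cross <- (outer(dmn, !dmn, "&") | outer(!dmn, dmn, "&"))
  off <- !diag(nrow(M))
  expect_true(all(M[cross & off] < 0))
  expect_true(all(M[!cross & off] > 0))

  # every generated covariance: PSD, unit diagonal
  for (cv in covs) {
    expect_equal(diag(cv@matrix), rep(1, nROIs(p)))
    expect_gte(min(eigen(cv@matrix, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
  }
})

test_that("invalid pattern targets and missing DMN label are rejected", {
  p <- toyParcellation(2, 3)
  expect_error(buildStateCovariances(p, list(list(within = 1.2, between = 0))),
               "\\|r\\| < 1")
  q <- toyParcellation(2, 3, networks = c("A", "B"))
  expect_error(buildStateCovariances(q), "DMN")
  one <- makeParcellation(c("a", "b"), c("N", "N"))
  expect_error(buildStateCovariances(one, list(list(within = 0.1, between = 0))),
               "at least 2 networks")
})

test_that("subject simulation honors the Markov dwell structure", {
  p <- toyParcellation(2, 3)
  covs <- buildStateCovariances(p)

  # absorbing chain
  s <- simulateSubject(covs, T = 50, stayProb = 1.0, seed = 1)
  expect_equal(length(unique(s$labels)), 1L)

  # determinism
  a <- simulateSubject(covs, T = 80, stayProb = 0.9, seed = 7)
  b <- simulateSubject(covs, T = 80, stayProb = 0.9, seed = 7)
  expect_identical(a$signal, b$signal)
  expect_identical(a$labels, b$labels)

  # mean run length ~ geometric mean 1/(1-p)
  s <- simulateSubject(covs, T = 10000, stayProb = 0.9, jitterSd = 0,
                       noiseSd = 0, seed = 11)
  runs <- rle(s$labels)$lengths
  expect_lt(abs(mean(runs) - 10) / 10, 0.05)

  # dimension mismatch
  small <- buildStateCovariances(toyParcellation(2, 2))
  expect_error(simulateSubject(c(covs[1], small[2]), T = 10, stayProb = 0.9),
               "share dimension")
})

test_that("run lengths follow the geometric distribution", {
  p <- toyParcellation(2, 3)
  covs <- buildStateCovariances(p)
  stay <- 0.8
  s <- simulateSubject(covs, T = 50000, stayProb = stay, jitterSd = 0,
                       noiseSd = 0, seed = 21)
  runs <- rle(s$labels)$lengths
  # drop the final (censored) run
  runs <- runs[-length(runs)]
  kmax <- 25
  obs <- tabulate(pmin(runs, kmax), kmax)
  pgeom_bins <- dgeom(0:(kmax - 2), prob = 1 - stay)
  probs <- c(pgeom_bins, 1 - sum(pgeom_bins))
  gof <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("in-state sample correlation converges to the planted covariance", {
  p <- toyParcellation(2, 3)
  covs <- buildStateCovariances(p)
  s <- simulateSubject(covs[1], T = 6000, stayProb = 1.0, jitterSd = 0,
                       noiseSd = 0, seed = 31)
  emp <- cor(s$signal)
  frob <- sqrt(sum((emp - covs[[1]]@matrix)^2))
  expect_lt(frob, 0.1)
})

test_that("cohort simulation writes a round-trippable on-disk layout", {
  dir <- withr::local_tempdir()
  design <- cohortDesign(nPerGroup = c(3L, 4L), R = 8L, T = 40L, seed = 5)
  sim <- simulateCohort(design, dir = dir)

  expect_equal(nrow(sim$manifest), 7)
  tsFiles <- list.files(dir, pattern = "_timeseries.tsv$")
  expect_length(tsFiles, 7)
  expect_length(list.files(dir, pattern = "_motion.txt$"), 7)

  id <- sim$manifest$subject_id[1]
  back <- readTimeseries(file.path(dir, paste0(id, "_timeseries.tsv")))
  expect_identical(unname(back), unname(sim$signals[[id]]))
  expect_equal(dim(back), c(40, 8))

  man <- readManifest(file.path(dir, "manifest.tsv"))
  expect_equal(man$subject_id, sim$manifest$subject_id)
  expect_equal(man$group, sim$manifest$group)

  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(unname(lengths(gt$labels)), rep(40, 7))
  expect_equal(gt$design$seed, 5)

  # reproducibility of the whole cohort
  sim2 <- simulateCohort(design)
  expect_identical(sim$signals, sim2$signals)

  tiny <- simulateCohort(cohortDesign(nPerGroup = c(1L, 1L), R = 6L, T = 30L))
  expect_equal(nrow(tiny$manifest), 2)
})

test_that("default full-size design yields the expected cohort dimensions", {
  design <- cohortDesign(seed = 2)
  expect_equal(design@nPerGroup, c(17L, 20L))
  sim <- simulateCohort(cohortDesign(nPerGroup = c(2L, 2L), seed = 2))
  expect_equal(dim(sim$signals[[1]]), c(130, 20))
})

test_that("lower stay probability produces more transitions", {
  p <- toyParcellation(2, 3)
  nA <- 0
  for (rep in 1:100) {
    designA <- cohortDesign(nPerGroup = c(3L, 3L), R = 6L, T = 100L,
                            stayProb = list(patient = 0.95, control = 0.80),
                            seed = 1000 + rep * 11L)
    sim <- simulateCohort(designA, parcellation = p)
    trans <- vapply(sim$labels, function(l) sum(diff(l) != 0), numeric(1))
    grp <- sim$manifest$group
    if (mean(trans[grp == "patient"]) < mean(trans[grp == "control"]))
      nA <- nA + 1
  }
  expect_gte(nA, 95)
})
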