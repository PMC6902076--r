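test_that("window count matches brute-force enumeration of start indices", {
  expect_equal(windowCount(130, 20, 1), 111)
  expect_equal(windowCount(20, 20, 1), 1)
  expect_equal(windowCount(10, 4, 2), 4)
  expect_error(windowCount(10, 11, 1), "exceeds")

  for (T in 2:50) {
    for (w in c(1, 2, 5, T)) {
      if (w > T) next
      for (step in 1:4) {
        brute <- length(seq(1, T - w + 1, by = step))
        expect_equal(windowCount(T, w, step), brute)
      }
    }
  }
})

test_that("Fisher transform is the clamped atanh with exact inverse", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisherZ(0.5), log(3) / 2)
  expect_equal(fisherZ(1), atanh(1 - 1e-7))
  expect_equal(fisherZ(-0.3), -fisherZ(0.3))
  expect_error(fisherZ(1.01), "<= 1")

  r <- seq(-0.999999, 0.999999, length.out = 101)
  expect_lt(max(abs(inverseFisherZ(fisherZ(r)) - r)), 1e-9)
})

test_that("static FC reproduces exact and asymptotic correlations", {
  set.seed(5)
  x <- rnorm(100)
  ts <- cbind(a = x, b = 2 * x, c = rnorm(100))
  C <- staticFC(ts)
  expect_equal(C["a", "b"], 1)
  ts2 <- cbind(a = x, b = -x)
  expect_equal(staticFC(ts2)["a", "b"], -1)

  big <- matrix(rnorm(2 * 10000), 10000, 2)
  expect_lt(abs(staticFC(big)[1, 2]), 0.05)

  degen <- cbind(x, rep(1, 100))
  expect_error(staticFC(degen), "zero-variance")
  expect_error(staticFC(ts[1:2, ]), "3 time points")
})

test_that("sliding FC agrees with direct per-window recomputation", {
  set.seed(6)
  T <- 60; R <- 5; w <- 15
  ts <- matrix(rnorm(T * R), T, R)
  wfc <- slidingFC(ts, w, 2, "s")
  expect_equal(nWindows(wfc), windowCount(T, w, 2))
  oracle <- t(sapply(windowStarts(wfc), function(s) {
    fisherZ(cor(ts[s:(s + w - 1), ])[lower.tri(diag(R))])
  }))
  expect_equal(windowValues(wfc), oracle, tolerance = 1e-10)
})

test_that("sliding FC tracks a planted connectivity flip", {
  set.seed(7)
  T <- 120; w <- 20
  z <- rnorm(T)
  x <- rnorm(T, sd = 0.3)
  first <- 1:(T / 2); second <- (T / 2 + 1):T
  a <- z + x
  b <- c(z[first], -z[second]) + rnorm(T, sd = 0.3)
  ts <- cbind(a, b, rnorm(T))
  wfc <- slidingFC(ts, w, 1, "s")
  traj <- windowValues(wfc)[, 1]      # edge (1,2)
  expect_gt(traj[1], 0.5)
  expect_lt(traj[length(traj)], -0.5)
  crossing <- which(diff(sign(traj)) != 0)
  expect_true(any(abs(crossing - (T / 2 - w / 2)) < w))
})

test_that("degenerate sliding windows raise informative errors", {
  ts <- matrix(rnorm(60 * 3), 60, 3)
  ts[5:30, 2] <- 7
  expect_error(slidingFC(ts, 20, 1), "window .*ROI")

  # stationary perfectly-correlated pair hits the Fisher clamp everywhere
  x <- rnorm(60)
  wfc <- slidingFC(cbind(x, x, rnorm(60)), 20, 1)
  expect_true(all(windowValues(wfc)[, 1] == atanh(1 - 1e-7)))
})

test_that("full-length window reduces sliding FC to static FC", {
  set.seed(8)
  ts <- matrix(rnorm(50 * 4), 50, 4)
  wfc <- slidingFC(ts, 50, 1)
  expect_equal(nWindows(wfc), 1)
  expect_equal(drop(windowValues(wfc)),
               fisherZ(matrixToVector(staticFC(ts))), tolerance = 1e-10)
})

test_that("dFCV is the per-edge sample SD and is affine invariant", {
  vals <- matrix(1.3, 5, 3)
  expect_true(all(computeDFCV(makeWfc(vals)) == 0))

  two <- matrix(c(0, 1, 0, 1, 0, 1), 2, 3)
  d <- computeDFCV(makeWfc(two))
  expect_equal(d[1, 2], sqrt(0.5), tolerance = 1e-6)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 3))

  expect_error(computeDFCV(makeWfc(two[1, , drop = FALSE])), "2 windows")

  # correlation invariance under common affine rescaling of the series
  set.seed(9)
  ts <- matrix(rnorm(80 * 4), 80, 4)
  d1 <- computeDFCV(slidingFC(ts, 20, 1))
  d2 <- computeDFCV(slidingFC(ts * 3 + 7, 20, 1))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("edgewise group comparison finds a planted dFCV shift", {
  set.seed(10)
  n1 <- 8; n2 <- 8; N <- 6
  manifest <- makeManifest(n1, n2)
  fcvs <- lapply(seq_len(n1 + n2), function(s) {
    v <- abs(rnorm(choose(N, 2), 0.3, 0.03))
    vectorToMatrix(v, N)
  })
  names(fcvs) <- manifest$subject_id
  # plant a strong increase on edge (1,2) in the patient group
  for (s in which(manifest$group == "patient"))
    fcvs[[s]][1, 2] <- fcvs[[s]][2, 1] <- fcvs[[s]][1, 2] + 0.3

  res <- fcvGroupCompare(fcvs, manifest, alpha = 0.005)
  expect_equal(dim(res$tMatrix), c(N, N))
  expect_equal(res$pMatrix, t(res$pMatrix))
  expect_true(all(res$pMatrix >= 0 & res$pMatrix <= 1))
  pv <- res$pMatrix
  diag(pv) <- 1
  expect_equal(which(pv == min(pv), arr.ind = TRUE)[1, ], c(row = 2, col = 1))
  expect_true(res$mask[1, 2])
  expect_gt(res$signMatrix[1, 2], 0)
})

test_that("edgewise test agrees with a permutation oracle", {
  set.seed(11)
  n <- 14
  manifest <- makeManifest(7, 7)
  N <- 4
  fcvs <- lapply(seq_len(n), function(s) vectorToMatrix(abs(rnorm(6, 0.4, 0.05)), N))
  names(fcvs) <- manifest$subject_id
  for (s in which(manifest$group == "patient"))
    fcvs[[s]][1, 2] <- fcvs[[s]][2, 1] <- fcvs[[s]][1, 2] + 0.08

  res <- fcvGroupCompare(fcvs, manifest)
  tObs <- res$tMatrix[1, 2]
  pParam <- res$pMatrix[1, 2]

  nPerm <- 1000
  tPerm <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    mperm <- manifest
    mperm$group <- sample(mperm$group)
    tPerm[b] <- fcvGroupCompare(fcvs, mperm)$tMatrix[1, 2]
  }
  pPerm <- mean(abs(tPerm) >= abs(tObs))
  mcErr <- 3 * sqrt(pParam * (1 - pParam) / nPerm) + 0.02
  expect_lt(abs(pPerm - pParam), mcErr + 0.05)
})

test_that("edgewise comparison rejects invalid designs", {
  manifest <- makeManifest(1, 5)
  fcvs <- lapply(1:6, function(s) vectorToMatrix(rep(0.2, 3), 3))
  names(fcvs) <- manifest$subject_id
  expect_error(fcvGroupCompare(fcvs, manifest), "at least 2")

  m2 <- makeManifest(3, 3)
  m2$age <- 50   # constant age collinear with intercept
  fcvs2 <- lapply(1:6, function(s) vectorToMatrix(abs(rnorm(3, 0.3, 0.02)), 3))
  names(fcvs2) <- m2$subject_id
  expect_error(fcvGroupCompare(fcvs2, m2), "collinear")
})

test_that("windowed tensors and dFCV matrices round-trip through disk", {
  dir <- withr::local_tempdir()
  set.seed(12)
  ts <- matrix(rnorm(60 * 5), 60, 5)
  wfc <- slidingFC(ts, 20, 2, "sub-x")
  path <- file.path(dir, "sub-x_tensor.tsv")
  writeWindowedFC(wfc, path)
  back <- readWindowedFC(path)
  expect_identical(windowValues(back), windowValues(wfc))
  expect_identical(windowStarts(back), windowStarts(wfc))
  expect_identical(subjectId(back), "sub-x")

  d <- computeDFCV(wfc, labels = paste0("roi_", 1:5))
  fpath <- file.path(dir, "sub-x_fcv.tsv")
  writeFCVMatrix(d, fpath)
  d2 <- readFCVMatrix(fpath)
  expect_equal(unname(d2), unname(d))
  expect_equal(colnames(d2), paste0("roi_", 1:5))
})
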