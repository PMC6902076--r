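## Signal conditioning for extracted ROI time series. The fixed pipeline
## order is: volume discard -> confound + trend regression -> ideal
## band-pass. Image-space preprocessing (slice timing, realignment,
## normalization, smoothing) is upstream and out of scope.

#' Discard initial volumes
#'
#' @param ts T x R time-series matrix.
#' @param n number of initial time points to drop (0 <= n < T).
#' @return The shortened matrix.
#' @export
discardInitialVolumes <- function(ts, n = 10L) {
  ts <- as.matrix(ts)
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  if (n >= nrow(ts))
    stop("cannot discard ", n, " volumes from a series of length ", nrow(ts))
  if (n == 0L) return(ts)
  ts[-seq_len(n), , drop = FALSE]
}

#' Head-motion exclusion decision
#'
#' A subject is excluded when the maximum absolute translation exceeds
#' `transLimitMm` or the maximum absolute rotation exceeds `rotLimitDeg`
#' (strict inequalities: values exactly at the limit are retained). The
#' per-volume absolute displacements in the motion file are used, not
#' framewise differences.
#'
#' @param motion T x 6 matrix (tx ty tz mm, rx ry rz degrees).
#' @param transLimitMm translation limit in mm (default 2.0).
#' @param rotLimitDeg rotation limit in degrees (default 2.0).
#' @return List with `included` (logical), `maxTrans`, `maxRot`.
#' @export
motionExclusion <- function(motion, transLimitMm = 2.0, rotLimitDeg = 2.0) {
  motion <- as.matrix(motion)
  if (nrow(motion) == 0L) stop("empty motion trace")
  if (ncol(motion) != 6L) stop("motion trace must have 6 columns")
  if (any(!is.finite(motion))) stop("motion trace contains non-finite values")
  maxTrans <- max(abs(motion[, 1:3]))
  maxRot <- max(abs(motion[, 4:6]))
  list(included = !(maxTrans > transLimitMm || maxRot > rotLimitDeg),
       maxTrans = maxTrans, maxRot = maxRot)
}

#' Friston 24-parameter motion regressor set
#'
#' Expands a 6-column rigid-body trace R into the 24 columns
#' `[R, R lagged one step, R^2, lagged R^2]`; lagged columns are
#' zero-padded at the first time point.
#'
#' @param motion T x 6 motion matrix, T >= 2.
#' @return T x 24 regressor matrix.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion trace must have 6 columns")
  T <- nrow(motion)
  if (T < 2L) stop("at least 2 time points required")
  lag <- rbind(matrix(0, 1, 6), motion[-T, , drop = FALSE])
  out <- cbind(motion, lag, motion^2, lag^2)
  colnames(out) <- c(paste0("m", 1:6), paste0("m", 1:6, "_lag"),
                     paste0("m", 1:6, "_sq"), paste0("m", 1:6, "_lagsq"))
  out
}

#' Regress confounds and polynomial trends out of a time series
#'
#' Fits, per ROI, an ordinary least-squares model on an intercept, linear
#' and quadratic trend terms and any supplied confound columns (e.g. the
#' [friston24()] set, or WM/CSF signals when available), and returns the
#' residuals. Residuals are orthogonal to every regressor column.
#'
#' @param ts T x R time-series matrix.
#' @param confounds optional T x q confound matrix.
#' @param polyDegree polynomial trend degree (default 2: linear + quadratic).
#' @return Residual matrix of the same dimension as `ts`.
#' @export
regressConfounds <- function(ts, confounds = NULL, polyDegree = 2L) {
  ts <- as.matrix(ts)
  T <- nrow(ts)
  tt <- seq_len(T)
  X <- cbind(intercept = rep(1, T))
  if (polyDegree >= 1L)
    X <- cbind(X, stats::poly(tt, degree = polyDegree))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != T)
      stop("confound rows (", nrow(confounds), ") do not match T (", T, ")")
    if (is.null(colnames(confounds)))
      colnames(confounds) <- paste0("confound", seq_len(ncol(confounds)))
    X <- cbind(X, confounds)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient regressor matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  ts - X %*% qr.coef(qrX, ts)
}

#' Ideal frequency-domain band-pass filter
#'
#' Retains exactly the discrete Fourier bins whose frequency magnitude lies
#' in `[lowHz, highHz]` and zeroes all others (including DC), i.e. a
#' rectangular ideal filter. The output is real. Applying the filter twice
#' equals applying it once.
#'
#' @param ts T x R time-series matrix.
#' @param trSeconds sampling interval (TR) in seconds.
#' @param lowHz,highHz pass-band edges; requires
#'   `0 < lowHz < highHz < 1/(2 trSeconds)` (Nyquist).
#' @return Filtered matrix of the same dimension.
#' @export
bandpassFilter <- function(ts, trSeconds, lowHz = 0.01, highHz = 0.08) {
  ts <- as.matrix(ts)
  T <- nrow(ts)
  nyquist <- 1 / (2 * trSeconds)
  if (lowHz <= 0) stop("lowHz must be > 0")
  if (highHz <= lowHz) stop("highHz must exceed lowHz")
  if (highHz >= nyquist)
    stop(sprintf("highHz (%g) exceeds Nyquist %g for TR %g s",
                 highHz, nyquist, trSeconds))
  f <- (seq_len(T) - 1) / (T * trSeconds)
  fm <- pmin(f, 1 / trSeconds - f) # two-sided frequency magnitude
  keep <- fm >= lowHz & fm <= highHz
  Fts <- mvfft(ts)
  Fts[!keep, ] <- 0
  out <- Re(mvfft(Fts, inverse = TRUE)) / T
  dimnames(out) <- dimnames(ts)
  out
}

#' Condition one subject's time series
#'
#' Applies the fixed chain: discard initial volumes, regress trends plus the
#' Friston-24 expansion of the (equally shortened) motion trace and any
#' extra confounds, then ideal band-pass.
#'
#' @param ts T x R raw time-series matrix.
#' @param motion optional T x 6 motion trace matching the raw series length.
#' @param trSeconds TR in seconds.
#' @param discard number of initial volumes to drop.
#' @param lowHz,highHz band-pass edges.
#' @param extraConfounds optional additional confound columns (rows must
#'   match the post-discard length).
#' @return Conditioned matrix with `nrow(ts) - discard` rows.
#' @export
prepSubject <- function(ts, motion = NULL, trSeconds = 2, discard = 10L,
                        lowHz = 0.01, highHz = 0.08, extraConfounds = NULL) {
  ts <- discardInitialVolumes(ts, discard)
  confounds <- NULL
  if (!is.null(motion)) {
    motion <- discardInitialVolumes(as.matrix(motion), discard)
    confounds <- friston24(motion)
  }
  if (!is.null(extraConfounds)) confounds <- cbind(confounds, extraConfounds)
  ts <- regressConfounds(ts, confounds)
  bandpassFilter(ts, trSeconds, lowHz, highHz)
}

#' Condition an on-disk cohort
#'
#' Reads every subject in the manifest, applies the motion-exclusion rule,
#' conditions retained subjects with [prepSubject()] and (optionally) writes
#' the conditioned series plus an exclusion report
#' (`subject_id, max_trans, max_rot, included`).
#'
#' @param dir cohort directory as written by [simulateCohort()].
#' @param outDir optional output directory for conditioned TSVs and the
#'   report.
#' @param trSeconds,discard,lowHz,highHz conditioning parameters. The
#'   default `discard = 0` suits simulated cohorts, which are written
#'   post-discard; set `discard = 10` (or as appropriate) for raw series
#'   that still carry their initial volumes.
#' @param transLimitMm,rotLimitDeg motion-exclusion limits.
#' @return List with `signals` (named list of conditioned matrices for the
#'   retained subjects), `report` (data.frame) and `manifest` (retained rows).
#' @export
prepCohort <- function(dir, outDir = NULL, trSeconds = 2, discard = 0L,
                       lowHz = 0.01, highHz = 0.08,
                       transLimitMm = 2.0, rotLimitDeg = 2.0) {
  manifest <- readManifest(file.path(dir, "manifest.tsv"))
  report <- data.frame(subject_id = manifest$subject_id,
                       max_trans = NA_real_, max_rot = NA_real_,
                       included = NA)
  signals <- list()
  for (r in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[r]
    ts <- readTimeseries(file.path(dir, paste0(id, "_timeseries.tsv")))
    motionPath <- file.path(dir, paste0(id, "_motion.txt"))
    motion <- if (file.exists(motionPath)) readMotion(motionPath) else NULL
    if (!is.null(motion)) {
      dec <- motionExclusion(motion, transLimitMm, rotLimitDeg)
      report$max_trans[r] <- dec$maxTrans
      report$max_rot[r] <- dec$maxRot
      report$included[r] <- dec$included
      if (!dec$included) next
    } else {
      report$included[r] <- TRUE
    }
    signals[[id]] <- prepSubject(ts, motion, trSeconds, discard, lowHz, highHz)
  }
  if (!is.null(outDir)) {
    if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
      stop("cannot create output directory: ", outDir)
    for (id in names(signals))
      writeTimeseries(signals[[id]], file.path(outDir, paste0(id, "_conditioned.tsv")))
    write.table(report, file.path(outDir, "exclusion_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(signals = signals, report = report,
       manifest = manifest[manifest$subject_id %in% names(signals), ,
                           drop = FALSE])
}
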