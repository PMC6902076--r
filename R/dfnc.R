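## Sliding-window dynamic functional connectivity: windowed Fisher-z
## tensors, static FC, dFCV matrices and the covariate-adjusted edgewise
## group comparison.

.FISHER_CLAMP <- 1 - 1e-7

#' Fisher r-to-z transform with clamping
#'
#' `z = atanh(clamp(r, +-(1 - 1e-7)))`. The clamp keeps perfectly
#' (anti)correlated edges finite; `inverseFisherZ()` is plain `tanh`.
#'
#' @param r correlation value(s), |r| <= 1.
#' @return Fisher z value(s).
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  atanh(pmin(pmax(r, -.FISHER_CLAMP), .FISHER_CLAMP))
}

#' @rdname fisherZ
#' @param z Fisher z value(s).
#' @export
inverseFisherZ <- function(z) tanh(z)

#' Number of sliding windows
#'
#' `floor((T - w) / step) + 1` windows of length `w` advanced by `step`.
#'
#' @param T series length in TRs.
#' @param w window length in TRs (w <= T).
#' @param step step size in TRs (>= 1).
#' @return Integer window count.
#' @examples
#' windowCount(130, 20, 1) # 111
#' @export
windowCount <- function(T, w, step = 1L) {
  if (w > T) stop("window length (", w, ") exceeds series length (", T, ")")
  if (step < 1L) stop("step must be >= 1")
  as.integer(floor((T - w) / step) + 1)
}

.checkVariance <- function(ts, context = NULL) {
  v <- apply(ts, 2, stats::var)
  bad <- which(v <= 0 | !is.finite(v))
  if (length(bad)) {
    ids <- colnames(ts)
    if (is.null(ids)) ids <- paste0("roi_", seq_len(ncol(ts)))
    where <- if (is.null(context)) "" else paste0(" in ", context)
    stop("zero-variance ROI(s)", where, ": ", paste(ids[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Static functional connectivity
#'
#' Pearson correlation over the whole series.
#'
#' @param ts T x R matrix with T >= 3 and no zero-variance ROI.
#' @return Symmetric R x R correlation matrix with unit diagonal.
#' @export
staticFC <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("at least 3 time points required")
  .checkVariance(ts)
  C <- cor(ts)
  (C + t(C)) / 2
}

#' Sliding-window Fisher-z connectivity tensor
#'
#' Computes Pearson correlations on each rectangular (untapered) window,
#' Fisher z-transforms them and vectorizes along the canonical
#' [edgeIndex()] order.
#'
#' @param ts T x R conditioned time-series matrix.
#' @param window window length in TRs.
#' @param step step size in TRs.
#' @param subjectId identifier stored on the result.
#' @return A [WindowedFC-class] with W x E values.
#' @export
slidingFC <- function(ts, window = 20L, step = 1L, subjectId = "subject") {
  ts <- as.matrix(ts)
  T <- nrow(ts)
  R <- ncol(ts)
  window <- as.integer(window)
  step <- as.integer(step)
  W <- windowCount(T, window, step)
  starts <- seq.int(1L, by = step, length.out = W)
  idx <- edgeIndex(R)

  ## windowed sums via cumulative sums: every window's first and second
  ## moments in one vectorized pass
  cs <- rbind(0, apply(ts, 2, cumsum))               # (T+1) x R
  cs2 <- rbind(0, apply(ts^2, 2, cumsum))            # (T+1) x R
  prod <- ts[, idx[, "i"], drop = FALSE] * ts[, idx[, "j"], drop = FALSE]
  csp <- rbind(0, apply(prod, 2, cumsum))            # (T+1) x E
  ends <- starts + window - 1L

  Sx <- cs[ends + 1L, , drop = FALSE] - cs[starts, , drop = FALSE]   # W x R
  Sxx <- cs2[ends + 1L, , drop = FALSE] - cs2[starts, , drop = FALSE]
  Sxy <- csp[ends + 1L, , drop = FALSE] - csp[starts, , drop = FALSE] # W x E
  varW <- Sxx - Sx^2 / window                        # W x R (x window scale)

  tolV <- 1e-12 * pmax(apply(ts^2, 2, max), 1)
  bad <- which(varW <= rep(tolV, each = W), arr.ind = TRUE)
  if (nrow(bad)) {
    ids <- colnames(ts)
    if (is.null(ids)) ids <- paste0("roi_", seq_len(R))
    stop(sprintf("zero-variance segment (window %d, ROI %s)",
                 bad[1, 1], ids[bad[1, 2]]))
  }

  covW <- Sxy - Sx[, idx[, "i"], drop = FALSE] * Sx[, idx[, "j"], drop = FALSE] / window
  r <- covW / sqrt(varW[, idx[, "i"], drop = FALSE] * varW[, idx[, "j"], drop = FALSE])
  r[r > 1] <- 1   # guard rounding excursions
  r[r < -1] <- -1
  values <- fisherZ(r)

  new("WindowedFC", subjectId = subjectId, values = values,
      window = window, step = step, starts = as.integer(starts))
}

#' Dynamic functional connectivity variability (dFCV) matrix
#'
#' Per edge, the sample standard deviation (denominator W - 1) of the
#' Fisher-z values across all windows, reshaped to a symmetric matrix with
#' zero diagonal.
#'
#' @param wfc a [WindowedFC-class] with at least 2 windows.
#' @param labels optional ROI ids for the dimnames.
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
computeDFCV <- function(wfc, labels = NULL) {
  stopifnot(is(wfc, "WindowedFC"))
  if (nWindows(wfc) < 2L) stop("at least 2 windows required for dFCV")
  sds <- apply(windowValues(wfc), 2, sd)
  vectorToMatrix(sds, diagonal = 0, labels = labels)
}

#' Edgewise covariate-adjusted group comparison of dFCV matrices
#'
#' For every edge fits `value ~ intercept + group + age + sex` by ordinary
#' least squares across subjects and reports the two-sided t statistic and
#' p value of the group coefficient, a sign map (positive = higher in the
#' non-reference group) and the uncorrected significance mask at `alpha`.
#' Following the analysis convention this reproduces, dFCV entries are
#' Fisher z-transformed before testing even though they are standard
#' deviations rather than correlations; entries >= 1 are clamped with a
#' warning.
#'
#' @param fcvs named list of dFCV matrices (one per subject).
#' @param manifest data.frame with `subject_id`, `group`, and the covariate
#'   columns. The group factor's second level is the tested (patient-like)
#'   group; if a level named "control" exists it becomes the reference.
#' @param covariates covariate column names (default age and sex).
#' @param alpha uncorrected edgewise threshold (default 0.005).
#' @param fisherTransform apply atanh to the (clamped) dFCV entries first.
#' @param fdr additionally report a Benjamini-Hochberg adjusted mask.
#' @return List with symmetric matrices `tMatrix`, `pMatrix`, `signMatrix`,
#'   logical `mask`, the model degrees of freedom `df`, `alpha`, and
#'   `nSignificant` (edge count below `alpha`).
#' @export
fcvGroupCompare <- function(fcvs, manifest, covariates = c("age", "sex"),
                            alpha = 0.005, fisherTransform = TRUE,
                            fdr = FALSE) {
  ids <- manifest$subject_id
  if (!all(ids %in% names(fcvs)))
    stop("missing dFCV matrix for subject(s): ",
         paste(setdiff(ids, names(fcvs)), collapse = ", "))
  grp <- factor(manifest$group)
  if (nlevels(grp) != 2L) stop("exactly two groups required")
  if ("control" %in% levels(grp)) grp <- stats::relevel(grp, "control")
  if (min(table(grp)) < 2L) stop("each group needs at least 2 subjects")

  Y <- t(vapply(ids, function(id) matrixToVector(fcvs[[id]]),
                numeric(length(matrixToVector(fcvs[[ids[1]]])))))
  if (fisherTransform) {
    if (any(Y >= 1)) {
      warning("dFCV entries >= 1 clamped before Fisher transform")
    }
    Y <- fisherZ(pmin(Y, .FISHER_CLAMP))
  }

  X <- cbind(intercept = rep(1, nrow(manifest)),
             group = as.numeric(grp) - 1)
  for (cv in covariates) {
    v <- manifest[[cv]]
    if (is.null(v)) stop("covariate column not found: ", cv)
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("collinear design column(s): ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  seGroup <- sqrt(sigma2 * XtXinv["group" == colnames(X), "group" == colnames(X)])
  tvals <- beta["group", ] / seGroup
  pvals <- 2 * pt(-abs(tvals), df)

  N <- nrow(fcvs[[ids[1]]])
  res <- list(
    tMatrix = vectorToMatrix(tvals, N, diagonal = 0),
    pMatrix = vectorToMatrix(pvals, N, diagonal = 1),
    signMatrix = vectorToMatrix(sign(beta["group", ]), N, diagonal = 0),
    mask = vectorToMatrix(as.numeric(pvals < alpha), N, diagonal = 0) > 0,
    df = df, alpha = alpha, nSignificant = sum(pvals < alpha)
  )
  if (fdr) {
    padj <- stats::p.adjust(pvals, method = "BH")
    res$fdrMask <- vectorToMatrix(as.numeric(padj < alpha), N, diagonal = 0) > 0
  }
  res
}
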