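## Sparsity-thresholded binary-graph topology of static connectivity:
## global/local efficiency across a sparsity grid with trapezoidal AUC
## summaries and a two-sample group comparison of the AUCs.

#' Binarize a weighted connectivity matrix at a sparsity threshold
#'
#' Keeps the `round(s * N(N-1)/2)` edges of largest weight (by absolute
#' value by default, since strong negative correlations also carry
#' connections), with deterministic tie-breaking by canonical edge index.
#' `round` is the usual half-to-even rule. Increasing `s` never removes an
#' edge, so grids of thresholds give nested graphs.
#'
#' @param weights symmetric weight matrix (diagonal ignored).
#' @param s sparsity in (0, 1]: target fraction of possible edges.
#' @param mode rank edges by `"absolute"` (default) or `"positive"` weight.
#' @return List with `adjacency` (symmetric 0/1 matrix, zero diagonal),
#'   `sparsity` (achieved fraction) and `nEdges`.
#' @export
binarizeBySparsity <- function(weights, s, mode = c("absolute", "positive")) {
  mode <- match.arg(mode)
  if (s <= 0 || s > 1) stop("sparsity must lie in (0, 1]")
  w <- matrixToVector(weights)
  nPairs <- length(w)
  m <- round(s * nPairs)
  if (m < 1) stop("sparsity ", s, " yields zero edges")
  key <- if (mode == "absolute") abs(w) else w
  ord <- order(-key, seq_along(w))
  sel <- ord[seq_len(m)]
  v <- numeric(nPairs)
  v[sel] <- 1
  list(adjacency = vectorToMatrix(v, nrow(weights), diagonal = 0),
       sparsity = m / nPairs, nEdges = as.integer(m))
}

.shortestPaths <- function(adjacency) {
  g <- igraph::graph_from_adjacency_matrix(adjacency != 0, mode = "undirected",
                                           diag = FALSE)
  igraph::distances(g, algorithm = "unweighted")
}

#' Global efficiency of a binary graph
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' disconnected pairs contributing 0. Paths are unweighted (breadth-first).
#'
#' @param adjacency symmetric 0/1 adjacency matrix, N >= 2.
#' @return Efficiency in `[0, 1]`.
#' @examples
#' globalEfficiency(matrix(1, 4, 4) - diag(4)) # complete K4: 1
#' @export
globalEfficiency <- function(adjacency) {
  N <- nrow(adjacency)
  if (N < 2L) stop("at least 2 nodes required")
  d <- .shortestPaths(adjacency)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (N * (N - 1))
}

#' Local efficiency of a binary graph
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors; nodes with fewer than 2 neighbors contribute 0.
#'
#' @param adjacency symmetric 0/1 adjacency matrix, N >= 2.
#' @return Efficiency in `[0, 1]`.
#' @export
localEfficiency <- function(adjacency) {
  N <- nrow(adjacency)
  if (N < 2L) stop("at least 2 nodes required")
  vals <- vapply(seq_len(N), function(i) {
    nb <- which(adjacency[i, ] != 0)
    nb <- setdiff(nb, i)
    if (length(nb) < 2L) return(0)
    globalEfficiency(adjacency[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Trapezoidal area under a metric-versus-sparsity curve
#'
#' @param x ascending grid.
#' @param y metric values at the grid points.
#' @return The trapezoidal integral in sparsity units.
#' @export
aucTrapz <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.unsorted(x, strictly = TRUE)) stop("grid must be strictly ascending")
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Efficiency curve of one subject across the sparsity grid
#'
#' Thresholds the weight matrix (typically the Fisher-z static FC) at every
#' grid point and computes global and local efficiency of the resulting
#' nested binary graphs, plus the trapezoidal AUC of each curve.
#'
#' @param weights symmetric weight matrix.
#' @param grid ascending sparsity grid (default 0.01 to 0.50 by 0.01).
#' @param subjectId identifier stored on the curve.
#' @param mode edge-ranking mode, see [binarizeBySparsity()].
#' @return An [EfficiencyCurve-class].
#' @export
efficiencyCurve <- function(weights, grid = seq(0.01, 0.50, by = 0.01),
                            subjectId = "subject",
                            mode = c("absolute", "positive")) {
  mode <- match.arg(mode)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly ascending")
  eg <- el <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    b <- binarizeBySparsity(weights, grid[gi], mode)
    eg[gi] <- globalEfficiency(b$adjacency)
    el[gi] <- localEfficiency(b$adjacency)
  }
  new("EfficiencyCurve", subjectId = subjectId, sparsity = grid,
      eGlobal = eg, eLocal = el,
      aucGlobal = aucTrapz(grid, eg), aucLocal = aucTrapz(grid, el))
}

#' Group comparison of efficiency AUCs
#'
#' Two-sample pooled-variance t tests of the global- and local-efficiency
#' AUC values between the two groups, with per-group "mean (SD)" summaries.
#'
#' @param curves named list of [EfficiencyCurve-class] objects by subject.
#' @param manifest data.frame with `subject_id` and `group`.
#' @return data.frame with one row per metric: group summaries, `t`, `df`,
#'   `p`.
#' @export
efficiencyGroupCompare <- function(curves, manifest) {
  ids <- manifest$subject_id
  if (!all(ids %in% names(curves)))
    stop("missing efficiency curve for subject(s): ",
         paste(setdiff(ids, names(curves)), collapse = ", "))
  grp <- factor(manifest$group)
  if (nlevels(grp) != 2L) stop("exactly two groups required")
  if ("control" %in% levels(grp)) grp <- stats::relevel(grp, "control")
  gref <- levels(grp)[1]; gtest <- levels(grp)[2]
  auc <- data.frame(
    global = vapply(ids, function(id) aucGlobal(curves[[id]]), numeric(1)),
    local = vapply(ids, function(id) aucLocal(curves[[id]]), numeric(1))
  )
  rows <- lapply(c("global", "local"), function(metric) {
    x <- auc[[metric]][grp == gtest]
    y <- auc[[metric]][grp == gref]
    if (sd(x) == 0 && sd(y) == 0) stop("zero variance in both groups for ", metric)
    tt <- t.test(x, y, var.equal = TRUE)
    data.frame(metric = paste0(metric, "_efficiency_auc"),
               summary_test = sprintf("%.4g (%.3g)", mean(x), sd(x)),
               summary_ref = sprintf("%.4g (%.3g)", mean(y), sd(y)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- c(paste0(gtest, "_mean_sd"), paste0(gref, "_mean_sd"))
  out
}
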