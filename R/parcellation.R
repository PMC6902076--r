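#' Load a parcellation table
#'
#' Reads a tab-separated parcellation with columns `roi_id`, `x`, `y`, `z`
#' (MNI mm) and `network`. Row order defines the canonical ROI order used by
#' every matrix/vector conversion. A census of network sizes is reported via
#' `message()`.
#'
#' @param path path to the TSV file.
#' @param quiet suppress the network census message.
#' @return A [Parcellation-class] object.
#' @examples
#' tsv <- system.file("extdata", "parcellation_264_synthetic.tsv",
#'                    package = "dynconn")
#' p <- loadParcellation(tsv, quiet = TRUE)
#' nROIs(p)
#' @export
loadParcellation <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("parcellation file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  required <- c("roi_id", "x", "y", "z", "network")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("parcellation is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (cc in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(is.na(v)))
      stop("non-numeric coordinate in column '", cc, "'")
    df[[cc]] <- v
  }
  ids <- as.character(df$roi_id)
  if (anyDuplicated(ids))
    stop("duplicate roi_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  p <- new("Parcellation",
           roiId = ids,
           coords = cbind(x = df$x, y = df$y, z = df$z),
           network = as.character(df$network),
           excluded = character(0))
  if (!quiet) {
    cen <- networkCensus(p)
    message(sprintf("Loaded %d ROIs in %d networks: %s", nROIs(p), length(cen),
                    paste(sprintf("%s=%d", names(cen), as.integer(cen)),
                          collapse = ", ")))
  }
  p
}

#' Build a parcellation from vectors
#'
#' Programmatic constructor, mostly useful for simulations and tests.
#'
#' @param roiId,network character vectors of equal length.
#' @param coords optional numeric matrix of MNI coordinates (defaults to 0).
#' @return A [Parcellation-class].
#' @export
makeParcellation <- function(roiId, network, coords = NULL) {
  n <- length(roiId)
  if (is.null(coords)) coords <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  new("Parcellation", roiId = as.character(roiId), coords = coords,
      network = as.character(network), excluded = character(0))
}

#' Remove whole networks from a parcellation
#'
#' Drops every ROI whose network label is in `names`, preserving the relative
#' order of the remaining rows, and records the excluded set on the returned
#' object.
#'
#' @param parcellation a [Parcellation-class].
#' @param names character vector of network names to remove; every name must
#'   be present in the table. An empty vector returns the table unchanged.
#' @return A [Parcellation-class] with the listed networks removed.
#' @export
excludeNetworks <- function(parcellation, names) {
  stopifnot(is(parcellation, "Parcellation"))
  names <- as.character(names)
  if (!length(names)) return(parcellation)
  present <- unique(parcellation@network)
  unknown <- setdiff(names, present)
  if (length(unknown))
    stop("unknown network name(s): ", paste(unknown, collapse = ", "))
  keep <- !(parcellation@network %in% names)
  if (!any(keep)) stop("excluding all networks would leave an empty parcellation")
  new("Parcellation",
      roiId = parcellation@roiId[keep],
      coords = parcellation@coords[keep, , drop = FALSE],
      network = parcellation@network[keep],
      excluded = sort(unique(c(parcellation@excluded, names))))
}

#' Canonical edge index for an N-node undirected network
#'
#' Enumerates all unordered ROI pairs (i, j) with i < j in lexicographic
#' order. This is the column order of every windows-by-edges matrix in the
#' package and equals the column-major lower triangle of a symmetric matrix.
#'
#' @param N number of ROIs (>= 2).
#' @return Integer matrix with columns `i`, `j` and N(N-1)/2 rows (1-based).
#' @examples
#' edgeIndex(4)
#' @export
edgeIndex <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("N must be an integer >= 2")
  ## i column: 1 repeated N-1 times, 2 repeated N-2 times, ...
  i <- rep.int(seq_len(N - 1L), (N - 1L):1L)
  j <- unlist(lapply(seq_len(N - 1L), function(a) (a + 1L):N), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Vectorize a symmetric matrix along the canonical edge order
#'
#' @param M symmetric N x N matrix (asymmetry beyond `tol` is an error).
#' @param tol symmetry tolerance.
#' @return Numeric vector of length N(N-1)/2 in [edgeIndex()] order.
#' @export
matrixToVector <- function(M, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("M must be a square matrix")
  if (max(abs(M - t(M))) > tol) stop("M is not symmetric within tolerance ", tol)
  ## column-major lower triangle == lexicographic (i, j), i < j
  M[lower.tri(M)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [matrixToVector()] off the diagonal.
#'
#' @param v edge vector of length N(N-1)/2.
#' @param N number of ROIs; inferred from `length(v)` when missing.
#' @param diagonal value placed on the diagonal (default 0).
#' @param labels optional dimnames (ROI ids).
#' @return Symmetric N x N matrix.
#' @export
vectorToMatrix <- function(v, N = NULL, diagonal = 0, labels = NULL) {
  if (is.null(N)) {
    N <- (1 + sqrt(1 + 8 * length(v))) / 2
    if (abs(N - round(N)) > 1e-9)
      stop("vector length ", length(v), " is not N(N-1)/2 for integer N")
    N <- as.integer(round(N))
  }
  N <- as.integer(N)
  if (length(v) != N * (N - 1L) / 2L)
    stop("wrong vector length: expected ", N * (N - 1L) / 2L, ", got ", length(v))
  M <- matrix(0, N, N)
  M[lower.tri(M)] <- v
  M <- M + t(M)
  diag(M) <- diagonal
  if (!is.null(labels)) dimnames(M) <- list(labels, labels)
  M
}

## edge -> network-pair bookkeeping used by dFCV summaries and simulations
.edgeNetworks <- function(parcellation) {
  idx <- edgeIndex(nROIs(parcellation))
  net <- networkLabels(parcellation)
  data.frame(i = idx[, "i"], j = idx[, "j"],
             net_i = net[idx[, "i"]], net_j = net[idx[, "j"]],
             within = net[idx[, "i"]] == net[idx[, "j"]],
             stringsAsFactors = FALSE)
}
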