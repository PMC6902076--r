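## Central S4 containers. Validity methods encode the structural invariants
## that every downstream stage relies on.

#' Parcellation: ROI identities, coordinates and network membership
#'
#' Holds the ROI table that defines the canonical node order for every
#' matrix/vector conversion in the package. Row order is meaningful and is
#' preserved by all operations.
#'
#' @slot roiId character vector of unique ROI identifiers.
#' @slot coords numeric matrix with one row per ROI and columns x, y, z
#'   (MNI millimetres).
#' @slot network character vector of network labels, one per ROI.
#' @slot excluded character vector of network names that were removed by
#'   [excludeNetworks()] (empty for a freshly loaded table).
#'
#' @seealso [loadParcellation()], [excludeNetworks()], [edgeIndex()]
#' @export
setClass("Parcellation",
  slots = c(
    roiId = "character",
    coords = "matrix",
    network = "character",
    excluded = "character"
  )
)

setValidity("Parcellation", function(object) {
  n <- length(object@roiId)
  if (n == 0L) return("parcellation must contain at least one ROI")
  if (anyDuplicated(object@roiId)) return("roi_id values must be unique")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    return("coords must be a numeric matrix with columns x, y, z")
  if (nrow(object@coords) != n) return("coords rows must match roiId length")
  if (any(!is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@network) != n) return("network labels must match roiId length")
  if (any(is.na(object@network) | !nzchar(object@network)))
    return("network labels must be non-empty strings")
  TRUE
})

#' StateCovariance: ground-truth covariance of one connectivity state
#'
#' A unit-diagonal, positive semi-definite correlation-scale matrix used by
#' the cohort simulator as the latent covariance of one connectivity state.
#'
#' @slot stateId integer state identifier (1-based).
#' @slot matrix symmetric R x R correlation matrix.
#' @slot description free-text description of the pattern.
#' @export
setClass("StateCovariance",
  slots = c(stateId = "integer", matrix = "matrix", description = "character")
)

setValidity("StateCovariance", function(object) {
  M <- object@matrix
  if (nrow(M) != ncol(M)) return("matrix must be square")
  if (max(abs(M - t(M))) > 1e-8) return("matrix must be symmetric")
  if (max(abs(diag(M) - 1)) > 1e-8) return("matrix must have unit diagonal")
  off <- M[lower.tri(M)]
  if (any(off < -1 - 1e-8 | off > 1 + 1e-8))
    return("off-diagonal entries must lie in [-1, 1]")
  ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) return(sprintf("matrix is not PSD (min eigenvalue %.3g)", ev))
  TRUE
})

#' CohortDesign: parameters of a simulated two-group cohort
#'
#' @slot nPerGroup integer vector of length 2, subjects per group.
#' @slot groups character vector of length 2 with the group labels; the
#'   first is treated as the patient-like group, the second as control.
#' @slot R number of ROIs.
#' @slot T time points per subject (after any volume discard).
#' @slot TR sampling interval in seconds.
#' @slot stayProb named list with one entry per group: probability of
#'   remaining in the current state per step, either a scalar (shared by all
#'   states) or one value per state.
#' @slot initialStateProb simplex vector over states.
#' @slot noiseSd observation noise scale (added i.i.d. per ROI and time point).
#' @slot jitterSd scale of the per-subject Gaussian perturbation applied to
#'   the off-diagonals of each state covariance before PSD repair.
#' @slot patterns list of per-state pattern specifications passed to
#'   [buildStateCovariances()]; may instead carry one such list per group
#'   (named by group) for group-specific state patterns.
#' @slot seed integer base seed; subject s uses seed + s deterministically.
#' @export
setClass("CohortDesign",
  slots = c(
    nPerGroup = "integer", groups = "character",
    R = "integer", T = "integer", TR = "numeric",
    stayProb = "list", initialStateProb = "numeric",
    noiseSd = "numeric", jitterSd = "numeric",
    patterns = "list", seed = "integer"
  )
)

setValidity("CohortDesign", function(object) {
  if (length(object@nPerGroup) != 2L || any(object@nPerGroup < 1L))
    return("nPerGroup must be two counts >= 1")
  if (length(object@groups) != 2L || anyDuplicated(object@groups))
    return("groups must be two distinct labels")
  if (!identical(sort(names(object@stayProb)), sort(object@groups)))
    return("stayProb must be a list named by the two groups")
  for (g in object@groups) {
    p <- object@stayProb[[g]]
    if (any(p <= 0 | p >= 1)) return("stay probabilities must lie in (0, 1)")
  }
  if (abs(sum(object@initialStateProb) - 1) > 1e-8 ||
      any(object@initialStateProb < 0))
    return("initialStateProb must be a simplex vector")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@jitterSd < 0) return("jitterSd must be >= 0")
  if (object@T < 1L) return("T must be >= 1")
  if (object@R < 2L) return("R must be >= 2")
  TRUE
})

#' WindowedFC: sliding-window Fisher-z connectivity tensor of one subject
#'
#' Rows are windows, columns are edges in the canonical [edgeIndex()] order;
#' entries are Fisher z-transformed Pearson correlations of the rectangular
#' window.
#'
#' @slot subjectId subject identifier.
#' @slot values W x E numeric matrix of Fisher-z edge weights.
#' @slot window window length in TRs.
#' @slot step step size in TRs.
#' @slot starts integer vector of 1-based window start indices (length W).
#' @export
setClass("WindowedFC",
  slots = c(
    subjectId = "character", values = "matrix",
    window = "integer", step = "integer", starts = "integer"
  )
)

setValidity("WindowedFC", function(object) {
  if (nrow(object@values) != length(object@starts))
    return("one start index per window required")
  if (any(!is.finite(object@values))) return("all Fisher-z values must be finite")
  if (object@window < 2L) return("window length must be >= 2")
  if (object@step < 1L) return("step must be >= 1")
  ## back-converted correlations must be strictly inside (-1, 1)
  if (max(abs(tanh(range(object@values)))) >= 1)
    return("tanh(z) must lie in (-1, 1)")
  TRUE
})

#' StateModel: k-means decomposition of pooled windowed connectivity
#'
#' @slot k number of states.
#' @slot centroids k x E matrix; each row is the arithmetic mean of the
#'   window vectors assigned to that state.
#' @slot labels named list of per-subject label sequences (integer vectors).
#' @slot objective final clustering objective: sum over windows of the
#'   correlation distance to the assigned centroid.
#' @slot validity data.frame of cluster-validity indices by k (possibly
#'   empty when the model was fit for a single k).
#' @slot distance distance metric used ("correlation").
#' @export
setClass("StateModel",
  slots = c(
    k = "integer", centroids = "matrix", labels = "list",
    objective = "numeric", validity = "data.frame", distance = "character"
  )
)

setValidity("StateModel", function(object) {
  if (nrow(object@centroids) != object@k)
    return("centroids must have k rows")
  labs <- unlist(object@labels, use.names = FALSE)
  if (length(labs) && (min(labs) < 1L || max(labs) > object@k))
    return("labels must lie in 1..k")
  TRUE
})

#' EfficiencyCurve: graph efficiency of one subject across a sparsity grid
#'
#' @slot subjectId subject identifier.
#' @slot sparsity ascending grid of sparsity thresholds.
#' @slot eGlobal global efficiency at each grid point.
#' @slot eLocal local efficiency at each grid point.
#' @slot aucGlobal trapezoidal AUC of the global-efficiency curve.
#' @slot aucLocal trapezoidal AUC of the local-efficiency curve.
#' @export
setClass("EfficiencyCurve",
  slots = c(
    subjectId = "character", sparsity = "numeric",
    eGlobal = "numeric", eLocal = "numeric",
    aucGlobal = "numeric", aucLocal = "numeric"
  )
)

setValidity("EfficiencyCurve", function(object) {
  m <- length(object@sparsity)
  if (length(object@eGlobal) != m || length(object@eLocal) != m)
    return("one efficiency value per grid point required")
  if (is.unsorted(object@sparsity, strictly = TRUE))
    return("sparsity grid must be strictly ascending")
  if (any(object@eGlobal < -1e-12 | object@eGlobal > 1 + 1e-12) ||
      any(object@eLocal < -1e-12 | object@eLocal > 1 + 1e-12))
    return("efficiencies must lie in [0, 1]")
  TRUE
})
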