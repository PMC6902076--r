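#' @name accessors
#' @title Accessors for dynconn classes
#' @description Small accessor generics; prefer these to direct slot access.
#' @param x an object of the appropriate class.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("nROIs", function(x) standardGeneric("nROIs"))

#' @rdname accessors
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' @rdname accessors
#' @export
setGeneric("networkLabels", function(x) standardGeneric("networkLabels"))

#' @rdname accessors
#' @export
setGeneric("networkCensus", function(x) standardGeneric("networkCensus"))

#' @rdname accessors
#' @export
setGeneric("excludedNetworks", function(x) standardGeneric("excludedNetworks"))

#' @rdname accessors
#' @export
setGeneric("windowValues", function(x) standardGeneric("windowValues"))

#' @rdname accessors
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))

#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname accessors
#' @export
setGeneric("validityTable", function(x) standardGeneric("validityTable"))

#' @rdname accessors
#' @export
setGeneric("clusterObjective", function(x) standardGeneric("clusterObjective"))

#' @rdname accessors
#' @export
setGeneric("sparsityGrid", function(x) standardGeneric("sparsityGrid"))

#' @rdname accessors
#' @export
setGeneric("aucGlobal", function(x) standardGeneric("aucGlobal"))

#' @rdname accessors
#' @export
setGeneric("aucLocal", function(x) standardGeneric("aucLocal"))

setMethod("nROIs", "Parcellation", function(x) length(x@roiId))
setMethod("roiIds", "Parcellation", function(x) x@roiId)
setMethod("networkLabels", "Parcellation", function(x) x@network)
setMethod("networkCensus", "Parcellation", function(x) table(x@network))
setMethod("excludedNetworks", "Parcellation", function(x) x@excluded)

setMethod("windowValues", "WindowedFC", function(x) x@values)
setMethod("windowStarts", "WindowedFC", function(x) x@starts)
setMethod("nWindows", "WindowedFC", function(x) nrow(x@values))
setMethod("subjectId", "WindowedFC", function(x) x@subjectId)

setMethod("centroids", "StateModel", function(x) x@centroids)
setMethod("stateLabels", "StateModel", function(x) x@labels)
setMethod("validityTable", "StateModel", function(x) x@validity)
setMethod("clusterObjective", "StateModel", function(x) x@objective)

setMethod("sparsityGrid", "EfficiencyCurve", function(x) x@sparsity)
setMethod("aucGlobal", "EfficiencyCurve", function(x) x@aucGlobal)
setMethod("aucLocal", "EfficiencyCurve", function(x) x@aucLocal)
setMethod("subjectId", "EfficiencyCurve", function(x) x@subjectId)

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d ROIs, %d networks",
              nROIs(object), length(unique(object@network))))
  if (length(object@excluded))
    cat(sprintf(" (excluded: %s)", paste(object@excluded, collapse = ", ")))
  cat("\n")
  cen <- networkCensus(object)
  cat(paste(sprintf("%s=%d", names(cen), as.integer(cen)), collapse = ", "),
      "\n")
})

setMethod("show", "StateCovariance", function(object) {
  cat(sprintf("StateCovariance (state %d, %dx%d): %s\n", object@stateId,
              nrow(object@matrix), ncol(object@matrix), object@description))
})

setMethod("show", "CohortDesign", function(object) {
  cat(sprintf("CohortDesign: %s n=%d vs %s n=%d, R=%d, T=%d, TR=%gs\n",
              object@groups[1], object@nPerGroup[1],
              object@groups[2], object@nPerGroup[2],
              object@R, object@T, object@TR))
})

setMethod("show", "WindowedFC", function(object) {
  cat(sprintf("WindowedFC [%s]: %d windows x %d edges (w=%d TR, step=%d TR)\n",
              object@subjectId, nrow(object@values), ncol(object@values),
              object@window, object@step))
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel: k=%d, %d subjects, %d pooled windows, objective %.4f\n",
              object@k, length(object@labels),
              sum(lengths(object@labels)), object@objective))
})

setMethod("show", "EfficiencyCurve", function(object) {
  cat(sprintf(
    "EfficiencyCurve [%s]: grid %g..%g (%d points), AUC global %.4f local %.4f\n",
    object@subjectId, min(object@sparsity), max(object@sparsity),
    length(object@sparsity), object@aucGlobal, object@aucLocal))
})
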