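#' @name wgfc-accessors
#' @title Accessors for wgfc S4 classes
#' @description Read-only accessors for the slots of the package's S4
#'   containers; user code should use these rather than \code{@}.
#' @param object an object of the documented class.
#' @return The corresponding slot value.
NULL

#' @rdname wgfc-accessors
#' @export
setGeneric("tsData", function(object) standardGeneric("tsData"))
#' @rdname wgfc-accessors
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))
#' @rdname wgfc-accessors
#' @export
setGeneric("compartments", function(object) standardGeneric("compartments"))
#' @rdname wgfc-accessors
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))
#' @rdname wgfc-accessors
#' @export
setGeneric("nTimepoints", function(object) standardGeneric("nTimepoints"))
#' @rdname wgfc-accessors
#' @export
setGeneric("nRois", function(object) standardGeneric("nRois"))
#' @rdname wgfc-accessors
#' @export
setGeneric("fcValues", function(object) standardGeneric("fcValues"))
#' @rdname wgfc-accessors
#' @export
setGeneric("fcKind", function(object) standardGeneric("fcKind"))
#' @rdname wgfc-accessors
#' @export
setGeneric("edgeIndex", function(object) standardGeneric("edgeIndex"))
#' @rdname wgfc-accessors
#' @export
setGeneric("nWindows", function(object) standardGeneric("nWindows"))
#' @rdname wgfc-accessors
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))
#' @rdname wgfc-accessors
#' @export
setGeneric("metrics", function(object) standardGeneric("metrics"))
#' @rdname wgfc-accessors
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))
#' @rdname wgfc-accessors
#' @export
setGeneric("rocCurve", function(object) standardGeneric("rocCurve"))

setMethod("tsData", "RoiTimeSeriesSet", function(object) object@data)
setMethod("roiLabels", "RoiTimeSeriesSet", function(object) object@roiLabels)
setMethod("compartments", "RoiTimeSeriesSet",
          function(object) object@compartment)
setMethod("trSeconds", "RoiTimeSeriesSet", function(object) object@trSeconds)
setMethod("nTimepoints", "RoiTimeSeriesSet",
          function(object) nrow(object@data))
setMethod("nRois", "RoiTimeSeriesSet", function(object) ncol(object@data))

setMethod("fcValues", "FCMatrix", function(object) object@values)
setMethod("fcKind", "FCMatrix", function(object) object@kind)
setMethod("roiLabels", "FCMatrix",
          function(object) list(row = object@rowLabels,
                                col = object@colLabels))

setMethod("fcValues", "DynamicFCSeries", function(object) object@values)
setMethod("edgeIndex", "DynamicFCSeries", function(object) object@edgeIndex)
setMethod("nWindows", "DynamicFCSeries", function(object) ncol(object@values))

setMethod("edgeIndex", "EdgeStats", function(object) object@edgeIndex)
setMethod("edgeTable", "EdgeStats", function(object) {
  tab <- data.frame(t = object@t, p = object@p, q = object@q,
                    selected = object@selected)
  if (nrow(object@edgeIndex)) tab <- cbind(object@edgeIndex, tab)
  tab
})

setMethod("metrics", "ClassificationResult", function(object) object@metrics)
setMethod("confusion", "ClassificationResult",
          function(object) object@confusion)
setMethod("rocCurve", "ClassificationResult", function(object) object@roc)

#' Subset a time-series set to one compartment
#'
#' @param object a [RoiTimeSeriesSet-class].
#' @param compartment \code{"WM"} or \code{"GM"}.
#' @return A [RoiTimeSeriesSet-class] with only the requested ROIs.
#' @export
setGeneric("compartmentSubset",
           function(object, compartment) standardGeneric("compartmentSubset"))

setMethod("compartmentSubset", "RoiTimeSeriesSet",
  function(object, compartment) {
    compartment <- match.arg(compartment, .COMPARTMENTS)
    keep <- object@compartment == compartment
    if (!any(keep))
      stop("no ROIs in compartment '", compartment, "'")
    RoiTimeSeriesSet(object@data[, keep, drop = FALSE],
                     roiLabels = object@roiLabels[keep],
                     compartment = object@compartment[keep],
                     trSeconds = object@trSeconds)
  })

setMethod("show", "RoiTimeSeriesSet", function(object) {
  cat("RoiTimeSeriesSet:", nrow(object@data), "timepoints x",
      ncol(object@data), "ROIs (",
      sum(object@compartment == "WM"), "WM /",
      sum(object@compartment == "GM"), "GM ), TR =",
      object@trSeconds, "s\n")
})

setMethod("show", "FCMatrix", function(object) {
  cat("FCMatrix [", object@kind, "]: ", nrow(object@values), " x ",
      ncol(object@values),
      if (object@symmetric) " (symmetric)" else " (rectangular)", "\n",
      sep = "")
})

setMethod("show", "DynamicFCSeries", function(object) {
  cat("DynamicFCSeries:", nrow(object@values), "edges x",
      ncol(object@values), "windows (length", object@windowLength,
      ", step", paste0(object@step, ")"), "\n")
  if (object@degenerateWindows > 0L)
    cat("  degenerate (zero-variance) windows set to 0:",
        object@degenerateWindows, "\n")
})

setMethod("show", "EdgeStats", function(object) {
  cat("EdgeStats:", length(object@t), "edges;")
  if (!is.na(object@alpha))
    cat(" selected", sum(object@selected), "at p <=", object@alpha)
  cat("\n")
})

setMethod("show", "ClassificationResult", function(object) {
  m <- object@metrics
  cat(sprintf(
    "ClassificationResult (%s protocol): ACC %.2f%% SEN %.2f%% SPE %.2f%% AUC %.4f F %.2f\n",
    object@protocol, m["acc"], m["sen"], m["spe"], m["auc"], m["fscore"]))
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", 2L * object@nPerGroup, "subjects (",
      object@nPerGroup, "per group ),", object@nWm, "WM +", object@nGm,
      "GM ROIs,", object@nTimepoints, "timepoints @ TR",
      object@trSeconds, "s\n")
  cat("  static effect:", nrow(object@staticEffectEdges), "edges, delta",
      object@staticEffectDelta, "; dynamic effect:",
      nrow(object@dynamicEffectEdges), "edges, amplitude",
      object@dynamicEffectDelta, "\n")
})
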