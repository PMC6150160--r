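## Accessor generics. Slots are never reached into directly by user code.

#' @name topiQuant-accessors
#' @title Accessors for topiQuant result objects
#' @description Small accessor generics exposing the slots of the package's
#'   S4 result classes.
#' @param object a topiQuant S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname topiQuant-accessors
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("constants", function(object) standardGeneric("constants"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("rSquaredValue", function(object) standardGeneric("rSquaredValue"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("fitResiduals", function(object) standardGeneric("fitResiduals"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("bestModel", function(object) standardGeneric("bestModel"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("modelFits", function(object) standardGeneric("modelFits"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("releaseTimes", function(object) standardGeneric("releaseTimes"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("releasedFraction",
           function(object) standardGeneric("releasedFraction"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("profileLabel", function(object) standardGeneric("profileLabel"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("fluxJ", function(object) standardGeneric("fluxJ"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("steadyStateSlope",
           function(object) standardGeneric("steadyStateSlope"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("lagTime", function(object) standardGeneric("lagTime"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("permeability", function(object) standardGeneric("permeability"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("dabChannel", function(object) standardGeneric("dabChannel"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("hematoxylinChannel",
           function(object) standardGeneric("hematoxylinChannel"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("zoneCounts", function(object) standardGeneric("zoneCounts"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("globalScore", function(object) standardGeneric("globalScore"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("partialScores", function(object) standardGeneric("partialScores"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("euPerPixel", function(object) standardGeneric("euPerPixel"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("correctedEU", function(object) standardGeneric("correctedEU"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("groupValues", function(object) standardGeneric("groupValues"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname topiQuant-accessors
#' @export
setGeneric("significanceCategory",
           function(object) standardGeneric("significanceCategory"))

#' @rdname topiQuant-accessors
setMethod("modelId", "KineticFit", function(object) object@model)
#' @rdname topiQuant-accessors
setMethod("constants", "KineticFit", function(object) object@constants)
#' @rdname topiQuant-accessors
setMethod("rSquaredValue", "KineticFit", function(object) object@rSquared)
#' @rdname topiQuant-accessors
setMethod("fitResiduals", "KineticFit", function(object) object@residuals)
#' @rdname topiQuant-accessors
setMethod("bestModel", "ModelSelection", function(object) object@best)
#' @rdname topiQuant-accessors
setMethod("modelFits", "ModelSelection", function(object) object@fits)
#' @rdname topiQuant-accessors
setMethod("releaseTimes", "DissolutionProfile", function(object) object@times)
#' @rdname topiQuant-accessors
setMethod("releasedFraction", "DissolutionProfile",
          function(object) object@released)
#' @rdname topiQuant-accessors
setMethod("profileLabel", "DissolutionProfile", function(object) object@label)
#' @rdname topiQuant-accessors
setMethod("releaseTimes", "PermeationSeries", function(object) object@times)
#' @rdname topiQuant-accessors
setMethod("fluxJ", "PermeationResult", function(object) object@fluxJ)
#' @rdname topiQuant-accessors
setMethod("steadyStateSlope", "PermeationResult", function(object) object@jss)
#' @rdname topiQuant-accessors
setMethod("lagTime", "PermeationResult", function(object) object@lagTime)
#' @rdname topiQuant-accessors
setMethod("permeability", "PermeationResult", function(object) object@kp)
#' @rdname topiQuant-accessors
setMethod("dabChannel", "StainChannels", function(object) object@dab)
#' @rdname topiQuant-accessors
setMethod("hematoxylinChannel", "StainChannels",
          function(object) object@hematoxylin)
#' @rdname topiQuant-accessors
setMethod("zoneCounts", "ZoneHistogram", function(object) object@counts)
#' @rdname topiQuant-accessors
setMethod("globalScore", "IhcScore", function(object) object@globalScore)
#' @rdname topiQuant-accessors
setMethod("partialScores", "IhcScore", function(object) object@partialScores)
#' @rdname topiQuant-accessors
setMethod("euPerPixel", "EnergyMeasure", function(object) object@euPerPixel)
#' @rdname topiQuant-accessors
setMethod("correctedEU", "EnergyMeasure", function(object) object@corrected)
#' @rdname topiQuant-accessors
setMethod("groupLabel", "GroupMeasurements", function(object) object@label)
#' @rdname topiQuant-accessors
setMethod("groupValues", "GroupMeasurements", function(object) object@values)
#' @rdname topiQuant-accessors
setMethod("pValue", "PairwiseComparison", function(object) object@pValue)
#' @rdname topiQuant-accessors
setMethod("significanceCategory", "PairwiseComparison",
          function(object) object@category)

## ---- show methods ---------------------------------------------------------

setMethod("show", "DissolutionProfile", function(object) {
  cat(sprintf("DissolutionProfile '%s': %d points over %.3g-%.3g h, final release %.2f%%\n",
              object@label, length(object@times),
              min(object@times), max(object@times),
              100 * utils::tail(object@released, 1)))
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit [%s]  R² = %.4f\n", object@model, object@rSquared))
  cat("  ", paste(sprintf("%s = %.6g", names(object@constants),
                          object@constants), collapse = ", "), "\n", sep = "")
})

setMethod("show", "ModelSelection", function(object) {
  cat("ModelSelection (criterion:", object@criterion, ")\n")
  for (f in object@fits) {
    mark <- if (f@model == object@best) " <- best" else ""
    cat(sprintf("  %-18s R² = %.4f%s\n", f@model, f@rSquared, mark))
  }
})

setMethod("show", "PermeationResult", function(object) {
  if (object@flagged) {
    cat("PermeationResult: flagged (non-positive steady-state slope)\n")
  } else {
    cat(sprintf("PermeationResult: Jss = %.4g ug/cm^2/h, J = %.4g ug/h, lag = %.3g h, Kp = %.4g cm/h\n",
                object@jss, object@fluxJ, object@lagTime, object@kp))
  }
})

setMethod("show", "RgbImage", function(object) {
  d <- dim(object)
  cat(sprintf("RgbImage: %d x %d pixels, 8-bit RGB\n", d[1], d[2]))
})

setMethod("show", "StainChannels", function(object) {
  d <- dim(object@dab)
  cat(sprintf("StainChannels: %d x %d (DAB / hematoxylin / complementary)\n",
              d[1], d[2]))
})

setMethod("show", "ZoneHistogram", function(object) {
  cat("ZoneHistogram (", object@total, "masked pixels )\n")
  print(object@counts)
})

setMethod("show", "IhcScore", function(object) {
  cat(sprintf("IhcScore: global = %.4f over %d included pixels\n",
              object@globalScore, object@includedTotal))
})

setMethod("show", "EnergyMeasure", function(object) {
  cat(sprintf("EnergyMeasure (%s): sample %.4g, control %.4g, corrected %.4g EU/pixel%s\n",
              object@mode, object@euPerPixel, object@controlEuPerPixel,
              object@corrected, if (object@clamped) " [clamped]" else ""))
})

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf("GroupSummary: mean %.4g, SD %.4g, SE %.4g (n = %d)\n",
              object@mean, object@sd, object@se, object@n))
})

setMethod("show", "PairwiseComparison", function(object) {
  cat(sprintf("Welch comparison: t = %.4g, df = %.3g, p = %.4g -> %s%s\n",
              object@tStatistic, object@df, object@pValue, object@category,
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "ComparisonMatrix", function(object) {
  cat("ComparisonMatrix (pairwise Welch t-tests)\n")
  m <- object@categories
  dimnames(m) <- list(object@labels, object@labels)
  print(m, quote = FALSE)
})
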