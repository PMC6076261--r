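# Accessors and show methods for the package classes.

#' @describeIn LabeledField-class channel role names present in the field
#' @param x,object a `LabeledField`
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @export
setMethod("channelNames", "LabeledField", function(x) names(x@channels))

#' @describeIn LabeledField-class extract one channel matrix by role
#' @param role channel role string
#' @export
setGeneric("getChannel", function(x, role) standardGeneric("getChannel"))

#' @export
setMethod("getChannel", "LabeledField", function(x, role) {
  if (!role %in% names(x@channels))
    stop("channel '", role, "' not present in field (has: ",
         paste(names(x@channels), collapse = ", "), ")")
  x@channels[[role]]
})

#' @describeIn LabeledField-class image dimensions (rows, cols)
#' @export
setGeneric("fieldDim", function(x) standardGeneric("fieldDim"))

#' @export
setMethod("fieldDim", "LabeledField", function(x) dim(x@channels[[1]]))

#' @export
setMethod("show", "LabeledField", function(object) {
  d <- fieldDim(object)
  cat("LabeledField:", d[1], "x", d[2], "px,",
      length(object@channels), "channel(s):",
      paste(names(object@channels), collapse = ", "), "\n")
  if (!is.na(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

#' @describeIn FieldTruth-class simulated cell table
#' @param x,object a `FieldTruth`
#' @export
setGeneric("truthCells", function(x) standardGeneric("truthCells"))

#' @export
setMethod("truthCells", "FieldTruth", function(x) x@cells)

#' @describeIn FieldTruth-class simulated punctum table
#' @export
setGeneric("truthPuncta", function(x) standardGeneric("truthPuncta"))

#' @export
setMethod("truthPuncta", "FieldTruth", function(x) x@puncta)

#' @export
setMethod("show", "FieldTruth", function(object) {
  cat("FieldTruth:", nrow(object@cells), "cells,",
      nrow(object@puncta), "puncta (seed", object@seed, ")\n")
})

#' @describeIn SimulatedAssay-class assay design/value table
#' @param x,object a `SimulatedAssay`
#' @export
setGeneric("assayData", function(x) standardGeneric("assayData"))

#' @export
setMethod("assayData", "SimulatedAssay", function(x) x@data)

#' @describeIn SimulatedAssay-class true generating parameters
#' @export
setGeneric("trueParams", function(x) standardGeneric("trueParams"))

#' @export
setMethod("trueParams", "SimulatedAssay", function(x) x@truth)

#' @export
setMethod("show", "SimulatedAssay", function(object) {
  cat("SimulatedAssay '", object@model, "': ", nrow(object@data),
      " rows (seed ", object@seed, ")\n", sep = "")
  cat("  truth:", paste(names(object@truth),
      vapply(object@truth, function(v) format(v, digits = 4), ""),
      sep = "=", collapse = ", "), "\n")
})

#' @describeIn FitResult-class named parameter estimates
#' @param object a `FitResult`
#' @export
setMethod("coef", "FitResult", function(object, ...) object@estimates)

#' @describeIn FitResult-class 95% confidence intervals (rows lower/upper)
#' @export
setMethod("confint", "FitResult",
          function(object, parm, level = 0.95, ...) object@ci)

#' @describeIn FitResult-class convergence status
#' @param x a `FitResult`
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @export
setMethod("isConverged", "FitResult", function(x) x@converged)

#' @describeIn FitResult-class data-quality flags (empty when clean)
#' @export
setGeneric("fitFlags", function(x) standardGeneric("fitFlags"))

#' @export
setMethod("fitFlags", "FitResult", function(x) x@flags)

#' @export
setMethod("show", "FitResult", function(object) {
  cat("FitResult [", object@model, "]",
      if (!object@converged) " (NOT converged)", "\n", sep = "")
  est <- object@estimates
  for (p in names(est)) {
    cat(sprintf("  %-8s %.6g", p, est[[p]]))
    lo <- object@ci["lower", p]; hi <- object@ci["upper", p]
    if (!is.na(lo) || !is.na(hi))
      cat(sprintf("  [%.6g, %.6g]", lo, hi))
    cat("\n")
  }
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @export
setMethod("show", "FieldSummary", function(object) {
  cat("FieldSummary:", object@nCells, "cells (", object@nLive, "live /",
      object@nDead, "dead )\n")
  cat(sprintf("  frac live cells with >= %d puncta: %s\n", object@minPuncta,
      format(object@fracPositive, digits = 4)))
  if (!is.na(object@normalizedValue))
    cat("  normalized to control:",
        format(object@normalizedValue, digits = 4), "\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @export
setMethod("show", "FluxSummary", function(object) {
  cat("FluxSummary:", object@nCellsAnalyzed, "cells analyzed,",
      object@nCellsExcluded, "excluded (no yellow puncta)\n")
  cat(sprintf("  mean red:yellow ratio %s +/- %s (SEM); pooled %s\n",
      format(object@meanRatio, digits = 4),
      format(object@semRatio, digits = 4),
      format(object@pooledRatio, digits = 4)))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @export
setMethod("show", "LtrResult", function(object) {
  cat("LtrResult: metric", format(object@metric, digits = 4),
      "( meanGray", format(object@meanGray, digits = 4),
      "- background", format(object@backgroundMean, digits = 4),
      ") /", object@nNuclei, "nuclei\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @export
setMethod("show", "PkSummary", function(object) {
  cat(sprintf(
    "PkSummary: Cmax %.4g at Tmax %.3g h; AUC(0-t) %.4g (dose %.4g mg/kg)\n",
    object@cmax, object@tmax, object@auc, object@dose))
})
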