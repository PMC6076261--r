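#' @import methods
NULL

VALID_CHANNEL_ROLES <- c("nuclear", "viability", "gfp", "red", "green", "ltr")

#' Multi-channel fluorescence field
#'
#' Container for a single imaged field: a named list of same-sized intensity
#' matrices, one per channel role. Intensities are arbitrary fluorescence
#' units, finite and non-negative. Pixel coordinates throughout the package
#' are 1-based `(row, col)`.
#'
#' @slot channels named list of numeric matrices; names are channel roles
#'   from `"nuclear"`, `"viability"`, `"gfp"`, `"red"`, `"green"`, `"ltr"`.
#' @slot provenance character scalar recording where the field came from
#'   (a file path or a generator description).
#' @export
setClass("LabeledField",
  representation(channels = "list", provenance = "character"),
  prototype(channels = list(), provenance = NA_character_)
)

setValidity("LabeledField", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("field has no channels")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named by role")
  bad <- setdiff(names(ch), VALID_CHANNEL_ROLES)
  if (length(bad))
    return(paste0("unknown channel role(s): ", paste(bad, collapse = ", ")))
  dims <- vapply(ch, function(m) {
    if (!is.matrix(m) || !is.numeric(m)) return(c(NA_integer_, NA_integer_))
    dim(m)
  }, integer(2))
  if (anyNA(dims)) return("all channels must be numeric matrices")
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all channels must share identical dimensions")
  for (m in ch) {
    if (!all(is.finite(m))) return("channel intensities must be finite")
    if (any(m < 0)) return("channel intensities must be >= 0")
  }
  TRUE
})

#' Construct a LabeledField
#'
#' @param channels named list of numeric matrices (one per channel role).
#' @param provenance optional character tag.
#' @return a [LabeledField-class] object.
#' @examples
#' f <- LabeledField(list(gfp = matrix(0, 8, 8)))
#' fieldDim(f)
#' @export
LabeledField <- function(channels, provenance = NA_character_) {
  new("LabeledField", channels = channels, provenance = provenance)
}

#' Ground truth for a simulated field
#'
#' @slot cells data.frame with one row per simulated cell: `row`, `col`
#'   (center), `nucleusRadius`, `cellRadius`, `dead` (logical),
#'   `viabilityOverlap` (fraction of the cell disc painted with viability
#'   stain; 0 for live cells), `brightness` (per-cell lognormal factor).
#' @slot puncta data.frame with one row per simulated punctum: `row`, `col`,
#'   `radius`, `cell` (owning cell index), `class` (`"green"`, `"red_only"`
#'   or `"yellow"`).
#' @slot seed integer seed used by the generator.
#' @export
setClass("FieldTruth",
  representation(cells = "data.frame", puncta = "data.frame",
                 seed = "integer"),
  prototype(cells = data.frame(), puncta = data.frame(), seed = NA_integer_)
)

setValidity("FieldTruth", function(object) {
  p <- object@puncta
  if (nrow(p)) {
    if (!all(p$cell >= 1 & p$cell <= nrow(object@cells)))
      return("punctum owner index out of range")
  }
  TRUE
})

#' Simulated assay table with ground truth
#'
#' @slot model model name (e.g. `"fourPL"`, `"michaelis_menten_uncompetitive"`).
#' @slot data data.frame of design points and values; truth rows carry
#'   `is_truth = TRUE` and `replicate = 0`.
#' @slot truth named list of the true generating parameters.
#' @slot seed integer seed.
#' @export
setClass("SimulatedAssay",
  representation(model = "character", data = "data.frame", truth = "list",
                 seed = "integer")
)

#' Nonlinear/linear model fit result
#'
#' Common return type of the enzymology fitters: point estimates, 95%
#' confidence intervals, convergence status and residual diagnostics.
#'
#' @slot model model name.
#' @slot estimates named numeric vector of parameter estimates.
#' @slot ci numeric matrix with rows `lower`/`upper`, one column per
#'   parameter (all `NA` when no CI was requested or computable).
#' @slot converged logical.
#' @slot flags character vector of data-quality flags (e.g.
#'   `"no_dose_effect"`), empty when clean.
#' @slot residuals numeric residuals of the fit.
#' @slot nobs number of observations used.
#' @slot details list of auxiliary results (model-specific).
#' @export
setClass("FitResult",
  representation(model = "character", estimates = "numeric", ci = "matrix",
                 converged = "logical", flags = "character",
                 residuals = "numeric", nobs = "integer", details = "list"),
  prototype(flags = character(0), details = list())
)

setValidity("FitResult", function(object) {
  est <- object@estimates
  ci <- object@ci
  if (length(est) && ncol(ci)) {
    common <- intersect(names(est), colnames(ci))
    for (p in common) {
      lo <- ci["lower", p]; hi <- ci["upper", p]
      if (!is.na(lo) && !is.na(hi) && !is.na(est[[p]]) &&
          (est[[p]] < lo - 1e-8 || est[[p]] > hi + 1e-8))
        return(paste0("CI for ", p, " does not contain the point estimate"))
    }
  }
  TRUE
})

newFitResult <- function(model, estimates, ci = NULL, converged = TRUE,
                         flags = character(0), residuals = numeric(0),
                         nobs = length(residuals), details = list()) {
  if (is.null(ci)) {
    ci <- matrix(NA_real_, 2, length(estimates),
                 dimnames = list(c("lower", "upper"), names(estimates)))
  }
  new("FitResult", model = model, estimates = estimates, ci = ci,
      converged = converged, flags = flags, residuals = as.numeric(residuals),
      nobs = as.integer(nobs), details = details)
}

#' Per-field high-content screening summary
#'
#' @slot nCells,nLive,nDead cell counts.
#' @slot punctaPerLiveCell integer vector of puncta counts over live cells.
#' @slot minPuncta threshold used for the positivity endpoint (comparator
#'   is `>=`).
#' @slot fracPositive fraction of live cells with at least `minPuncta`
#'   puncta; `NA` when no live cells (see `flags`).
#' @slot normalizedValue `fracPositive` divided by the mean control
#'   fraction; `NA` when no controls were supplied.
#' @slot flags character; contains `"no_live_cells"` when undefined.
#' @export
setClass("FieldSummary",
  representation(nCells = "integer", nLive = "integer", nDead = "integer",
                 punctaPerLiveCell = "integer", minPuncta = "integer",
                 fracPositive = "numeric", normalizedValue = "numeric",
                 flags = "character"),
  prototype(flags = character(0), normalizedValue = NA_real_)
)

#' Tandem-reporter flux summary
#'
#' @slot perCell data.frame: `cell`, `nRedOnly`, `nYellow`, `ratio` (`NA`
#'   for cells with no yellow puncta).
#' @slot meanRatio,semRatio mean and SEM of the per-cell ratio over cells
#'   with at least one yellow punctum.
#' @slot pooledRatio total red-only / total yellow puncta (`Inf` flagged
#'   when no yellow puncta at all).
#' @slot nCellsAnalyzed number of cells entering the per-cell statistics.
#' @slot nCellsExcluded cells with zero yellow puncta (excluded from the
#'   mean but reported).
#' @slot flags character, e.g. `"no_yellow_puncta"`, `"few_cells"`.
#' @export
setClass("FluxSummary",
  representation(perCell = "data.frame", meanRatio = "numeric",
                 semRatio = "numeric", pooledRatio = "numeric",
                 nCellsAnalyzed = "integer", nCellsExcluded = "integer",
                 flags = "character"),
  prototype(flags = character(0))
)

#' Lysotracker per-image intensity metric
#'
#' @slot meanGray mean intensity of the whole (unadjusted) dye channel.
#' @slot backgroundMean mean intensity over the cell-free background mask.
#' @slot nNuclei nuclei counted on the nuclear channel.
#' @slot metric `(meanGray - backgroundMean) / nNuclei`; `NA` when no nuclei.
#' @slot normalizedToControl metric divided by a control metric (`NA` if no
#'   control given).
#' @slot flags character, e.g. `"no_nuclei"`.
#' @export
setClass("LtrResult",
  representation(meanGray = "numeric", backgroundMean = "numeric",
                 nNuclei = "integer", metric = "numeric",
                 normalizedToControl = "numeric", flags = "character"),
  prototype(normalizedToControl = NA_real_, flags = character(0))
)

#' Noncompartmental pharmacokinetic summary
#'
#' @slot cmax maximum observed plasma concentration (same units as input).
#' @slot tmax time of `cmax` (h).
#' @slot auc area under the concentration-time curve from 0 to the last
#'   sample, linear trapezoid.
#' @slot dose administered dose (mg/kg).
#' @slot aucPerDose,cmaxPerDose dose-normalized metrics.
#' @export
setClass("PkSummary",
  representation(cmax = "numeric", tmax = "numeric", auc = "numeric",
                 dose = "numeric", aucPerDose = "numeric",
                 cmaxPerDose = "numeric")
)
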