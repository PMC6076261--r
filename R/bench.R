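# Western-blot densitometry normalization, the bafilomycin-additivity
# flux-block statistic, and noncompartmental pharmacokinetic summaries.
# Band quantification from gel images is out of scope: these start from
# numeric band densities.

#' Normalize a band to loading control and vehicle controls
#'
#' `rel = (band / loading) / mean(controlBand / controlLoading)`: each
#' lane is first corrected by its loading control (actin/vinculin), then
#' expressed relative to the mean corrected control (DMSO) lane. The
#' result is invariant to rescaling all intensities by a common factor.
#'
#' @param band target band intensity (e.g. LC3B-II), vectorized.
#' @param loading loading-control intensity for the same lane(s) (> 0).
#' @param controlBand,controlLoading intensities of the control lanes
#'   (nonempty, loading > 0).
#' @return relative level(s).
#' @examples
#' normalizeBand(300, 100, controlBand = c(150, 150),
#'               controlLoading = c(100, 100))  # 2.0
#' @export
normalizeBand <- function(band, loading, controlBand, controlLoading) {
  if (!length(controlBand)) stop("control lanes must be nonempty")
  if (any(loading <= 0) || any(controlLoading <= 0))
    stop("zero or negative loading-control intensity")
  (band / loading) / mean(controlBand / controlLoading)
}

#' Bafilomycin-additivity ratio and flux-block call
#'
#' For relative levels measured under vehicle, vehicle + Baf A1, drug and
#' drug + Baf A1, the additivity ratio is
#' `R = mean(drugBaf - drug) / mean(vehicleBaf - vehicle)`.
#' A drug that blocks autophagic flux at or upstream of the lysosome
#' leaves nothing for Baf A1 to add (`R ~ 0`), while a drug that acts
#' elsewhere leaves the full Baf increment (`R ~ 1`). The flux-block call
#' is `R <= threshold` (inclusive; the default 0.25 is an operational
#' cutoff, configurable). `R` is invariant to a common affine
#' renormalization of the levels. Replicate-level inference is delegated
#' to a generic paired t-test of `drugBaf` vs `drug` when replicate
#' vectors of equal length >= 2 are given.
#'
#' @param vehicle,vehicleBaf,drug,drugBaf relative levels (replicate
#'   vectors or scalars).
#' @param threshold flux-block call threshold on `R`.
#' @param nboot bootstrap resamples for the CI of `R` (resampling
#'   replicates within each condition); skipped when any condition has a
#'   single replicate.
#' @param seed bootstrap seed.
#' @return list with `R`, `fluxBlocked`, `ci` (length-2 or `NULL`),
#'   `pPaired` (or `NA`), `flags`.
#' @export
bafAdditivity <- function(vehicle, vehicleBaf, drug, drugBaf,
                          threshold = 0.25, nboot = 1000L, seed = NULL) {
  vInc <- mean(vehicleBaf) - mean(vehicle)
  flags <- character(0)
  if (vInc <= 0) {
    return(list(R = NA_real_, fluxBlocked = NA, ci = NULL,
                pPaired = NA_real_,
                flags = "vehicle_increment_nonpositive"))
  }
  R <- (mean(drugBaf) - mean(drug)) / vInc
  ci <- NULL
  if (min(lengths(list(vehicle, vehicleBaf, drug, drugBaf))) >= 2) {
    calcR <- function(v, vb, d, db) (mean(db) - mean(d)) / (mean(vb) - mean(v))
    boot <- function() {
      rs <- function(x) sample(x, length(x), replace = TRUE)
      r <- calcR(rs(vehicle), rs(vehicleBaf), rs(drug), rs(drugBaf))
      if (is.finite(r)) r else NA_real_
    }
    draws <- if (is.null(seed)) replicate(nboot, boot()) else
      withSeed(seed, replicate(nboot, boot()))
    draws <- draws[is.finite(draws)]
    if (length(draws) >= nboot / 2)
      ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  }
  pPaired <- if (length(drug) == length(drugBaf) && length(drug) >= 2) {
    stats::t.test(drugBaf, drug, paired = TRUE)$p.value
  } else NA_real_
  # inclusive boundary, guarded against floating-point dust
  list(R = R, fluxBlocked = R <= threshold + 1e-9, ci = ci,
       pPaired = pPaired, flags = flags)
}

#' Noncompartmental pharmacokinetic summary
#'
#' `Cmax`/`Tmax` from the observed points and `AUC(0-t)` by the linear
#' trapezoid rule (no extrapolation to infinity, no log-linear tail).
#'
#' @param times sampling times (h), starting at 0, strictly increasing,
#'   >= 3 points.
#' @param conc plasma concentrations (>= 0; any consistent unit).
#' @param dose administered dose (mg/kg).
#' @return a [PkSummary-class].
#' @export
pkSummary <- function(times, conc, dose) {
  if (length(times) < 3) stop("need >= 3 timepoints")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  imax <- which.max(conc)
  n <- length(times)
  auc <- sum(diff(times) * (conc[-1] + conc[-n]) / 2)
  new("PkSummary", cmax = conc[imax], tmax = times[imax], auc = auc,
      dose = dose, aucPerDose = auc / dose, cmaxPerDose = conc[imax] / dose)
}

#' Dose-proportionality ratio between two PK profiles
#'
#' `(AUC2 / dose2) / (AUC1 / dose1)`: 1 under exact dose proportionality.
#'
#' @param pk1,pk2 [PkSummary-class] objects.
#' @export
doseProportionality <- function(pk1, pk2) {
  pk2@aucPerDose / pk1@aucPerDose
}
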