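# Closed-form assay models. Concentration units are whatever the caller
# uses, as long as they are consistent within one call (the generators and
# fitters work in uM for concentrations and M/s for rates).

#' Four-parameter logistic (4PL) dose-response
#'
#' `response = bottom + (top - bottom) / (1 + (conc / ic50)^h)`. With
#' `h > 0` the response runs from `top` at low dose to `bottom` at high
#' dose; an activating curve is obtained by swapping `top` and `bottom`.
#' At `conc = ic50` the response is exactly `(top + bottom) / 2`.
#'
#' @param conc dose(s), same units as `ic50`.
#' @param top,bottom asymptotes (response units).
#' @param ic50 half-maximal concentration.
#' @param h Hill slope.
#' @export
fourPL <- function(conc, top, bottom, ic50, h) {
  bottom + (top - bottom) / (1 + (conc / ic50)^h)
}

#' Michaelis-Menten rate with optional inhibition term
#'
#' Plain Michaelis-Menten `v = Vmax * S / (KM + S)` and its classical
#' single-inhibitor extensions:
#' * `uncompetitive`: `v = Vmax * S / (KM + S * (1 + I/Ki))` — both apparent
#'   `Vmax` and `KM` shrink by `1/(1 + I/Ki)`;
#' * `competitive`: `v = Vmax * S / (KM * (1 + I/Ki) + S)`;
#' * `noncompetitive`: `v = Vmax / (1 + I/Ki) * S / (KM + S)`.
#'
#' @param S substrate concentration(s).
#' @param Vmax maximal rate.
#' @param KM Michaelis constant (same units as `S`).
#' @param I inhibitor concentration (same units as `Ki`); default 0.
#' @param Ki inhibition constant; `Inf` disables inhibition.
#' @param mode inhibition mode.
#' @export
michaelisMentenRate <- function(S, Vmax, KM, I = 0, Ki = Inf,
                                mode = c("uncompetitive", "competitive",
                                         "noncompetitive", "none")) {
  mode <- match.arg(mode)
  a <- if (is.infinite(Ki)) 1 else 1 + I / Ki
  switch(mode,
    none          = Vmax * S / (KM + S),
    uncompetitive = Vmax * S / (KM + S * a),
    competitive   = Vmax * S / (KM * a + S),
    noncompetitive = (Vmax / a) * S / (KM + S)
  )
}

#' Depletion-corrected 1:1 binding isotherm
#'
#' Fraction of protein bound at total ligand `L` and total protein `P0`,
#' from the exact quadratic solution of `P + L <-> PL`:
#' `fb = (L + P0 + KD - sqrt((L + P0 + KD)^2 - 4 L P0)) / (2 P0)`.
#' For `P0 << KD` this reduces to the hyperbola `L / (L + KD)`.
#'
#' @param L total ligand concentration(s).
#' @param P0 total protein concentration (> 0).
#' @param KD dissociation constant.
#' @export
fractionBound <- function(L, P0, KD) {
  s <- L + P0 + KD
  (s - sqrt(pmax(s^2 - 4 * L * P0, 0))) / (2 * P0)
}

#' One-compartment oral (first-order absorption) plasma concentration
#'
#' `C(t) = dose * ka / (VF * (ka - ke)) * (exp(-ke t) - exp(-ka t))`,
#' with `dose` in mg/kg and `VF` the apparent volume of distribution
#' (V/F) in L/kg, giving mg/L; multiplied by `1000 / mw` to report uM.
#' The analytic time of peak is `ln(ka/ke) / (ka - ke)` and the total
#' exposure is `AUC(0-Inf) = dose / (VF * ke)` (in mg.h/L before the
#' molar conversion).
#'
#' @param t time(s) after dosing, hours.
#' @param dose oral dose, mg/kg.
#' @param ka,ke first-order absorption and elimination constants, 1/h
#'   (`ka != ke`).
#' @param VF apparent volume of distribution, L/kg.
#' @param mw molar mass in g/mol used to convert mg/L to uM; use `NULL`
#'   to keep mg/L.
#' @export
pkOralConcentration <- function(t, dose, ka, ke, VF, mw = 425) {
  if (ka == ke) stop("ka must differ from ke in the two-exponential form")
  conc <- dose * ka / (VF * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
  if (!is.null(mw)) conc <- conc * 1000 / mw
  conc
}

#' Convert between micromolar and molar
#'
#' Round-trip-safe unit helpers used at all CSV boundaries (tables store
#' concentrations in uM, enzymology rates in M/s).
#'
#' @param x numeric concentration(s).
#' @export
uM2M <- function(x) x * 1e-6

#' @rdname uM2M
#' @export
M2uM <- function(x) x * 1e6
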