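# Protease-assay analytics: standard curves and initial rates, 4PL IC50,
# Michaelis-Menten kinetics, inhibition-mode diagnosis and global
# uncompetitive Ki, the mass-spectrometry cleavage statistic, and the
# depletion-corrected binding KD. Nonlinear fits use minpack.lm::nlsLM
# (Levenberg-Marquardt); confidence intervals are seeded residual
# bootstraps (percentile) with an asymptotic Wald alternative.

# residual-bootstrap percentile CI around a fitted model.
# refit(yStar) must return a named estimate vector or NULL on failure.
# When the fitted values are bounded away from zero (assay rates,
# fluorescence signals) the resampling is multiplicative — relative
# residuals resid/fitted are resampled — matching the proportional error
# structure of such data; otherwise plain additive residual resampling.
bootstrapCI <- function(fitted, resid, refit, nboot = 1000L, seed = NULL,
                        level = 0.95) {
  if (!is.null(seed)) {
    out <- withSeed(seed, bootstrapCI(fitted, resid, refit, nboot, NULL,
                                      level))
    return(out)
  }
  relative <- all(fitted > 0) && min(fitted) > 0.02 * max(fitted)
  rel <- if (relative) resid / fitted
  draws <- lapply(seq_len(nboot), function(b) {
    y <- if (relative)
      fitted * (1 + sample(rel, length(rel), replace = TRUE))
    else fitted + sample(resid, length(resid), replace = TRUE)
    refit(y)
  })
  draws <- draws[!vapply(draws, is.null, logical(1))]
  if (length(draws) < max(20L, nboot %/% 10L)) return(NULL)
  M <- do.call(rbind, draws)
  a <- (1 - level) / 2
  ci <- apply(M, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  rownames(ci) <- c("lower", "upper")
  ci
}

waldCI <- function(fit, level = 0.95) {
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, length(est)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- rbind(lower = est - z * se, upper = est + z * se)
  colnames(ci) <- names(est)
  ci
}

# widen a CI minimally so it contains the point estimate (a percentile
# bootstrap can, rarely, exclude it by a hair)
containEstimate <- function(ci, est) {
  if (is.null(ci)) return(NULL)
  for (p in intersect(colnames(ci), names(est))) {
    ci["lower", p] <- min(ci["lower", p], est[[p]], na.rm = TRUE)
    ci["upper", p] <- max(ci["upper", p], est[[p]], na.rm = TRUE)
  }
  ci
}

applyCImethod <- function(fit, est, refit, ciMethod, nboot, seed) {
  ci <- switch(ciMethod,
    none = NULL,
    wald = waldCI(fit),
    bootstrap = bootstrapCI(stats::fitted(fit), stats::residuals(fit),
                            refit, nboot = nboot, seed = seed))
  containEstimate(ci, est)
}

#' Fit a fluorescence standard curve
#'
#' Ordinary least-squares line `RFU = m * conc + b` used to convert raw
#' fluorescence rates to molar product rates. The inverse mapping is
#' available through [rfuToConc()].
#'
#' @param conc known product concentrations (M), at least 2 distinct.
#' @param rfu measured fluorescence at those concentrations.
#' @return a [FitResult-class] with estimates `slope` (RFU per M) and
#'   `intercept` (RFU); `details` holds `r2` and `residSD`; flag
#'   `"nonpositive_slope"` when `m <= 0`.
#' @export
fitStandardCurve <- function(conc, rfu) {
  if (length(unique(conc)) < 2)
    stop("singular design: need >= 2 distinct concentrations")
  fit <- stats::lm(rfu ~ conc)
  est <- c(slope = unname(stats::coef(fit)[2]),
           intercept = unname(stats::coef(fit)[1]))
  s <- suppressWarnings(summary(fit))  # exact lines warn "perfect fit"
  flags <- if (est[["slope"]] <= 0) "nonpositive_slope" else character(0)
  ci <- suppressWarnings(waldCI(fit))[, c(2, 1)]
  colnames(ci) <- c("slope", "intercept")
  newFitResult("standard_curve", est, ci = containEstimate(ci, est),
               converged = TRUE, flags = flags,
               residuals = stats::residuals(fit), nobs = length(rfu),
               details = list(r2 = s$r.squared, residSD = s$sigma))
}

#' @rdname fitStandardCurve
#' @param std a standard-curve [FitResult-class].
#' @param rfu fluorescence value(s) to invert to concentration (M).
#' @export
rfuToConc <- function(std, rfu) {
  (rfu - std@estimates[["intercept"]]) / std@estimates[["slope"]]
}

#' Initial rate from a progress curve
#'
#' OLS slope of signal vs time over the initial window in which the
#' estimated product stays below `maxFractionConsumed` of the starting
#' substrate (at least 3 points), converted from RFU/s to M/s with the
#' standard curve.
#'
#' @param times seconds, strictly increasing, >= 3 points.
#' @param rfu fluorescence readings.
#' @param std standard-curve [FitResult-class] from [fitStandardCurve()].
#' @param S0 starting substrate concentration (M).
#' @param maxFractionConsumed consumption cap defining the linear window.
#' @return rate in M/s, with attribute `window` (indices used).
#' @export
initialRate <- function(times, rfu, std, S0,
                        maxFractionConsumed = 0.1) {
  if (length(times) < 3 || any(diff(times) <= 0))
    stop("need >= 3 strictly increasing timepoints")
  product <- rfuToConc(std, rfu) - rfuToConc(std, rfu[1])
  over <- which(product >= maxFractionConsumed * S0)
  last <- if (length(over)) max(over[1] - 1L, 0L) else length(times)
  if (last < 3) {
    if (length(over) && over[1] <= 3)
      last <- 3L  # cap hit immediately: use the minimum window
    else stop("fewer than 3 usable points before the consumption cap")
  }
  w <- seq_len(last)
  slope <- unname(stats::coef(stats::lm(rfu[w] ~ times[w]))[2])
  if (is.na(slope)) slope <- 0
  structure(slope / std@estimates[["slope"]], window = w)
}

# Levenberg-Marquardt fit with deterministic retry: starts sitting exactly
# on the optimum of noiseless data can trip nls's singular-gradient check,
# so failed attempts are retried from slightly scaled starts.
safeNlsLM <- function(formula, data, start, lower = NULL) {
  for (fac in c(1, 1.05, 0.9, 1.2)) {
    st <- lapply(start, function(x) if (x == 0) 0.01 * (fac - 1) else x * fac)
    args <- list(formula, data = data, start = st,
                 control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(lower)) {
      args$lower <- lower
      args$start <- st <- Map(function(x, lo) max(x, lo), st,
                              as.list(lower)[seq_along(st)])
    }
    fit <- tryCatch(suppressWarnings(do.call(minpack.lm::nlsLM, args)),
                    error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  NULL
}

#' Fit a 4PL dose-response curve (IC50)
#'
#' Nonlinear least squares of [fourPL()] with data-driven starts (top and
#' bottom from the response quartiles, IC50 from the dose nearest the
#' half-response, Hill slope 1). Both inhibition and activation curves fit
#' (top and bottom are free). Flat data are flagged `"no_dose_effect"`
#' with no IC50 emitted; non-convergence is flagged, never silent.
#'
#' @param dose concentrations (> 0), >= 4 distinct values.
#' @param response measured responses (same length).
#' @param ciMethod `"bootstrap"` (residual, percentile), `"wald"`, or
#'   `"none"`.
#' @param nboot bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @return [FitResult-class] with estimates `top`, `bottom`, `ic50`, `h`.
#' @export
fitIC50 <- function(dose, response, ciMethod = c("bootstrap", "wald", "none"),
                    nboot = 1000L, seed = NULL) {
  ciMethod <- match.arg(ciMethod)
  if (length(unique(dose)) < 4)
    stop("need >= 4 distinct doses")
  if (any(dose <= 0)) stop("doses must be > 0")
  mu <- tapply(response, dose, mean)
  if (diff(range(mu)) <= 1e-10 * max(1, abs(mean(response)))) {
    est <- c(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
             h = NA_real_)
    return(newFitResult("fourPL", est, converged = FALSE,
                        flags = "no_dose_effect",
                        residuals = response - mean(response),
                        nobs = length(response)))
  }
  d <- sort(unique(dose))
  half <- (max(mu) + min(mu)) / 2
  ic0 <- d[which.min(abs(mu[as.character(d)] - half))]
  start <- list(top = mu[[as.character(d[1])]],
                bottom = mu[[as.character(d[length(d)])]],
                ic50 = ic0, h = 1)
  dat <- data.frame(dose = dose, response = response)
  fit <- safeNlsLM(response ~ fourPL(dose, top, bottom, ic50, h), dat, start,
                   lower = c(-Inf, -Inf, min(dose) * 1e-6, 1e-3))
  if (is.null(fit)) {
    est <- unlist(start)
    return(newFitResult("fourPL", est, converged = FALSE,
                        flags = "not_converged", nobs = length(response)))
  }
  est <- stats::coef(fit)
  refit <- function(y) {
    f <- safeNlsLM(y ~ fourPL(dose, top, bottom, ic50, h),
                   data.frame(dose = dose, y = y), as.list(est),
                   lower = c(-Inf, -Inf, min(dose) * 1e-6, 1e-3))
    if (is.null(f)) NULL else stats::coef(f)
  }
  newFitResult("fourPL", est,
               ci = applyCImethod(fit, est, refit, ciMethod, nboot, seed),
               converged = TRUE, residuals = stats::residuals(fit),
               nobs = length(response))
}

#' Fit the Michaelis-Menten model
#'
#' Least squares of `v = Vmax * S / (KM + S)`; start values from the
#' Hanes-Woolf linearization (`S/v` vs `S`), which keeps convergence
#' honest across the dynamic range of rates.
#'
#' @param S substrate concentrations (>= 3 distinct).
#' @param v rates.
#' @param ciMethod,nboot,seed as in [fitIC50()].
#' @return [FitResult-class] with estimates `Vmax`, `KM`; negative
#'   estimates are prevented by bounds and flagged if at the boundary.
#' @export
fitMichaelisMenten <- function(S, v, ciMethod = c("none", "bootstrap",
                                                  "wald"),
                               nboot = 1000L, seed = NULL) {
  ciMethod <- match.arg(ciMethod)
  if (length(unique(S)) < 3) stop("need >= 3 distinct substrate levels")
  hw <- tryCatch(stats::lm(I(S / v) ~ S), error = function(e) NULL)
  start <- if (!is.null(hw) && stats::coef(hw)[2] > 0 &&
               stats::coef(hw)[1] > 0) {
    list(Vmax = 1 / unname(stats::coef(hw)[2]),
         KM = unname(stats::coef(hw)[1] / stats::coef(hw)[2]))
  } else list(Vmax = max(v) * 1.2, KM = stats::median(S))
  dat <- data.frame(S = S, v = v)
  lower <- c(max(v) * 1e-9, min(S[S > 0]) * 1e-9)
  fit <- safeNlsLM(v ~ Vmax * S / (KM + S), dat, start, lower = lower)
  if (is.null(fit))
    return(newFitResult("michaelis_menten", unlist(start),
                        converged = FALSE, flags = "not_converged",
                        nobs = length(v)))
  est <- stats::coef(fit)
  flags <- if (any(est <= lower * 1.01)) "boundary_estimate" else character(0)
  refit <- function(y) {
    f <- safeNlsLM(y ~ Vmax * S / (KM + S), data.frame(S = S, y = y),
                   as.list(est), lower = lower)
    if (is.null(f)) NULL else stats::coef(f)
  }
  newFitResult("michaelis_menten", est,
               ci = applyCImethod(fit, est, refit, ciMethod, nboot, seed),
               converged = TRUE, flags = flags,
               residuals = stats::residuals(fit), nobs = length(v))
}

#' Apparent Michaelis-Menten parameters per inhibitor level
#'
#' Fits [fitMichaelisMenten()] separately at every inhibitor
#' concentration of a substrate-by-inhibitor rate grid.
#'
#' @param table data.frame with columns `substrate_uM`, `inhibitor_uM`,
#'   `rate_M_per_s`.
#' @return data.frame with columns `I`, `Vmax`, `KM`, `seVmax`, `seKM`
#'   (asymptotic standard errors of the per-level fits).
#' @export
fitApparentKinetics <- function(table) {
  Is <- sort(unique(table$inhibitor_uM))
  out <- lapply(Is, function(i) {
    sub <- table[table$inhibitor_uM == i, ]
    f <- fitMichaelisMenten(sub$substrate_uM, sub$rate_M_per_s,
                            ciMethod = "wald")
    ci <- f@ci
    se <- (ci["upper", ] - ci["lower", ]) / (2 * stats::qnorm(0.975))
    data.frame(I = i, Vmax = f@estimates[["Vmax"]],
               KM = f@estimates[["KM"]],
               seVmax = unname(se["Vmax"]), seKM = unname(se["KM"]))
  })
  do.call(rbind, out)
}

#' Diagnose the inhibition mode from apparent-parameter trends
#'
#' Classifies from the trends of apparent `Vmax` and `KM` against
#' inhibitor concentration, using the relative change predicted across
#' the tested range: both decreasing is uncompetitive (both apparent
#' constants scale by `1/(1 + I/Ki)`); `KM` up with flat `Vmax` is
#' competitive; `Vmax` down with flat `KM` is noncompetitive; neither
#' changing is none; any other combination is mixed.
#'
#' A parameter counts as changing only when the change is material
#' (relative magnitude at least `tau` over the range) *and* supported by
#' the data: when the apparent table carries standard errors (`seVmax`,
#' `seKM`, as produced by [fitApparentKinetics()]), the trend line is a
#' fixed-weight generalized least squares fit and the predicted change
#' must exceed `zCrit` of its standard errors. Without standard errors
#' the pure tolerance rule applies. This keeps a genuinely flat but
#' poorly identified parameter (e.g. apparent `Vmax` when the apparent
#' `KM` exceeds the highest tested substrate) from drifting past `tau`
#' by estimation noise alone.
#'
#' @param apparent data.frame with columns `I`, `Vmax`, `KM` and
#'   optionally `seVmax`, `seKM`; must include `I = 0`.
#' @param tau relative-change tolerance (default 0.1 over the range).
#' @param zCrit evidence threshold in standard errors (default 2.5).
#' @return list with `mode` and the relative changes `relVmax`, `relKM`.
#' @export
diagnoseInhibitionMode <- function(apparent, tau = 0.1, zCrit = 2.5) {
  if (nrow(apparent) < 3) stop("need >= 3 inhibitor concentrations")
  if (!any(apparent$I == 0)) stop("missing [I] = 0 baseline")
  trend <- function(y, se) {
    if (is.null(se)) {
      f <- stats::lm(y ~ I, data = apparent)
      p <- unname(stats::predict(f,
        newdata = data.frame(I = range(apparent$I))))
      return(c(rel = (p[2] - p[1]) / p[1], z = Inf * sign(p[2] - p[1])))
    }
    se <- pmax(se, 1e-9 * max(abs(y)))   # noiseless fits: avoid 1/0 weights
    w <- 1 / se^2
    X <- cbind(1, apparent$I)
    V <- solve(t(X * w) %*% X)
    beta <- V %*% (t(X * w) %*% y)
    dI <- diff(range(apparent$I))
    d <- beta[2] * dI
    p0 <- beta[1] + beta[2] * min(apparent$I)
    c(rel = unname(d / p0), z = unname(d / (sqrt(V[2, 2]) * dI)))
  }
  tv <- trend(apparent$Vmax, apparent$seVmax)
  tk <- trend(apparent$KM, apparent$seKM)
  rv <- tv[["rel"]]; rk <- tk[["rel"]]
  dirOf <- function(t) {
    if (t[["rel"]] <= -tau && t[["z"]] <= -zCrit) "down"
    else if (t[["rel"]] >= tau && t[["z"]] >= zCrit) "up"
    else "flat"
  }
  dv <- dirOf(tv); dk <- dirOf(tk)
  mode <- if (dv == "down" && dk == "down") "uncompetitive"
    else if (dv == "flat" && dk == "up") "competitive"
    else if (dv == "down" && dk == "flat") "noncompetitive"
    else if (dv == "flat" && dk == "flat") "none"
    else "mixed"
  list(mode = mode, relVmax = unname(rv), relKM = unname(rk))
}

#' Global uncompetitive-inhibition fit (Ki)
#'
#' Global least squares of `v = Vmax * S / (KM + S * (1 + I/Ki))` over a
#' substrate-by-inhibitor grid, reporting `Vmax`, `KM`, `Ki` and (in
#' `details$apparent`) the apparent-parameter consistency check: for a
#' truly uncompetitive inhibitor, `Vmax_app(I)/Vmax` and `KM_app(I)/KM`
#' both equal `1/(1 + I/Ki)`.
#'
#' @param table data.frame with columns `substrate_uM`, `inhibitor_uM`,
#'   `rate_M_per_s`; needs >= 3 substrate and >= 3 inhibitor levels.
#' @param ciMethod,nboot,seed as in [fitIC50()].
#' @return [FitResult-class].
#' @export
fitUncompetitiveKi <- function(table, ciMethod = c("bootstrap", "wald",
                                                   "none"),
                               nboot = 1000L, seed = NULL) {
  ciMethod <- match.arg(ciMethod)
  if (length(unique(table$substrate_uM)) < 3 ||
      length(unique(table$inhibitor_uM)) < 3)
    stop("grid too thin: need >= 3 substrate and >= 3 inhibitor levels")
  base <- table[table$inhibitor_uM == min(table$inhibitor_uM), ]
  f0 <- fitMichaelisMenten(base$substrate_uM, base$rate_M_per_s)
  start <- list(Vmax = f0@estimates[["Vmax"]],
                KM = f0@estimates[["KM"]],
                Ki = stats::median(table$inhibitor_uM[table$inhibitor_uM > 0]))
  dat <- data.frame(S = table$substrate_uM, I = table$inhibitor_uM,
                    v = table$rate_M_per_s)
  lower <- c(1e-300, 1e-9, 1e-9)
  fit <- safeNlsLM(v ~ Vmax * S / (KM + S * (1 + I / Ki)), dat, start,
                   lower = lower)
  if (is.null(fit))
    return(newFitResult("uncompetitive_ki", unlist(start),
                        converged = FALSE, flags = "not_converged",
                        nobs = nrow(dat)))
  est <- stats::coef(fit)
  app <- fitApparentKinetics(table)
  app$VmaxRatio <- app$Vmax / est[["Vmax"]]
  app$KMRatio <- app$KM / est[["KM"]]
  app$expectedRatio <- 1 / (1 + app$I / est[["Ki"]])
  refit <- function(y) {
    f <- safeNlsLM(y ~ Vmax * S / (KM + S * (1 + I / Ki)),
                   data.frame(S = dat$S, I = dat$I, y = y), as.list(est),
                   lower = lower)
    if (is.null(f)) NULL else stats::coef(f)
  }
  newFitResult("uncompetitive_ki", est,
               ci = applyCImethod(fit, est, refit, ciMethod, nboot, seed),
               converged = TRUE, residuals = stats::residuals(fit),
               nobs = nrow(dat), details = list(apparent = app))
}

#' Mass-spectrometry cleavage fraction and rate
#'
#' Cleavage statistic `A / (A + B)` per timepoint, where `A` is the peak
#' height of the cleaved product species and `B` the peak height of the
#' parent substrate, followed by the OLS slope of the fraction against
#' time over the (by default full) linear window.
#'
#' @param time timepoints (any consistent unit; the rate is per that
#'   unit).
#' @param A,B peak heights, `A + B > 0` at every timepoint.
#' @param window optional index vector restricting the rate fit.
#' @return list with `fractions` (data.frame `time`, `fraction`) and
#'   `rate` (slope of fraction per time unit).
#' @export
msCleavage <- function(time, A, B, window = seq_along(time)) {
  if (any(A < 0) || any(B < 0)) stop("peak heights must be >= 0")
  if (any(A + B <= 0)) stop("A + B must be > 0 at every timepoint")
  frac <- A / (A + B)
  rate <- if (length(window) >= 2)
    unname(stats::coef(stats::lm(frac[window] ~ time[window]))[2])
  else NA_real_
  list(fractions = data.frame(time = time, fraction = frac), rate = rate)
}

#' Percent inhibition relative to an uninhibited control
#'
#' `100 * (1 - v_inhibited / v_control)`. Negative values (activation or
#' noise) are reported as-is with a `clipped` attribute marking them.
#'
#' @param vInhibited rate(s) under inhibitor.
#' @param vControl control rate (> 0).
#' @return numeric percent inhibition with logical attribute `clipped`.
#' @export
percentInhibition <- function(vInhibited, vControl) {
  if (any(vControl <= 0)) stop("vControl must be > 0")
  p <- 100 * (1 - vInhibited / vControl)
  attr(p, "clipped") <- p < 0
  p
}

#' Fit the depletion-corrected 1:1 binding isotherm (KD)
#'
#' Least squares of `signal = Ffree + dF * fb(L, P0, KD)` with
#' [fractionBound()], the exact quadratic fraction-bound that remains
#' valid when the titrated ligand is not in large excess over the labeled
#' protein.
#'
#' @param L total ligand concentrations (>= 6 titration points).
#' @param signal measured signals.
#' @param P0 total labeled-protein concentration (> 0, same units as
#'   `L`).
#' @param ciMethod,nboot,seed as in [fitIC50()].
#' @return [FitResult-class] with estimates `Ffree`, `dF`, `KD`.
#' @export
fitBindingKd <- function(L, signal, P0, ciMethod = c("bootstrap", "wald",
                                                     "none"),
                         nboot = 1000L, seed = NULL) {
  ciMethod <- match.arg(ciMethod)
  if (length(L) < 6) stop("need >= 6 titration points")
  if (P0 <= 0) stop("P0 must be > 0")
  o <- order(L)
  start <- list(Ffree = signal[o][1],
                dF = signal[o][length(L)] - signal[o][1],
                KD = stats::median(L[L > 0]))
  dat <- data.frame(L = L, signal = signal)
  lower <- c(-Inf, -Inf, min(L[L > 0]) * 1e-9)
  fit <- safeNlsLM(signal ~ Ffree + dF * fractionBound(L, P0, KD), dat,
                   start, lower = lower)
  if (is.null(fit))
    return(newFitResult("binding_1to1", unlist(start), converged = FALSE,
                        flags = "not_converged", nobs = length(L)))
  est <- stats::coef(fit)
  flags <- if (est[["KD"]] <= lower[3] * 1.01) "boundary_kd" else character(0)
  refit <- function(y) {
    f <- safeNlsLM(y ~ Ffree + dF * fractionBound(L, P0, KD),
                   data.frame(L = L, y = y), as.list(est), lower = lower)
    if (is.null(f)) NULL else stats::coef(f)
  }
  newFitResult("binding_1to1", est,
               ci = applyCImethod(fit, est, refit, ciMethod, nboot, seed),
               converged = TRUE, flags = flags,
               residuals = stats::residuals(fit), nobs = length(L))
}
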