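# Enzymology fitters: standard curves, rates, IC50, Michaelis-Menten,
# inhibition mode, Ki, MS cleavage, binding KD.

test_that("standard curve recovers an exact line and rejects singular designs", {
  conc <- c(0, 2.5e-8, 5e-8, 1e-7, 2e-7)
  f <- fitStandardCurve(conc, 2e9 * conc + 5)
  expect_equal(coef(f)[["slope"]], 2e9, tolerance = 1e-9)
  expect_equal(coef(f)[["intercept"]], 5, tolerance = 1e-6)
  expect_equal(rfuToConc(f, 2e9 * 1e-7 + 5), 1e-7, tolerance = 1e-12)
  expect_error(fitStandardCurve(rep(1e-7, 4), 1:4), "singular")
})

test_that("noisy standard-curve slope lands within 3 SE of truth", {
  set.seed(61)
  conc <- seq(0, 2e-7, length.out = 12)
  rfu <- 2e9 * conc + 5 + rnorm(12, sd = 20)
  f <- fitStandardCurve(conc, rfu)
  se <- (confint(f)["upper", "slope"] - confint(f)["lower", "slope"]) /
    (2 * qnorm(0.975))
  expect_lt(abs(coef(f)[["slope"]] - 2e9), 3 * se)
})

test_that("initial rate converts a linear progress curve exactly", {
  std <- fitStandardCurve(c(0, 1e-7, 2e-7), c(0, 100, 200))  # 1e9 RFU/M
  times <- seq(0, 7200, by = 900)                            # every 15 min, 2 h
  # slope 0.01 RFU/s over 1e9 RFU/M -> 1e-11 M/s, well under the cap
  v <- initialRate(times, 0.01 * times, std, S0 = 1e-4)
  expect_equal(unclass(v), 1e-11, tolerance = 1e-12, ignore_attr = TRUE)
  # flat curve: zero rate
  v0 <- initialRate(times, rep(7, length(times)), std, S0 = 1e-4)
  expect_equal(unclass(v0), 0, ignore_attr = TRUE)
  expect_error(initialRate(c(0, 10), c(1, 2), std, 1e-4), "3")
})

test_that("the consumption cap trims the fitted window of a saturating curve", {
  std <- fitStandardCurve(c(0, 1e-7, 2e-7), c(0, 100, 200))
  times <- seq(0, 7200, by = 900)
  # product saturates at 2e-5 M with S0 = 1e-4: cap 0.1*S0 = 1e-5 M
  product <- 2e-5 * (1 - exp(-times / 4000))
  rfu <- product * 1e9
  v <- initialRate(times, rfu, std, S0 = 1e-4, maxFractionConsumed = 0.1)
  w <- attr(v, "window")
  expect_lt(length(w), length(times))
  # matches OLS on the hand-selected window
  over <- which(product - product[1] >= 1e-5)
  wantW <- seq_len(over[1] - 1)
  expect_identical(w, wantW)
  wantSlope <- unname(coef(lm(rfu[wantW] ~ times[wantW]))[2]) / 1e9
  expect_equal(unclass(v), wantSlope, ignore_attr = TRUE)
})

test_that("4PL fit recovers noiseless parameters and the midpoint identity", {
  conc <- 25 * 4^seq(-3, 3)
  resp <- fourPL(conc, top = 1, bottom = 0, ic50 = 25, h = 1)
  f <- fitIC50(conc, resp, ciMethod = "none")
  expect_true(isConverged(f))
  expect_lt(abs(coef(f)[["ic50"]] - 25) / 25, 1e-6)
  est <- coef(f)
  atIC50 <- fourPL(est[["ic50"]], est[["top"]], est[["bottom"]],
                   est[["ic50"]], est[["h"]])
  expect_equal(atIC50, (est[["top"]] + est[["bottom"]]) / 2)
})

test_that("flat dose-response is flagged with no IC50", {
  f <- fitIC50(c(1, 5, 25, 125), rep(0.8, 4))
  expect_true("no_dose_effect" %in% fitFlags(f))
  expect_true(is.na(coef(f)[["ic50"]]))
  expect_error(fitIC50(c(1, 1, 5, 5), 1:4), "4 distinct")
})

test_that("an activating (rising) dose-response still fits", {
  conc <- 10 * 4^seq(-3, 3)
  resp <- fourPL(conc, top = 0.1, bottom = 1.2, ic50 = 10, h = 1.5)
  f <- fitIC50(conc, resp, ciMethod = "none")
  expect_lt(abs(coef(f)[["ic50"]] - 10) / 10, 1e-5)
})

test_that("Michaelis-Menten fit is exact on clean data and guards inputs", {
  S <- c(10, 20, 40, 80, 124.4)
  v <- michaelisMentenRate(S, 1e-8, 50, mode = "none")
  f <- fitMichaelisMenten(S, v)
  expect_lt(abs(coef(f)[["Vmax"]] - 1e-8) / 1e-8, 1e-9)
  expect_lt(abs(coef(f)[["KM"]] - 50) / 50, 1e-9)
  # v(KM) = Vmax/2 on the fitted curve
  est <- coef(f)
  expect_equal(michaelisMentenRate(est[["KM"]], est[["Vmax"]], est[["KM"]],
                                   mode = "none"), est[["Vmax"]] / 2)
  expect_error(fitMichaelisMenten(c(10, 20), c(1, 2) * 1e-9), "3 distinct")
})

test_that("inhibition-mode diagnosis matches the analytic signatures", {
  I <- c(0, 6, 18, 54)
  # uncompetitive: both apparent parameters scale by 1/(1+I/Ki)
  app <- data.frame(I = I, Vmax = 1e-8 / (1 + I / 20),
                    KM = 50 / (1 + I / 20))
  expect_equal(diagnoseInhibitionMode(app)$mode, "uncompetitive")
  # textbook competitive: KM up, Vmax constant
  app2 <- data.frame(I = I, Vmax = rep(1e-8, 4), KM = 50 * (1 + I / 20))
  expect_equal(diagnoseInhibitionMode(app2)$mode, "competitive")
  # noncompetitive: Vmax down, KM constant
  app3 <- data.frame(I = I, Vmax = 1e-8 / (1 + I / 20), KM = rep(50, 4))
  expect_equal(diagnoseInhibitionMode(app3)$mode, "noncompetitive")
  # no inhibition
  app4 <- data.frame(I = I, Vmax = rep(1e-8, 4), KM = rep(50, 4))
  expect_equal(diagnoseInhibitionMode(app4)$mode, "none")
  # discordant: KM up and Vmax down
  app5 <- data.frame(I = I, Vmax = 1e-8 / (1 + I / 20), KM = 50 * (1 + I / 20))
  expect_equal(diagnoseInhibitionMode(app5)$mode, "mixed")
  expect_error(diagnoseInhibitionMode(app[-1, ]), "baseline")
})

test_that("noisy uncompetitive grids are labeled correctly in >= 90% of runs", {
  g <- defaultKineticGrid()
  ok <- 0L
  for (s in 1:40) {
    sp <- assaySpec("michaelis_menten_uncompetitive",
                    list(Vmax = 1e-8, KM = 50, Ki = 20), g, n = 4,
                    noiseCV = 0.05, seed = s)
    d <- assayData(genAssayTable(sp)); d <- d[!d$is_truth, ]
    ok <- ok + (diagnoseInhibitionMode(fitApparentKinetics(d))$mode ==
                "uncompetitive")
  }
  expect_gte(ok, 36L)
})

test_that("global uncompetitive fit recovers Ki and its internal identities", {
  g <- defaultKineticGrid()
  sp <- assaySpec("michaelis_menten_uncompetitive",
                  list(Vmax = 1e-8, KM = 50, Ki = 20), g, n = 1, seed = 4)
  d <- assayData(genAssayTable(sp)); d <- d[d$is_truth, ]
  f <- fitUncompetitiveKi(d, ciMethod = "none")
  expect_lt(abs(coef(f)[["Ki"]] - 20) / 20, 1e-6)
  est <- coef(f)
  # at I = Ki the apparent Vmax is Vmax/2
  vAtKi <- michaelisMentenRate(1e9, est[["Vmax"]], est[["KM"]],
                               I = est[["Ki"]], Ki = est[["Ki"]],
                               mode = "uncompetitive")
  expect_equal(vAtKi, est[["Vmax"]] / 2, tolerance = 1e-6)
  # uncompetitive signature: Vmax_app/Vmax = KM_app/KM = 1/(1+I/Ki)
  app <- f@details$apparent
  expect_equal(app$VmaxRatio, app$expectedRatio, tolerance = 1e-4)
  expect_equal(app$KMRatio, app$expectedRatio, tolerance = 1e-4)
  thin <- d[d$inhibitor_uM %in% c(0, 6), ]
  expect_error(fitUncompetitiveKi(thin), "thin")
})

test_that("MS cleavage fractions and rate follow A/(A+B)", {
  expect_equal(msCleavage(0, A = 3, B = 3)$fractions$fraction, 0.5)
  expect_equal(msCleavage(0, A = 0, B = 5)$fractions$fraction, 0)
  # fractions 0 .. 0.4 over 0..40 min: slope 0.01 per min (OLS by hand)
  r <- msCleavage(seq(0, 40, by = 10), A = seq(0, 0.4, by = 0.1),
                  B = 1 - seq(0, 0.4, by = 0.1))
  expect_equal(r$rate, 0.01, tolerance = 1e-12)
  expect_error(msCleavage(0, A = 0, B = 0), "A \\+ B")
})

test_that("percent inhibition handles the reference cases", {
  expect_equal(as.numeric(percentInhibition(5, 5)), 0)
  expect_equal(as.numeric(percentInhibition(0, 5)), 100)
  expect_equal(as.numeric(percentInhibition(0.57 * 5, 5)), 43)
  neg <- percentInhibition(6, 5)
  expect_true(attr(neg, "clipped"))
  expect_error(percentInhibition(1, 0), "> 0")
})

test_that("binding KD fit recovers the depletion-corrected isotherm", {
  L <- 800 / 2^(0:15)           # 1:1 dilution series, 16 capillaries
  sig <- 820 + 120 * fractionBound(L, P0 = 0.17, KD = 16)
  f <- fitBindingKd(L, sig, P0 = 0.17, ciMethod = "none")
  expect_lt(abs(coef(f)[["KD"]] - 16) / 16, 1e-6)
  expect_error(fitBindingKd(L[1:4], sig[1:4], 0.17), "6 titration")
  expect_error(fitBindingKd(L, sig, 0), "P0")
})

test_that("bootstrap and Wald intervals contain the point estimate", {
  conc <- 25 * 4^seq(-3, 3)
  set.seed(62)
  resp <- fourPL(rep(conc, 3), 1, 0, 25, 1) * (1 + rnorm(21, sd = 0.08))
  fb <- fitIC50(rep(conc, 3), resp, ciMethod = "bootstrap", nboot = 120,
                seed = 63)
  ci <- confint(fb)
  expect_true(ci["lower", "ic50"] <= coef(fb)[["ic50"]])
  expect_true(ci["upper", "ic50"] >= coef(fb)[["ic50"]])
  fw <- fitIC50(rep(conc, 3), resp, ciMethod = "wald")
  ciw <- confint(fw)
  expect_true(all(ciw["lower", ] <= coef(fw) & coef(fw) <= ciw["upper", ]))
})
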