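# Tandem-reporter flux quantification and the Lysotracker metric.

test_that("adaptive threshold obeys the stated inequality on constants", {
  img <- matrix(3.7, 20, 20)
  allTrue <- preprocessMask(img, tandemConfig(adaptiveOffset = 1))
  expect_true(all(allTrue))
  allFalse <- preprocessMask(img, tandemConfig(adaptiveOffset = -1))
  expect_false(any(allFalse))
  expect_error(preprocessMask(img, tandemConfig(adaptiveBlock = 10)), "odd")
  expect_error(preprocessMask(img, tandemConfig(gaussianSigma = -1)), ">= 0")
})

test_that("a bright blob is masked; verified against the local-mean oracle", {
  img <- matrix(0, 24, 24)
  img[10:11, 10:11] <- 50
  cfg <- tandemConfig(gaussianSigma = 0.5, adaptiveBlock = 11,
                      adaptiveOffset = -5)
  got <- preprocessMask(img, cfg)
  sm <- gaussianBlur(img, 0.5)
  want <- sm > localMeanOracle(sm, 11) + 5
  expect_identical(got, want)
  expect_true(all(got[10:11, 10:11]))
})

test_that("the mask is invariant to adding a constant to the image", {
  set.seed(8)
  img <- matrix(rexp(24 * 24, 1 / 20), 24, 24)
  cfg <- tandemConfig(adaptiveOffset = -10)
  expect_identical(preprocessMask(img, cfg), preprocessMask(img + 123, cfg))
})

test_that("findPuncta equals the flood-fill oracle and respects 8-connectivity", {
  m <- matrix(FALSE, 20, 20)
  m[2:4, 2:4] <- TRUE
  m[10:12, 10:12] <- TRUE
  m[17, 17] <- TRUE
  p <- findPuncta(m, tandemConfig(minArea = 1))
  expect_equal(nrow(p), 3)
  lab <- floodFillOracle(m)
  expect_setequal(unlist(p$pixels), which(lab > 0))
  # diagonal touch merges under 8-connectivity
  m2 <- matrix(FALSE, 10, 10); m2[3, 3] <- TRUE; m2[4, 4] <- TRUE
  expect_equal(nrow(findPuncta(m2, tandemConfig(minArea = 1))), 1)
  expect_equal(nrow(findPuncta(matrix(FALSE, 5, 5),
                               tandemConfig(minArea = 1))), 0)
})

test_that("red/yellow classification uses single-green overlap fractions", {
  mkP <- function(px, d = 20) {
    m <- matrix(FALSE, d, d); m[px] <- TRUE
    findPuncta(m, tandemConfig(minArea = 1))
  }
  red <- mkP(c(45, 46, 47, 65, 66, 67, 85, 86))     # 8 px
  expect_equal(red$area, 8)
  # no green puncta: red_only
  none <- classifyRedYellow(red, mkP(integer(0)), c(20, 20))
  expect_equal(none$colorClass, "red_only")
  # identical green punctum: overlap 1 -> yellow
  same <- classifyRedYellow(red, mkP(c(45, 46, 47, 65, 66, 67, 85, 86)),
                            c(20, 20))
  expect_equal(same$colorClass, "yellow")
  expect_equal(same$overlapFrac, 1.0)
  # 3 of 8 px overlap = 0.375 < 0.5 -> red_only
  part <- classifyRedYellow(red, mkP(c(45, 46, 47, 48, 49)), c(20, 20))
  expect_equal(part$overlapFrac, 3 / 8)
  expect_equal(part$colorClass, "red_only")
  expect_error(classifyRedYellow(red, red, c(20, 20), 0), "Threshold|threshold")
})

test_that("class counts are conserved and monotone in the overlap threshold", {
  sim <- genTandemField(fieldSpec(nCells = 20L, seed = 51L), 0.5)
  res <- analyzeTandemField(sim$field, tandemConfig(),
                            hcsConfig(cellRadius = 14))
  rp <- res$redPuncta
  expect_equal(sum(rp$colorClass == "red_only") +
               sum(rp$colorClass == "yellow"), nrow(rp))
  nRedAt <- function(t) sum(classifyRedYellow(rp, res$greenPuncta,
    fieldDim(sim$field), t)$colorClass == "red_only")
  expect_true(all(diff(c(nRedAt(0.3), nRedAt(0.5), nRedAt(0.8),
                         nRedAt(1.0))) >= 0))
})

test_that("per-cell flux ratios follow the exclusion rules", {
  cells <- data.frame(label = 1L, row = 10, col = 10)
  cells$nucleusPixels <- list(1L)
  cells$region <- list(seq_len(400))
  attr(cells, "dim.image") <- c(20L, 20L)
  mkRed <- function(n, cls) {
    data.frame(area = rep(1, n), perimeter = 4, formFactor = pi / 4,
               row = seq(2, 2 + n - 1), col = rep(10, n),
               colorClass = cls)
  }
  red <- rbind(mkRed(4, "red_only"), mkRed(2, "yellow"))
  red$pixels <- as.list(seq_len(6))
  s <- fluxRatio(red, cells, tandemConfig(minCellsAnalyzed = 1))
  expect_equal(s@perCell$ratio, 2.0)
  expect_equal(s@pooledRatio, 2.0)
  # all cells without yellow puncta: mean undefined, pooled flagged Inf
  red2 <- mkRed(3, "red_only"); red2$pixels <- as.list(1:3)
  s2 <- fluxRatio(red2, cells, tandemConfig(minCellsAnalyzed = 1))
  expect_true(is.na(s2@meanRatio))
  expect_true(is.infinite(s2@pooledRatio))
  expect_true("no_yellow_puncta" %in% s2@flags)
  expect_error(fluxRatio(red, cells[0, ], tandemConfig()), "no cells")
})

test_that("fewer cells than the advisory minimum raises a flag", {
  sim <- genTandemField(fieldSpec(nCells = 10L, width = 200L, height = 200L,
                                  seed = 52L), 0.5)
  res <- analyzeTandemField(sim$field, tandemConfig(),
                            hcsConfig(cellRadius = 14))
  expect_true("few_cells" %in% res$summary@flags)
})

test_that("lowering the generator red-only fraction lowers the computed ratio", {
  ratioAt <- function(rf) {
    s <- analyzeTandemField(genTandemField(fieldSpec(nCells = 30L,
      seed = 53L), rf)$field, tandemConfig(),
      hcsConfig(cellRadius = 14))$summary
    s@pooledRatio
  }
  r <- c(ratioAt(0.2), ratioAt(0.5), ratioAt(0.8))
  expect_true(all(diff(r) > 0))
})

test_that("the Lysotracker metric is zero on flat dye, linear, per-nucleus", {
  nuc <- matrix(0, 60, 60)
  for (ctr in list(c(15, 15), c(45, 45)))
    nuc[outer((1:60 - ctr[1])^2, (1:60 - ctr[2])^2, "+") <= 16] <- 200
  mk <- function(ltr, nn = nuc) LabeledField(list(ltr = ltr, nuclear = nn))
  cfg <- hcsConfig(minNucleusArea = 10, nuclearThreshold = 100)
  # uniform dye = background -> metric 0
  r0 <- ltrMetric(mk(matrix(30, 60, 60)), tandemConfig(), cfg)
  expect_equal(r0@metric, 0)
  expect_equal(r0@nNuclei, 2L)
  # doubling (signal - background) doubles the metric
  ltr1 <- matrix(10, 60, 60); ltr1[20:40, 20:40] <- 10 + 50
  ltr2 <- matrix(10, 60, 60); ltr2[20:40, 20:40] <- 10 + 100
  m1 <- ltrMetric(mk(ltr1), tandemConfig(), cfg)
  m2 <- ltrMetric(mk(ltr2), tandemConfig(), cfg)
  expect_equal(m2@metric / m1@metric, 2, tolerance = 1e-6)
  # halved nuclei count doubles the per-cell metric
  nuc1 <- matrix(0, 60, 60)
  nuc1[outer((1:60 - 15)^2, (1:60 - 15)^2, "+") <= 16] <- 200
  mHalf <- ltrMetric(mk(ltr1, nuc1), tandemConfig(), cfg)
  expect_equal(mHalf@metric / m1@metric, 2, tolerance = 1e-6)
  expect_equal(mHalf@normalizedToControl, NA_real_)
  # control normalization
  mn <- ltrMetric(mk(ltr2), tandemConfig(), cfg, control = m1)
  expect_equal(mn@normalizedToControl, 2, tolerance = 1e-6)
  # zero nuclei: undefined metric with flag
  suppressWarnings(mNo <- ltrMetric(mk(ltr1, matrix(0, 60, 60)),
                                    tandemConfig(), cfg))
  expect_true(is.na(mNo@metric))
  expect_true("no_nuclei" %in% mNo@flags)
})
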