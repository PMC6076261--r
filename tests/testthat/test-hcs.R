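# High-content pipeline: nuclei, cell regions, viability, puncta,
# field summary.

mkField <- function(nuclear = NULL, viability = NULL, gfp = NULL, d = 40) {
  ch <- list()
  base <- matrix(0, d, d)
  ch$nuclear <- if (is.null(nuclear)) base else nuclear
  ch$viability <- if (is.null(viability)) base else viability
  ch$gfp <- if (is.null(gfp)) base else gfp
  LabeledField(ch)
}

disc <- function(img, r0, c0, radius, value) {
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
    if ((i - r0)^2 + (j - c0)^2 <= radius^2) img[i, j] <- value
  img
}

test_that("constant nuclear channel yields zero nuclei with a warning", {
  f <- mkField(nuclear = matrix(7, 40, 40))
  expect_warning(lab <- segmentNuclei(f), "no signal")
  expect_equal(attr(lab, "n"), 0L)
})

test_that("two separated bright discs give exactly two labels with the
           thresholded pixel sets", {
  img <- matrix(10, 40, 40)
  img <- disc(img, 10, 10, 4, 200)
  img <- disc(img, 30, 30, 4, 200)
  lab <- segmentNuclei(mkField(nuclear = img),
                       hcsConfig(minNucleusArea = 10))
  expect_equal(attr(lab, "n"), 2L)
  want <- floodFillOracle(img > otsuThreshold(img))
  expect_identical(as.integer(lab > 0), as.integer(want > 0))
  expect_equal(attr(want, "n"), 2L)
})

test_that("synthetic fields at min separation segment to the true nucleus count", {
  sim <- genHcsField(fieldSpec(nCells = 50L, seed = 41L,
                               noisePoisson = FALSE, noiseGaussianSD = 0))
  lab <- segmentNuclei(sim$field)
  expect_equal(attr(lab, "n"), 50L)
})

test_that("a single nucleus gets the full clipped digital disc", {
  img <- matrix(0, 30, 30)
  img <- disc(img, 15, 15, 3, 100)
  lab <- segmentNuclei(mkField(nuclear = img, d = 30),
                       hcsConfig(minNucleusArea = 5, nuclearThreshold = 50))
  cells <- defineCellRegions(lab, radiusPx = 8)
  expect_equal(nrow(cells), 1)
  ctr <- c(cells$row[1], cells$col[1])
  want <- which(outer((1:30 - ctr[1])^2, (1:30 - ctr[2])^2, "+") <= 64)
  expect_setequal(cells$region[[1]], want)
})

test_that("two competing nuclei split the shared band along the bisector", {
  img <- matrix(0, 40, 40)
  img <- disc(img, 20, 14, 3, 100)
  img <- disc(img, 20, 26, 3, 100)
  lab <- segmentNuclei(mkField(nuclear = img),
                       hcsConfig(minNucleusArea = 5, nuclearThreshold = 50))
  cells <- defineCellRegions(lab, radiusPx = 10)
  expect_equal(nrow(cells), 2)
  # brute-force nearest-centroid assignment
  r1 <- cells$region[[1]]; r2 <- cells$region[[2]]
  expect_length(intersect(r1, r2), 0)
  all_px <- c(r1, r2)
  rows <- (all_px - 1) %% 40 + 1; cols <- (all_px - 1) %/% 40 + 1
  d1 <- (rows - cells$row[1])^2 + (cols - cells$col[1])^2
  d2 <- (rows - cells$row[2])^2 + (cols - cells$col[2])^2
  inR1 <- all_px %in% r1
  # pixels strictly nearer centroid 1 are in region 1 and vice versa
  expect_true(all(inR1[d1 < d2]))
  expect_true(all(!inR1[d2 < d1]))
  # every nucleus pixel belongs to its own region
  expect_true(all(cells$nucleusPixels[[1]] %in% r1))
  expect_true(all(cells$nucleusPixels[[2]] %in% r2))
})

test_that("a corner nucleus is clipped to the image bounds", {
  img <- matrix(0, 25, 25)
  img <- disc(img, 2, 2, 2, 100)
  lab <- segmentNuclei(mkField(nuclear = img, d = 25),
                       hcsConfig(minNucleusArea = 3, nuclearThreshold = 50))
  cells <- defineCellRegions(lab, radiusPx = 6)
  px <- cells$region[[1]]
  expect_true(all(px >= 1 & px <= 625))
  expect_error(defineCellRegions(lab, radiusPx = 0), "> 0")
})

test_that("viability threshold is inclusive at exactly 50% overlap", {
  # hand-built 10x10 cell region (100 px) so the overlap is exactly 0.50
  cells <- data.frame(label = 1L, row = 10.5, col = 10.5)
  region <- as.vector(outer(6:15, (6:15 - 1) * 20, "+"))
  cells$nucleusPixels <- list(region[1:5])
  cells$region <- list(region)
  attr(cells, "dim.image") <- c(20L, 20L)
  cfg <- hcsConfig(viabilityThreshold = 50)
  via <- matrix(0, 20, 20); via[region[1:50]] <- 100
  f <- LabeledField(list(nuclear = matrix(0, 20, 20), viability = via))
  got <- classifyViability(cells, f, 0.5, cfg)
  expect_equal(got$ethd1Overlap, 0.5)
  expect_equal(got$viability, "dead")        # "at least 50%" is inclusive
  via49 <- matrix(0, 20, 20); via49[region[1:49]] <- 100
  f49 <- LabeledField(list(nuclear = matrix(0, 20, 20), viability = via49))
  expect_equal(classifyViability(cells, f49, 0.5, cfg)$viability, "live")
})

test_that("zero viability signal leaves every cell live", {
  sim <- genHcsField(fieldSpec(nCells = 20L, deadFraction = 0, seed = 43L))
  res <- analyzeHcsField(sim$field, hcsConfig(cellRadius = 14))
  expect_true(all(res$cells$viability == "live"))
})

test_that("a 37%-masked region scores overlap 0.37 and stays live", {
  lab <- matrix(0L, 20, 20)
  lab[6:15, 6:15] <- 1L  # use a hand region via fixed assignment
  cells <- data.frame(label = 1L, row = 10.5, col = 10.5)
  cells$nucleusPixels <- list(which(lab == 1L)[1:5])
  cells$region <- list(which(lab == 1L))
  attr(cells, "dim.image") <- c(20L, 20L)
  via <- matrix(0, 20, 20)
  via[cells$region[[1]][1:37]] <- 100
  f <- LabeledField(list(nuclear = matrix(0, 20, 20), viability = via))
  got <- classifyViability(cells, f, 0.5, hcsConfig(viabilityThreshold = 50))
  expect_equal(got$ethd1Overlap, 0.37)
  expect_equal(got$viability, "live")
})

test_that("hand-built masks: compact square kept, elongated line rejected", {
  gfp <- matrix(0, 16, 16)
  gfp[3:5, 3:5] <- 100          # 3x3 square, FF = pi/4
  gfp[10, 3:12] <- 100          # 1x10 line, FF ~ 0.26
  f <- mkField(gfp = gfp, d = 16)
  cells <- data.frame(label = 1L, row = 8, col = 8)
  cells$nucleusPixels <- list(1L); cells$region <- list(seq_len(256))
  attr(cells, "dim.image") <- c(16L, 16L)
  cfg <- hcsConfig(gfpMode = "fixed", gfpThreshold = 50, minArea = 1,
                   minFormFactor = 0.4)
  det <- detectPuncta(f, cells, cfg)
  expect_equal(nrow(det$puncta), 1)
  expect_equal(det$puncta$area, 9)
  expect_equal(det$puncta$formFactor, pi / 4)
  # counts match the exhaustive flood-fill + edge-count oracle
  lab <- floodFillOracle(gfp > 50)
  per <- perimeterOracle(lab)
  a <- tabulate(lab[lab > 0], attr(lab, "n"))
  keep <- 4 * pi * a / per^2 >= 0.4
  expect_equal(sum(keep), 1)
})

test_that("empty GFP channel yields zero puncta and min-area-1 keeps single
           pixels", {
  f <- mkField(d = 16)
  cells <- data.frame(label = 1L, row = 8, col = 8)
  cells$nucleusPixels <- list(1L); cells$region <- list(seq_len(256))
  attr(cells, "dim.image") <- c(16L, 16L)
  cfg <- hcsConfig(gfpMode = "fixed", gfpThreshold = 50)
  expect_equal(nrow(detectPuncta(f, cells, cfg)$puncta), 0)
  gfp <- matrix(0, 16, 16); gfp[8, 8] <- 100
  det <- detectPuncta(mkField(gfp = gfp, d = 16), cells, cfg)
  expect_equal(det$puncta$area, 1)
  expect_equal(det$puncta$formFactor, pi / 4)  # exactly retained
  expect_error(detectPuncta(f, cells, hcsConfig(minArea = 0)), "minArea")
  expect_error(detectPuncta(f, cells, hcsConfig(minFormFactor = 0.9)),
               "minFormFactor")
})

test_that("raising the form-factor or area cutoff never adds puncta", {
  sim <- genHcsField(fieldSpec(nCells = 25L, seed = 44L))
  lab <- segmentNuclei(sim$field)
  cells <- defineCellRegions(lab, 14)
  nAt <- function(ff, ma) nrow(detectPuncta(sim$field, cells,
    hcsConfig(minFormFactor = ff, minArea = ma))$puncta)
  counts <- c(nAt(0.2, 1), nAt(0.4, 1), nAt(0.6, 1))
  expect_true(all(diff(counts) <= 0))
  areas <- c(nAt(0.4, 1), nAt(0.4, 5), nAt(0.4, 15))
  expect_true(all(diff(areas) <= 0))
})

test_that("raising the dead-overlap threshold never adds dead cells", {
  sim <- genHcsField(fieldSpec(nCells = 30L, deadFraction = 0.5, seed = 45L))
  lab <- segmentNuclei(sim$field)
  cells <- defineCellRegions(lab, 14)
  nDead <- function(t) sum(classifyViability(cells, sim$field, t)$viability ==
                           "dead")
  expect_true(all(diff(c(nDead(0.3), nDead(0.5), nDead(0.9))) <= 0))
})

test_that("field summary endpoints follow the documented counting rules", {
  cells <- data.frame(viability = rep("live", 10),
                      nPuncta = c(0, 1, 5, 5, 6, 2, 0, 7, 3, 5))
  s <- summarizeField(cells, minPuncta = 5)
  expect_equal(s@fracPositive, 0.5)
  expect_equal(s@nLive, 10L)
  # identity normalization against itself
  s2 <- summarizeField(cells, minPuncta = 5, controlSummaries = list(s))
  expect_equal(s2@normalizedValue, 1.0)
  # all-dead field: undefined fraction, explicit flag
  dead <- data.frame(viability = rep("dead", 4), nPuncta = 0:3)
  sd <- summarizeField(dead)
  expect_true(is.na(sd@fracPositive))
  expect_true("no_live_cells" %in% sd@flags)
  # tissue reading: threshold 1 counts any puncta-positive cell
  expect_equal(summarizeField(cells, minPuncta = 1)@fracPositive, 0.8)
})

test_that("the full pipeline is deterministic for a fixed field and config", {
  sim <- genHcsField(fieldSpec(nCells = 15L, seed = 46L))
  a <- analyzeHcsField(sim$field, hcsConfig(cellRadius = 14))
  b <- analyzeHcsField(sim$field, hcsConfig(cellRadius = 14))
  expect_identical(a$summary@fracPositive, b$summary@fracPositive)
  expect_identical(a$cells$nPuncta, b$cells$nPuncta)
})
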