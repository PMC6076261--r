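# Tandem mRFP-eGFP-LC3 flux quantification (red vs yellow puncta per
# cell) and the Lysotracker per-image intensity metric.

#' Tandem/LTR analysis configuration
#'
#' @param gaussianSigma Gaussian pre-filter SD, px.
#' @param adaptiveBlock adaptive-threshold window (odd, >= 3), px.
#' @param adaptiveOffset offset in `mask = smoothed > localMean - offset`.
#'   Note the sign: positive offsets are permissive (a constant image
#'   becomes all-foreground), so punctum detection uses a negative offset;
#'   `NULL` sets `-2 *` robust SD of the smoothed image.
#' @param regularize apply [majorityRegularize()] to the channel masks in
#'   the pipeline (after [preprocessMask()], before [findPuncta()]).
#' @param minArea minimum punctum area, px (default 6: a resolvable
#'   punctum disc covers >= 13 px at this magnification, while surviving
#'   noise blobs are smaller).
#' @param yellowOverlapThreshold fraction of a red punctum's area that must
#'   be covered by a single green punctum to call it yellow (inclusive).
#' @param minCellsAnalyzed advisory minimum number of cells for the
#'   per-cell ratio (the conventional "at least 100 cells"); fewer cells
#'   sets a `"few_cells"` flag.
#' @param ltrErosion erosion radius (px) applied to the cell-free
#'   background mask of the LTR channel.
#' @export
tandemConfig <- function(gaussianSigma = 1.0, adaptiveBlock = 11L,
                         adaptiveOffset = NULL, regularize = TRUE,
                         minArea = 6L,
                         yellowOverlapThreshold = 0.5,
                         minCellsAnalyzed = 100L, ltrErosion = 2L) {
  list(gaussianSigma = gaussianSigma, adaptiveBlock = adaptiveBlock,
       adaptiveOffset = adaptiveOffset, regularize = regularize,
       minArea = minArea,
       yellowOverlapThreshold = yellowOverlapThreshold,
       minCellsAnalyzed = minCellsAnalyzed, ltrErosion = ltrErosion)
}

#' Gaussian filter + adaptive threshold punctum mask
#'
#' `mask = gaussianBlur(img, sigma) > localMean(blurred, block) - offset`.
#' The local-mean subtraction makes the mask invariant to adding a
#' constant to the whole image. On a constant image the inequality reduces
#' to `0 > -offset`: all-true for `offset > 0`, all-false for
#' `offset < 0`.
#'
#' @param img single-channel intensity matrix.
#' @param cfg a [tandemConfig()] (sigma, block, offset).
#' @return logical mask.
#' @export
preprocessMask <- function(img, cfg = tandemConfig()) {
  if (cfg$gaussianSigma < 0) stop("gaussianSigma must be >= 0")
  if (cfg$adaptiveBlock %% 2 != 1 || cfg$adaptiveBlock < 3)
    stop("adaptiveBlock must be odd and >= 3")
  sm <- gaussianBlur(img, cfg$gaussianSigma)
  off <- cfg$adaptiveOffset
  if (is.null(off)) off <- -2 * robustSD(sm)
  sm > localMean(sm, cfg$adaptiveBlock) - off
}

#' Find puncta in a binary mask
#'
#' 8-connected components with area `>= minArea`, with pixel sets and
#' centroids — equivalent to contour discovery followed by interior fill.
#'
#' @param mask logical matrix.
#' @param cfg a [tandemConfig()] (`minArea`).
#' @return data.frame: `area`, `perimeter`, `formFactor`, `row`, `col`,
#'   list-column `pixels`.
#' @export
findPuncta <- function(mask, cfg = tandemConfig()) {
  maskToPuncta(mask, minArea = cfg$minArea, minFormFactor = 0)
}

#' Classify red puncta as red-only or yellow
#'
#' A red punctum is `yellow` iff the largest fraction of its area covered
#' by any single green punctum reaches `yellowOverlapThreshold`
#' (inclusive); otherwise `red_only`. With no green puncta everything is
#' `red_only`.
#'
#' @param redPuncta,greenPuncta punctum tables from [findPuncta()] on the
#'   red and green channel masks of the same field.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @param yellowOverlapThreshold threshold in `(0, 1]`.
#' @return `redPuncta` with added columns `colorClass` and `overlapFrac`.
#' @export
classifyRedYellow <- function(redPuncta, greenPuncta, dim,
                              yellowOverlapThreshold = 0.5) {
  if (yellowOverlapThreshold <= 0 || yellowOverlapThreshold > 1)
    stop("yellowOverlapThreshold must be in (0, 1]")
  greenLab <- matrix(0L, dim[1], dim[2])
  for (g in seq_len(nrow(greenPuncta)))
    greenLab[greenPuncta$pixels[[g]]] <- g
  ov <- vapply(seq_len(nrow(redPuncta)), function(i) {
    px <- redPuncta$pixels[[i]]
    gl <- greenLab[px]
    gl <- gl[gl > 0L]
    if (!length(gl)) return(0)
    max(tabulate(gl)) / length(px)
  }, numeric(1))
  redPuncta$overlapFrac <- ov
  redPuncta$colorClass <- ifelse(ov >= yellowOverlapThreshold,
                                 "yellow", "red_only")
  redPuncta
}

#' Per-cell red:yellow flux ratio
#'
#' Assigns classified red puncta to cells by centroid membership and
#' computes the per-cell ratio `nRedOnly / nYellow` for cells with at
#' least one yellow punctum (cells with none are excluded from the mean
#' but counted and reported), the mean ratio with SEM, and the pooled
#' ratio `sum(red_only) / sum(yellow)` over all assigned puncta.
#'
#' @param redPuncta classified punctum table from [classifyRedYellow()].
#' @param cells cell table from [defineCellRegions()].
#' @param cfg a [tandemConfig()] (`minCellsAnalyzed`).
#' @return a [FluxSummary-class].
#' @export
fluxRatio <- function(redPuncta, cells, cfg = tandemConfig()) {
  if (nrow(cells) == 0L) stop("no cells to assign puncta to")
  dimImg <- attr(cells, "dim.image")
  ownerMap <- matrix(0L, dimImg[1], dimImg[2])
  for (i in seq_len(nrow(cells))) ownerMap[cells$region[[i]]] <- cells$label[i]
  own <- if (nrow(redPuncta)) {
    ownerMap[cbind(pmin(pmax(round(redPuncta$row), 1L), dimImg[1]),
                   pmin(pmax(round(redPuncta$col), 1L), dimImg[2]))]
  } else integer(0)
  assigned <- own > 0L
  nRed <- tabulate(own[assigned][redPuncta$colorClass[assigned] == "red_only"],
                   nbins = max(cells$label))
  nYel <- tabulate(own[assigned][redPuncta$colorClass[assigned] == "yellow"],
                   nbins = max(cells$label))
  perCell <- data.frame(cell = cells$label,
                        nRedOnly = nRed[cells$label],
                        nYellow = nYel[cells$label])
  perCell$ratio <- ifelse(perCell$nYellow >= 1L,
                          perCell$nRedOnly / perCell$nYellow, NA_real_)
  incl <- !is.na(perCell$ratio)
  flags <- character(0)
  if (!any(incl)) flags <- c(flags, "no_yellow_puncta")
  meanR <- if (any(incl)) mean(perCell$ratio[incl]) else NA_real_
  semR <- if (sum(incl) > 1)
    stats::sd(perCell$ratio[incl]) / sqrt(sum(incl)) else NA_real_
  totYel <- sum(perCell$nYellow)
  pooled <- if (totYel > 0) sum(perCell$nRedOnly) / totYel else {
    flags <- unique(c(flags, "no_yellow_puncta"))
    Inf
  }
  if (nrow(cells) < cfg$minCellsAnalyzed) flags <- c(flags, "few_cells")
  new("FluxSummary", perCell = perCell, meanRatio = meanR, semRatio = semR,
      pooledRatio = pooled, nCellsAnalyzed = sum(incl),
      nCellsExcluded = sum(!incl), flags = flags)
}

#' Run the full tandem flux pipeline on one field
#'
#' Segments nuclei and cell regions, builds the red/green punctum masks
#' with [preprocessMask()], classifies red puncta and returns the
#' [FluxSummary-class].
#'
#' @param field [LabeledField-class] with `red`, `green`, `nuclear`
#'   channels.
#' @param cfg a [tandemConfig()].
#' @param hcsCfg an [hcsConfig()] (nuclei segmentation and cell radius).
#' @return list with `cells`, `redPuncta`, `greenPuncta`, `summary`.
#' @export
analyzeTandemField <- function(field, cfg = tandemConfig(),
                               hcsCfg = hcsConfig(cellRadius = 12)) {
  labels <- segmentNuclei(field, hcsCfg)
  cells <- defineCellRegions(labels, hcsCfg$cellRadius)
  chMask <- function(role) {
    m <- preprocessMask(getChannel(field, role), cfg)
    if (isTRUE(cfg$regularize)) m <- majorityRegularize(m)
    m
  }
  red <- findPuncta(chMask("red"), cfg)
  green <- findPuncta(chMask("green"), cfg)
  red <- classifyRedYellow(red, green, fieldDim(field),
                           cfg$yellowOverlapThreshold)
  list(cells = cells, redPuncta = red, greenPuncta = green,
       summary = fluxRatio(red, cells, cfg))
}

#' Lysotracker mean-intensity metric per image
#'
#' `metric = (mean gray of the unadjusted dye channel - mean background)
#' / number of nuclei`. The cell-free background mask is the set of dye
#' pixels below the channel's Otsu threshold, eroded by `ltrErosion`
#' pixels; nuclei are counted with [segmentNuclei()] on the nuclear
#' channel.
#'
#' @param field [LabeledField-class] with `ltr` and `nuclear` channels.
#' @param cfg a [tandemConfig()].
#' @param hcsCfg an [hcsConfig()] for the nuclei count.
#' @param control optional control [LtrResult-class] (or numeric metric)
#'   for normalization.
#' @return an [LtrResult-class].
#' @export
ltrMetric <- function(field, cfg = tandemConfig(), hcsCfg = hcsConfig(),
                      control = NULL) {
  ltr <- getChannel(field, "ltr")
  meanGray <- mean(ltr)
  thr <- otsuThreshold(ltr)
  bgMask <- if (is.finite(thr)) ltr <= thr else
    matrix(TRUE, nrow(ltr), ncol(ltr))
  er <- erodeSquare(bgMask, cfg$ltrErosion)
  if (any(er)) bgMask <- er  # keep the uneroded mask if erosion empties it
  bgMean <- mean(ltr[bgMask])
  lab <- segmentNuclei(field, hcsCfg)
  nN <- attr(lab, "n")
  flags <- character(0)
  metric <- if (nN >= 1L) (meanGray - bgMean) / nN else {
    flags <- "no_nuclei"
    NA_real_
  }
  norm <- NA_real_
  if (!is.null(control)) {
    cm <- if (is(control, "LtrResult")) control@metric else as.numeric(control)
    norm <- metric / cm
  }
  new("LtrResult", meanGray = meanGray, backgroundMean = bgMean,
      nNuclei = as.integer(nN), metric = metric,
      normalizedToControl = norm, flags = flags)
}
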