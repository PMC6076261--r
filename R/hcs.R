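# High-content-screen quantification: nuclei -> radius-limited cell
# regions -> live/dead by viability-stain overlap -> puncta with a
# form-factor filter -> per-field endpoints.

#' HCS analysis configuration
#'
#' All tunable parameters of the high-content pipeline, with the defaults
#' the package documents as its declared substitutes for the original
#' instrument's undisclosed algorithms.
#'
#' @param minNucleusArea smallest nuclear object kept, px.
#' @param nuclearThreshold fixed nuclear-channel threshold; `NULL` = Otsu.
#' @param splitTouching split touching nuclei by distance-transform
#'   watershed (requires the EBImage package).
#' @param cellRadius radius around each nucleus defining the cell border,
#'   px.
#' @param viabilityThreshold fixed viability-channel threshold; `NULL` =
#'   robust (median + `viabilityK` * MAD).
#' @param viabilityK robust-threshold multiplier for the viability channel.
#' @param deadOverlapThreshold overlap fraction at or above which a cell is
#'   dead (inclusive, per the "at least 50%" rule).
#' @param gfpMode `"background"` (median-filtered background subtraction,
#'   robust-SD threshold) or `"fixed"` (absolute threshold
#'   `gfpThreshold`).
#' @param gfpWindow median-filter window for the background estimate, px.
#' @param gfpSigma smoothing scale (px) of the second branch of the
#'   two-scale positivity rule: a pixel is GFP-positive only if it clears
#'   the robust threshold both in the raw and in the Gaussian-smoothed
#'   background-subtracted image (suppresses isolated shot-noise pixels);
#'   `0` disables the smoothed branch.
#' @param gfpK threshold in robust SDs above the subtracted background.
#' @param gfpThreshold absolute threshold for `gfpMode = "fixed"`.
#' @param gfpRegularize apply a 3x3 majority vote to the positivity mask
#'   (boundary regularization; only in `"background"` mode).
#' @param minArea smallest punctum area kept (px, >= 1).
#' @param minFormFactor form-factor cutoff in `(0, pi/4]`.
#' @param minPuncta puncta count (comparator `>=`) defining a
#'   puncta-positive live cell.
#' @return named list of settings.
#' @export
hcsConfig <- function(minNucleusArea = 20L, nuclearThreshold = NULL,
                      splitTouching = FALSE, cellRadius = 30,
                      viabilityThreshold = NULL, viabilityK = 6,
                      deadOverlapThreshold = 0.5, gfpMode = "background",
                      gfpWindow = 15L, gfpSigma = 0.8, gfpK = 4,
                      gfpThreshold = NULL, gfpRegularize = TRUE,
                      minArea = 1L, minFormFactor = 0.4, minPuncta = 5L) {
  list(minNucleusArea = minNucleusArea, nuclearThreshold = nuclearThreshold,
       splitTouching = splitTouching, cellRadius = cellRadius,
       viabilityThreshold = viabilityThreshold, viabilityK = viabilityK,
       deadOverlapThreshold = deadOverlapThreshold, gfpMode = gfpMode,
       gfpWindow = gfpWindow, gfpSigma = gfpSigma, gfpK = gfpK,
       gfpThreshold = gfpThreshold, gfpRegularize = gfpRegularize,
       minArea = minArea, minFormFactor = minFormFactor,
       minPuncta = minPuncta)
}

#' Segment nuclei from the nuclear-stain channel
#'
#' Global (Otsu by default) threshold, hole filling, removal of objects
#' below `minNucleusArea`, 8-connected labeling; optionally a
#' distance-transform watershed split for touching nuclei.
#'
#' @param field a [LabeledField-class] with a `nuclear` channel.
#' @param cfg an [hcsConfig()].
#' @return integer label matrix (0 = background) with attribute `n`.
#' @export
segmentNuclei <- function(field, cfg = hcsConfig()) {
  img <- getChannel(field, "nuclear")
  thr <- cfg$nuclearThreshold
  if (is.null(thr)) thr <- otsuThreshold(img)
  if (!is.finite(thr) || !any(img > thr)) {
    warning("nuclear channel has no signal above threshold; empty labeling")
    lab <- matrix(0L, nrow(img), ncol(img)); attr(lab, "n") <- 0L
    return(lab)
  }
  mask <- fillHoles(img > thr)
  if (isTRUE(cfg$splitTouching)) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("splitTouching requires the EBImage package")
    d <- EBImage::distmap(mask)
    lab0 <- EBImage::watershed(d)
    mask <- lab0 > 0  # relabel below under the package's 8-conn convention
    # keep the watershed separations: zero out ridge lines
    ridge <- mask & (shiftMatrix(lab0, 0L, 1L, 0L) != lab0 |
                     shiftMatrix(lab0, 1L, 0L, 0L) != lab0) &
             shiftMatrix(lab0, 0L, 1L, 0L) > 0 & shiftMatrix(lab0, 1L, 0L, 0L) > 0
    mask[ridge] <- FALSE
  }
  lab <- labelComponents(mask, connectivity = 8)
  n <- attr(lab, "n")
  if (n == 0L) return(lab)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(areas >= cfg$minNucleusArea)
  newId <- integer(n)
  newId[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- newId[lab[pos]]
  attr(out, "n") <- length(keep)
  out
}

#' Define radius-limited cell regions around nuclei
#'
#' Each cell's region is the set of pixels within `radiusPx` of its
#' nucleus centroid that are nearer (Euclidean) to this centroid than to
#' any other (a Voronoi-limited digital disc, clipped to the image).
#' Regions are pairwise disjoint; ties go to the lower label; every
#' nucleus pixel belongs to its own cell's region.
#'
#' @param labels nuclear label matrix from [segmentNuclei()].
#' @param radiusPx cell radius in pixels (> 0).
#' @return data.frame with one row per cell: `label`, `row`, `col`
#'   (nucleus centroid), and list-columns `nucleusPixels` and `region`
#'   (linear pixel indices); attribute `dim` carries the image size.
#' @export
defineCellRegions <- function(labels, radiusPx) {
  if (radiusPx <= 0) stop("radiusPx must be > 0")
  n <- attr(labels, "n")
  if (is.null(n)) n <- max(0L, max(labels))
  nr <- nrow(labels); nc <- ncol(labels)
  empty <- data.frame(label = integer(0), row = numeric(0), col = numeric(0))
  if (n == 0L) {
    empty$nucleusPixels <- list(); empty$region <- list()
    attr(empty, "dim.image") <- c(nr, nc)
    return(empty)
  }
  idx <- which(labels > 0L)
  lb <- labels[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  crow <- as.numeric(tapply(rows, lb, mean))
  ccol <- as.numeric(tapply(cols, lb, mean))
  bestDist <- matrix(Inf, nr, nc)
  bestLab <- matrix(0L, nr, nc)
  for (i in seq_len(n)) {
    ri <- max(1L, floor(crow[i] - radiusPx)):min(nr, ceiling(crow[i] + radiusPx))
    ci <- max(1L, floor(ccol[i] - radiusPx)):min(nc, ceiling(ccol[i] + radiusPx))
    d2 <- outer((ri - crow[i])^2, (ci - ccol[i])^2, "+")
    upd <- d2 <= radiusPx^2 & d2 < bestDist[ri, ci]
    sub <- bestLab[ri, ci]; sub[upd] <- i
    bestLab[ri, ci] <- sub
    subd <- bestDist[ri, ci]; subd[upd] <- d2[upd]
    bestDist[ri, ci] <- subd
  }
  bestLab[idx] <- lb  # nucleus pixels always belong to their own cell
  nucPix <- split(idx, lb)
  regPix <- split(which(bestLab > 0L), bestLab[bestLab > 0L])
  cells <- data.frame(label = seq_len(n), row = crow, col = ccol)
  cells$nucleusPixels <- unname(nucPix[as.character(seq_len(n))])
  cells$region <- unname(regPix[as.character(seq_len(n))])
  attr(cells, "dim.image") <- c(nr, nc)
  cells
}

#' Classify cells live/dead by viability-stain overlap
#'
#' The viability (EthD1) mask is the viability channel above a threshold
#' (robust median + k*MAD by default); a cell is dead iff the fraction of
#' its region covered by the mask is at least `deadOverlapThreshold`
#' (inclusive: exactly 50% overlap is dead).
#'
#' @param cells cell table from [defineCellRegions()].
#' @param field the [LabeledField-class] (needs a `viability` channel).
#' @param deadOverlapThreshold dead-call threshold in `(0, 1]`.
#' @param cfg an [hcsConfig()] (threshold settings).
#' @return `cells` with added columns `ethd1Overlap` and `viability`
#'   (`"live"`/`"dead"`).
#' @export
classifyViability <- function(cells, field, deadOverlapThreshold = 0.5,
                              cfg = hcsConfig()) {
  if (deadOverlapThreshold <= 0 || deadOverlapThreshold > 1)
    stop("deadOverlapThreshold must be in (0, 1]")
  img <- getChannel(field, "viability")
  thr <- cfg$viabilityThreshold
  if (is.null(thr))
    thr <- stats::median(img) + cfg$viabilityK * robustSD(img)
  mask <- img > thr
  ov <- vapply(cells$region, function(px) {
    if (!length(px)) stop("empty cell region")
    mean(mask[px])
  }, numeric(1))
  cells$ethd1Overlap <- ov
  cells$viability <- ifelse(ov >= deadOverlapThreshold, "dead", "live")
  cells
}

# binary punctum mask for the GFP channel per configuration
gfpPositiveMask <- function(img, cfg) {
  if (identical(cfg$gfpMode, "fixed")) {
    if (is.null(cfg$gfpThreshold))
      stop("gfpMode 'fixed' needs gfpThreshold")
    return(img > cfg$gfpThreshold)
  }
  bgnd <- medianBackground(img, window = cfg$gfpWindow)
  resid <- img - bgnd
  mask <- resid > cfg$gfpK * robustSD(resid)
  if (cfg$gfpSigma > 0) {
    # two-scale rule: a positive pixel must also clear the threshold after
    # smoothing, which removes isolated shot-noise pixels while leaving
    # multi-pixel puncta intact
    sm <- gaussianBlur(resid, cfg$gfpSigma)
    mask <- mask & (sm > cfg$gfpK * robustSD(sm))
  }
  if (isTRUE(cfg$gfpRegularize)) mask <- majorityRegularize(mask)
  mask
}

#' Detect GFP puncta and assign them to cells
#'
#' Builds the GFP-positive mask (median-background subtraction with a
#' robust-SD threshold by default), labels 8-connected components, keeps
#' those with area `>= minArea` and form factor `>= minFormFactor`
#' (edge-count perimeter convention), and assigns each punctum to the cell
#' whose region contains its centroid (unassigned otherwise).
#'
#' @param field [LabeledField-class] with a `gfp` channel.
#' @param cells cell table from [defineCellRegions()] (may already carry
#'   viability calls).
#' @param cfg an [hcsConfig()].
#' @return list with `puncta` (data.frame: `area`, `perimeter`,
#'   `formFactor`, `row`, `col`, `cell` with `NA` = unassigned, and a
#'   `pixels` list-column) and `cells` (input with an `nPuncta` column).
#' @export
detectPuncta <- function(field, cells, cfg = hcsConfig()) {
  if (cfg$minArea < 1) stop("minArea must be >= 1")
  if (cfg$minFormFactor <= 0 || cfg$minFormFactor > pi / 4 + 1e-12)
    stop("minFormFactor must be in (0, pi/4]")
  img <- getChannel(field, "gfp")
  mask <- gfpPositiveMask(img, cfg)
  res <- maskToPuncta(mask, minArea = cfg$minArea,
                      minFormFactor = cfg$minFormFactor)
  nr <- nrow(img)
  ownerMap <- matrix(0L, nr, ncol(img))
  for (i in seq_len(nrow(cells))) ownerMap[cells$region[[i]]] <- cells$label[i]
  if (nrow(res)) {
    ctr <- cbind(pmin(pmax(round(res$row), 1L), nr),
                 pmin(pmax(round(res$col), 1L), ncol(img)))
    own <- ownerMap[ctr]
    res$cell <- ifelse(own > 0L, own, NA_integer_)
  } else res$cell <- integer(0)
  counts <- tabulate(res$cell[!is.na(res$cell)], nbins = max(cells$label, 0L))
  cells$nPuncta <- if (nrow(cells)) counts[cells$label] else integer(0)
  list(puncta = res, cells = cells)
}

# label a punctum mask and measure area / perimeter / form factor
maskToPuncta <- function(mask, minArea = 1L, minFormFactor = 0) {
  lab <- labelComponents(mask, connectivity = 8)
  n <- attr(lab, "n")
  nr <- nrow(mask)
  if (n == 0L) {
    out <- data.frame(area = integer(0), perimeter = integer(0),
                      formFactor = numeric(0), row = numeric(0),
                      col = numeric(0))
    out$pixels <- list()
    return(out)
  }
  idx <- which(lab > 0L)
  lb <- lab[idx]
  areas <- tabulate(lb, nbins = n)
  per <- perimeterEdges(lab)
  ff <- 4 * pi * areas / per^2
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  crow <- as.numeric(tapply(rows, lb, mean))
  ccol <- as.numeric(tapply(cols, lb, mean))
  keep <- which(areas >= minArea & ff >= minFormFactor - 1e-12)
  out <- data.frame(area = areas[keep], perimeter = per[keep],
                    formFactor = ff[keep], row = crow[keep],
                    col = ccol[keep])
  pix <- split(idx, lb)
  out$pixels <- unname(pix[as.character(keep)])
  out
}

#' Summarize a field: puncta-positive fraction of live cells
#'
#' `fracPositive` is the fraction of live cells with at least `minPuncta`
#' puncta (5 for the screening endpoint; 1 for the tissue "puncta
#' positive" reading). With control summaries supplied, the value is also
#' normalized to the mean control fraction. A field with no live cells
#' yields `NA` with an explicit `"no_live_cells"` flag, never a silent
#' zero.
#'
#' @param cells cell table carrying `viability` and `nPuncta` columns.
#' @param minPuncta positivity threshold (comparator `>=`).
#' @param controlSummaries optional list of [FieldSummary-class] objects
#'   (or numeric fractions) from control wells.
#' @return a [FieldSummary-class].
#' @export
summarizeField <- function(cells, minPuncta = 5L, controlSummaries = NULL) {
  if (!all(c("viability", "nPuncta") %in% names(cells)))
    stop("cells must carry viability and nPuncta (run classifyViability ",
         "and detectPuncta first)")
  live <- cells$viability == "live"
  counts <- as.integer(cells$nPuncta[live])
  flags <- character(0)
  frac <- if (any(live)) mean(counts >= minPuncta) else {
    flags <- "no_live_cells"
    NA_real_
  }
  norm <- NA_real_
  if (!is.null(controlSummaries)) {
    cf <- vapply(controlSummaries, function(s)
      if (is(s, "FieldSummary")) s@fracPositive else as.numeric(s),
      numeric(1))
    norm <- frac / mean(cf)
  }
  new("FieldSummary", nCells = nrow(cells), nLive = sum(live),
      nDead = sum(!live), punctaPerLiveCell = counts,
      minPuncta = as.integer(minPuncta), fracPositive = frac,
      normalizedValue = norm, flags = flags)
}

#' Run the full HCS pipeline on one field
#'
#' Convenience wrapper: [segmentNuclei()], [defineCellRegions()],
#' [classifyViability()], [detectPuncta()], [summarizeField()].
#'
#' @param field a [LabeledField-class] with `nuclear`, `viability` and
#'   `gfp` channels.
#' @param cfg an [hcsConfig()].
#' @param controlSummaries passed to [summarizeField()].
#' @return list with `labels`, `cells`, `puncta`, `summary`.
#' @export
analyzeHcsField <- function(field, cfg = hcsConfig(),
                            controlSummaries = NULL) {
  labels <- segmentNuclei(field, cfg)
  cells <- defineCellRegions(labels, cfg$cellRadius)
  cells <- classifyViability(cells, field, cfg$deadOverlapThreshold, cfg)
  det <- detectPuncta(field, cells, cfg)
  list(labels = labels, cells = det$cells, puncta = det$puncta,
       summary = summarizeField(det$cells, cfg$minPuncta, controlSummaries))
}
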