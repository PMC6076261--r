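# Pixel-level kernels shared by the imaging modules.
#
# Conventions (fixed, and audited against brute-force oracles in the test
# suite): objects are 8-connected (4-connected available for background /
# hole work), the perimeter of a pixel region is the count of 4-neighbor
# edges between a region pixel and a non-region pixel with the image border
# counting as non-region, and all grids are 1-based (row, col).

# value of the (dr, dc)-neighbor of every pixel; `fill` outside the image
shiftMatrix <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr) + dr
  ci <- seq_len(nc) + dc
  vr <- ri >= 1L & ri <= nr
  vc <- ci >= 1L & ci <= nc
  if (any(vr) && any(vc)) out[vr, vc] <- m[ri[vr], ci[vc]]
  out
}

#' Label connected components
#'
#' Labels connected foreground components of a binary mask. Components are
#' numbered 1..K by the column-major position of their first pixel, so the
#' labeling is canonical and reproducible. Uses vertical-run encoding with
#' union-find, which is exact and fast even for large sprawling components.
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @param connectivity 8 (default, objects) or 4 (background convention).
#' @return integer matrix of labels (0 = background) with attribute `n`,
#'   the number of components.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
#' attr(labelComponents(m), "n")       # 1 (8-connected)
#' attr(labelComponents(m, 4), "n")    # 2
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) { attr(lab, "n") <- 0L; return(lab) }

  # vertical runs per column, found on a row-padded copy
  mp <- rbind(FALSE, mask, FALSE)
  vp <- as.vector(mp)
  len <- length(vp)
  starts <- which(vp & !c(FALSE, vp[-len]))
  ends   <- which(!vp & c(FALSE, vp[-len])) - 1L
  runCol <- (starts - 1L) %/% (nr + 2L) + 1L
  runRs  <- (starts - 1L) %% (nr + 2L)      # padded row - 1 == true row
  runRe  <- (ends   - 1L) %% (nr + 2L)
  nRuns <- length(starts)

  parent <- seq_len(nRuns)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8) 1L else 0L

  # runs are ordered by (col, row); link each run to overlapping runs in the
  # previous column with a two-pointer sweep
  cnt <- tabulate(runCol, nbins = nc)
  lastRun <- cumsum(cnt)
  firstRun <- lastRun - cnt + 1L
  for (j in seq_len(nc)[-1]) {
    if (cnt[j] == 0L || cnt[j - 1L] == 0L) next
    a <- firstRun[j]; aEnd <- lastRun[j]
    b <- firstRun[j - 1L]; bEnd <- lastRun[j - 1L]
    bi <- b
    for (ai in a:aEnd) {
      while (bi <= bEnd && runRe[bi] < runRs[ai] - slack) bi <- bi + 1L
      bj <- bi
      while (bj <= bEnd && runRs[bj] <= runRe[ai] + slack) {
        ra <- findRoot(ai); rb <- findRoot(bj)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        bj <- bj + 1L
      }
    }
  }

  roots <- vapply(seq_len(nRuns), findRoot, integer(1))
  # canonical numbering: components ordered by first run (column-major order)
  lbl <- match(roots, unique(roots))
  lens <- runRe - runRs + 1L
  base <- (runCol - 1L) * nr + runRs
  idx <- rep.int(base, lens) + sequence(lens) - 1L
  lab[idx] <- rep.int(lbl, lens)
  attr(lab, "n") <- max(lbl)
  lab
}

#' Per-component boundary-edge perimeter
#'
#' Counts, for every labeled component, the 4-neighbor edges between a
#' component pixel and a non-component pixel (other labels, background, or
#' the image border). This is the perimeter convention under which the
#' form factor of a digital shape is bounded by pi/4.
#'
#' @param lab integer label matrix as from [labelComponents()].
#' @return integer vector of perimeters, one per label 1..K.
#' @export
perimeterEdges <- function(lab) {
  n <- attr(lab, "n")
  if (is.null(n)) n <- max(0L, max(lab))
  if (n == 0L) return(integer(0))
  per <- integer(n)
  for (s in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- shiftMatrix(lab, s[1], s[2], 0L)
    edge <- lab > 0L & nb != lab
    per <- per + tabulate(lab[edge], nbins = n)
  }
  per
}

#' Form factor (circularity) of pixel regions
#'
#' `FF = 4 * pi * A / P^2` with `A` the pixel count and `P` the 4-neighbor
#' boundary-edge count. Under this convention a single pixel and any filled
#' square score `pi/4 ~ 0.785` (the maximum) and elongated shapes score low;
#' the conventional cutoff 0.4 separates compact puncta from streaks.
#'
#' @param pixels two-column matrix of (row, col) pixel coordinates of one
#'   region, or a list of such matrices.
#' @return numeric form factor(s) in `(0, pi/4]`.
#' @examples
#' formFactor(cbind(1, 1))                      # single pixel: ~0.785
#' formFactor(as.matrix(expand.grid(1:3, 1:3))) # 3x3 square: ~0.785
#' @export
formFactor <- function(pixels) {
  if (is.list(pixels) && !is.matrix(pixels))
    return(vapply(pixels, formFactor, numeric(1)))
  if (!is.matrix(pixels) || ncol(pixels) != 2 || nrow(pixels) == 0)
    stop("pixels must be a nonempty two-column (row, col) matrix")
  r <- pixels[, 1] - min(pixels[, 1]) + 2L
  cc <- pixels[, 2] - min(pixels[, 2]) + 2L
  m <- matrix(FALSE, max(r) + 1L, max(cc) + 1L)
  m[cbind(r, cc)] <- TRUE
  a <- nrow(pixels)
  lab <- matrix(0L, nrow(m), ncol(m)); lab[m] <- 1L
  attr(lab, "n") <- 1L
  p <- perimeterEdges(lab)
  4 * pi * a / p^2
}

#' Separable Gaussian blur
#'
#' Smooths an intensity matrix with a Gaussian kernel (radius
#' `ceiling(3 * sigma)`), replicate padding at the borders.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `0` returns the input.
#' @return smoothed matrix of the same size.
#' @export
gaussianBlur <- function(img, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {  # along rows (vertical)
    nr <- nrow(m)
    acc <- matrix(0, nr, ncol(m))
    for (o in -r:r) {
      idx <- pmin(pmax(seq_len(nr) + o, 1L), nr)
      acc <- acc + k[o + r + 1L] * m[idx, , drop = FALSE]
    }
    acc
  }
  t(blur1(t(blur1(img))))
}

# window sums via integral image; pad = "replicate" or "zero"
localSum <- function(img, block, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  if (block %% 2 != 1 || block < 1) stop("block must be odd and >= 1")
  r <- (block - 1L) / 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(seq_len(nr + 2L * r) - r, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * r) - r, 1L), nc)
  P <- img[ri, ci, drop = FALSE]
  if (pad == "zero" && r > 0) {
    P[c(seq_len(r), nr + r + seq_len(r)), ] <- 0
    P[, c(seq_len(r), nc + r + seq_len(r))] <- 0
  }
  I <- apply(rbind(0, P), 2, cumsum)
  I <- t(apply(cbind(0, I), 1, cumsum))
  i <- seq_len(nr); j <- seq_len(nc)
  I[i + 2L * r + 1L, j + 2L * r + 1L, drop = FALSE] -
    I[i, j + 2L * r + 1L, drop = FALSE] -
    I[i + 2L * r + 1L, j, drop = FALSE] + I[i, j, drop = FALSE]
}

#' Local (moving-window) mean
#'
#' Box mean over an odd `block`-sized square window with replicate padding;
#' the workhorse of the adaptive threshold in [preprocessMask()].
#'
#' @param img numeric matrix.
#' @param block odd window size in pixels.
#' @return matrix of local means, same size as `img`.
#' @export
localMean <- function(img, block) localSum(img, block) / block^2

#' Otsu threshold
#'
#' Classic histogram threshold maximizing between-class variance. Returns a
#' value `t` such that foreground is `img > t`. A constant image returns
#' `Inf` (no foreground).
#'
#' @param img numeric matrix or vector.
#' @param levels number of histogram bins.
#' @export
otsuThreshold <- function(img, levels = 256L) {
  x <- as.numeric(img)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(Inf)
  br <- seq(lo, hi, length.out = levels + 1L)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), levels),
                nbins = levels)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mt <- cm[levels]
  valid <- cw > 0 & cw < 1
  bc <- rep(-Inf, levels)
  bc[valid] <- (mt * cw[valid] - cm[valid])^2 / (cw[valid] * (1 - cw[valid]))
  br[which.max(bc) + 1L]
}

#' Fill holes in a binary mask
#'
#' Background components (4-connected, the complement convention) that do
#' not touch the image border are turned into foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix with interior holes filled.
#' @export
fillHoles <- function(mask) {
  mask <- mask > 0
  bg <- labelComponents(!mask, connectivity = 4)
  nbg <- attr(bg, "n")
  if (nbg == 0L) return(mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  hole <- setdiff(seq_len(nbg), border)
  if (length(hole)) mask[bg %in% hole] <- TRUE
  mask
}

#' Binary erosion by a square structuring element
#'
#' Erodes a mask with a `(2r+1) x (2r+1)` square; pixels beyond the border
#' count as background, so the mask retreats from the image edge too.
#'
#' @param mask logical matrix.
#' @param r erosion radius in pixels (`0` returns the input).
#' @export
erodeSquare <- function(mask, r = 1L) {
  if (r <= 0) return(mask > 0)
  block <- 2L * r + 1L
  localSum((mask > 0) * 1, block, pad = "zero") >= block^2 - 0.5
}

# smooth background estimate: window medians on a coarse grid, bilinearly
# interpolated to the full image (background varies on scales >> gridStep)
medianBackground <- function(img, window = 15L, gridStep = 4L) {
  nr <- nrow(img); nc <- ncol(img)
  r <- (window - 1L) %/% 2L
  rs <- unique(c(seq(1L, nr, by = gridStep), nr))
  cs <- unique(c(seq(1L, nc, by = gridStep), nc))
  B <- matrix(0, length(rs), length(cs))
  for (a in seq_along(rs)) {
    ri <- max(1L, rs[a] - r):min(nr, rs[a] + r)
    sub <- img[ri, , drop = FALSE]
    for (b in seq_along(cs)) {
      ci <- max(1L, cs[b] - r):min(nc, cs[b] + r)
      B[a, b] <- stats::median(sub[, ci])
    }
  }
  if (length(rs) == 1L && length(cs) == 1L)
    return(matrix(B[1, 1], nr, nc))
  M1 <- if (length(rs) > 1L) {
    apply(B, 2, function(col) stats::approx(rs, col, xout = seq_len(nr),
                                            rule = 2)$y)
  } else matrix(rep(B[1, ], each = nr), nr)
  if (length(cs) > 1L) {
    t(apply(M1, 1, function(row) stats::approx(cs, row, xout = seq_len(nc),
                                               rule = 2)$y))
  } else matrix(M1[, 1], nr, nc)
}

# robust SD via scaled median absolute deviation
robustSD <- function(x) stats::mad(as.numeric(x))

#' Majority-vote mask regularization
#'
#' Keeps a pixel iff at least 5 of the 9 pixels in its 3x3 neighborhood
#' (itself included; outside the image counts as background) are
#' foreground. Smooths noise-ragged component boundaries — which matters
#' because the edge-count perimeter, and hence the form factor, is
#' sensitive to single-pixel raggedness — and removes isolated positive
#' pixels.
#'
#' @param mask logical matrix.
#' @return regularized logical mask.
#' @export
majorityRegularize <- function(mask) {
  localSum((mask > 0) * 1, 3L, pad = "zero") >= 5
}
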