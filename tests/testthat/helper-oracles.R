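# Independent brute-force oracles. Deliberately naive implementations
# (stack-based flood fill, per-pixel edge counting) kept free of any code
# shared with the package's vectorized kernels.

floodFillOracle <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); k <- 0L
  offs <- if (connectivity == 8) {
    cbind(dr = rep(-1:1, 3), dc = rep(-1:1, each = 3))[-5, ]
  } else cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      k <- k + 1L
      stack <- list(c(i, j)); lab[i, j] <- k
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (s in seq_len(nrow(offs))) {
          ii <- p[1] + offs[s, 1]; jj <- p[2] + offs[s, 2]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- k
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  attr(lab, "n") <- k
  lab
}

# per-label 4-neighbor boundary edge count, one pixel at a time
perimeterOracle <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(integer(0))
  nr <- nrow(lab); nc <- ncol(lab)
  per <- integer(n)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    l <- lab[i, j]
    if (l == 0L) next
    for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + s[1]; jj <- j + s[2]
      outside <- ii < 1 || ii > nr || jj < 1 || jj > nc || lab[ii, jj] != l
      if (outside) per[l] <- per[l] + 1L
    }
  }
  per
}

# direct evaluation of the adaptive-threshold inequality with replicate
# padding, pixel by pixel
localMeanOracle <- function(img, block) {
  r <- (block - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    acc <- 0
    for (dj in -r:r) for (di in -r:r) {
      ii <- min(max(i + di, 1), nr); jj <- min(max(j + dj, 1), nc)
      acc <- acc + img[ii, jj]
    }
    out[i, j] <- acc / block^2
  }
  out
}

# match analyzed cells to ground-truth cells by nearest center
matchCellsToTruth <- function(cells, truthCells) {
  vapply(seq_len(nrow(cells)), function(i) {
    which.min((truthCells$row - cells$row[i])^2 +
              (truthCells$col - cells$col[i])^2)
  }, integer(1))
}

# F1 of per-cell punctum counts against ground truth
punctumCountF1 <- function(detected, truth) {
  2 * sum(pmin(detected, truth)) / (sum(detected) + sum(truth))
}
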