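# Independent oracles, implemented naively and separately from the package
# code paths they check.

# Exhaustive window-scan spot detector: for every pixel whose full box fits
# in the image, extract the window, test "pixel is the window maximum" and
# "peak - mean(4 corners) > tol", then apply the same acceptance rule as the
# published contract (greedy by peak, ties row-major; no two accepted spots
# within one box window, i.e. Chebyshev distance < boxSize).
bruteForceSpots <- function(image, mask, boxSize, tol) {
  h <- (boxSize - 1L) %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  rows <- integer(); cols <- integer(); peaks <- numeric(); proms <- numeric()
  for (r in seq.int(1L + h, nr - h)) {
    for (co in seq.int(1L + h, nc - h)) {
      if (!mask[r, co]) next
      win <- image[(r - h):(r + h), (co - h):(co + h)]
      if (image[r, co] < max(win)) next
      cornerMean <- (win[1L, 1L] + win[1L, boxSize] +
                     win[boxSize, 1L] + win[boxSize, boxSize]) / 4
      prom <- image[r, co] - cornerMean
      if (prom > tol) {
        rows <- c(rows, r); cols <- c(cols, co)
        peaks <- c(peaks, image[r, co]); proms <- c(proms, prom)
      }
    }
  }
  if (!length(rows))
    return(data.frame(row = integer(), col = integer(),
                      peak = numeric(), prominence = numeric()))
  ord <- order(-peaks, rows, cols)
  accR <- integer(); accC <- integer(); accI <- integer()
  for (k in ord) {
    ok <- TRUE
    for (j in accI) {
      if (max(abs(rows[j] - rows[k]), abs(cols[j] - cols[k])) < boxSize) {
        ok <- FALSE; break
      }
    }
    if (ok) accI <- c(accI, k)
  }
  out <- data.frame(row = rows[accI], col = cols[accI],
                    peak = peaks[accI], prominence = proms[accI])
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive tetramer enumeration: all 2^4 labelled subunit assignments with
# per-slot probability fA of drawing an A subunit, tallied by A-count.
enumerateTetramers <- function(fA) {
  probs <- numeric(5L)
  for (s1 in 0:1) for (s2 in 0:1) for (s3 in 0:1) for (s4 in 0:1) {
    k <- s1 + s2 + s3 + s4
    w <- prod(ifelse(c(s1, s2, s3, s4) == 1, fA, 1 - fA))
    probs[k + 1L] <- probs[k + 1L] + w
  }
  probs
}

# Small-cell scene parameters used throughout the tests (a ~76 um^2 cell).
smallParams <- function(...) {
  args <- list(...)
  defaults <- list(imageShape = c(96L, 96L), cellAxes = c(36, 30), seed = 1L)
  do.call(sceneParams, utils::modifyList(defaults, args))
}

# A single-disk scene built directly (no RNG): one cluster of radius
# `radiusUm` and density `density` at the cell centre.
singleDiskScene <- function(radiusUm = 0.45, density = 1e5,
                            diffuseLevel = 0, noiseSd = 0,
                            backgroundLevel = 100, coloc = TRUE) {
  p <- smallParams(clusterRate = 0, diffuseLevel = diffuseLevel,
                   noiseSd = noiseSd, backgroundLevel = backgroundLevel)
  scene <- makeScene(p)
  scene@clusters <- data.frame(row = 48, col = 48, radius_um = radiusUm,
                               density = density, coloc = coloc)
  a <- pi * radiusUm^2
  maskPx <- sum(cellMask(scene))
  ifsT <- diffuseLevel * maskPx + density * a
  scene@trueMetrics <- list(
    cell_area_um2 = maskPx * 0.15^2, ifs_t = ifsT,
    surface_expression = ifsT / (maskPx * 0.15^2),
    n_clusters_norm = 1 / (maskPx * 0.15^2),
    fraction_in_clusters = density * a / ifsT,
    mean_cluster_area_um2 = a, mean_cluster_density = density)
  methods::validObject(scene)
  scene
}
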