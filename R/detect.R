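# Local-maximum spot counting. A box of odd size scans the image; the pixel
# at the centre is a spot candidate when it is the maximum of its box and
# exceeds the mean of the box's four corner pixels by more than the noise
# tolerance. Corner-mean subtraction makes the detector invariant to global
# intensity offsets.

shiftMatrix <- function(m, dr, dc) {
  # shift so that out[i,j] = m[i+dr, j+dc]; NA where undefined
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr
  cs <- seq_len(nc) + dc
  okr <- rs >= 1L & rs <= nr
  okc <- cs >= 1L & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

#' Automatic noise tolerance from robust image statistics
#'
#' Three times the robust standard deviation (1.4826 x MAD) of the in-mask
#' intensities. Used when `noiseTolerance = "auto"` in [detectSpots()].
#'
#' @param image numeric intensity matrix.
#' @param mask logical matrix, TRUE inside the cell.
#' @return A non-negative scalar tolerance.
#' @export
autoNoiseTolerance <- function(image, mask) {
  3 * stats::mad(image[mask])
}

#' Detect clustering-site spots by box local maxima
#'
#' A pixel is reported iff (i) its full `boxSize` x `boxSize` window fits in
#' the image (border windows are skipped, since their corner pixels are
#' undefined), (ii) the pixel is the maximum of that window, (iii) its
#' prominence, the peak minus the mean of the window's four corner pixels,
#' strictly exceeds `noiseTolerance`, and (iv) it lies inside the cell mask.
#' Acceptances closer than one box (Chebyshev distance < `boxSize`) are
#' suppressed keeping the higher peak; equal peaks keep the row-major-first
#' pixel, making the output deterministic on plateaus.
#'
#' @param image numeric intensity matrix (the red, channel-associated signal).
#' @param mask logical matrix, TRUE inside the cell.
#' @param boxSize odd integer >= 3, not larger than either image dimension.
#' @param noiseTolerance non-negative scalar, or `"auto"` for
#'   [autoNoiseTolerance()].
#' @return data.frame with columns `row`, `col`, `peak`, `prominence`,
#'   sorted row-major. Zero rows when nothing is detected or the mask is
#'   empty.
#' @examples
#' img <- matrix(0, 9, 9); img[5, 5] <- 10
#' detectSpots(img, matrix(TRUE, 9, 9), boxSize = 3, noiseTolerance = 5)
#' @export
detectSpots <- function(image, mask, boxSize = 5L, noiseTolerance = "auto") {
  boxSize <- as.integer(boxSize)
  if (boxSize < 3L || boxSize %% 2L == 0L)
    stop("boxSize must be an odd integer >= 3")
  if (boxSize > min(dim(image)))
    stop("boxSize exceeds the image dimensions")
  empty <- data.frame(row = integer(), col = integer(),
                      peak = numeric(), prominence = numeric())
  if (!any(mask)) return(empty)
  if (identical(noiseTolerance, "auto"))
    noiseTolerance <- autoNoiseTolerance(image, mask)
  if (noiseTolerance < 0) stop("noiseTolerance must be >= 0")

  h <- (boxSize - 1L) %/% 2L
  localMax <- matrix(-Inf, nrow(image), ncol(image))
  for (dr in -h:h)
    for (dc in -h:h)
      localMax <- pmax(localMax, shiftMatrix(image, dr, dc), na.rm = FALSE)
  cornerMean <- (shiftMatrix(image, -h, -h) + shiftMatrix(image, -h, h) +
                 shiftMatrix(image, h, -h) + shiftMatrix(image, h, h)) / 4
  prom <- image - cornerMean
  cand <- !is.na(localMax) & image == localMax & !is.na(prom) &
          prom > noiseTolerance & mask
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)

  peak <- image[idx]
  ord <- order(-peak, idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  peak <- peak[ord]
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    prior <- which(keep)
    if (!length(prior) ||
        all(pmax(abs(idx[prior, 1L] - idx[i, 1L]),
                 abs(idx[prior, 2L] - idx[i, 2L])) >= boxSize))
      keep[i] <- TRUE
  }
  idx <- idx[keep, , drop = FALSE]
  peak <- peak[keep]
  out <- data.frame(row = idx[, 1L], col = idx[, 2L], peak = peak,
                    prominence = prom[idx])
  out[order(out$row, out$col), , drop = FALSE]
}
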