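# Threshold-based segmentation of detected spots into bounded clustering
# sites, with background-corrected integrated signal (IFSc) per site.

#' Estimate the in-mask background intensity
#'
#' Median intensity over the in-mask pixels that do not belong to any
#' cluster; falls back to the median over the whole mask when the cluster
#' pixels cover it entirely.
#'
#' @param image numeric intensity matrix.
#' @param mask logical matrix, TRUE inside the cell.
#' @param clusterPixels logical matrix of pixels to exclude (or NULL).
#' @return Scalar background estimate.
#' @export
estimateBackground <- function(image, mask, clusterPixels = NULL) {
  if (!any(mask)) stop("cell mask is empty")
  sel <- if (is.null(clusterPixels)) mask else mask & !clusterPixels
  if (!any(sel)) sel <- mask
  stats::median(image[sel])
}

# Otsu threshold over the in-mask pixels only, via EBImage on the pixel
# vector packed as a one-row image (EBImage::otsu has no mask argument).
otsuMaskThreshold <- function(image, mask) {
  v <- image[mask]
  rg <- range(v)
  if (rg[1] == rg[2]) return(rg[1])
  EBImage::otsu(EBImage::Image(matrix(v, nrow = 1L)), range = rg, levels = 256L)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that touch
# diagonally are merged through the connected components of the label
# adjacency graph.
labelComponents <- function(bin, connectivity = 8L) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
  lab <- matrix(as.integer(lab), nrow(bin), ncol(bin))
  if (connectivity == 4L || max(lab) <= 1L) return(lab)
  pairs <- NULL
  for (dc in c(-1L, 1L)) {
    a <- lab[-nrow(lab), , drop = FALSE]
    b <- if (dc == 1L) lab[-1L, -1L, drop = FALSE] else lab[-1L, -ncol(lab), drop = FALSE]
    a <- if (dc == 1L) a[, -ncol(a), drop = FALSE] else a[, -1L, drop = FALSE]
    touch <- a > 0L & b > 0L & a != b
    if (any(touch)) pairs <- rbind(pairs, cbind(a[touch], b[touch]))
  }
  if (is.null(pairs)) return(lab)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pairs[, 1L]),
               to = as.character(pairs[, 2L])),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(max(lab)))))
  memb <- igraph::components(g)$membership
  relab <- as.integer(memb[as.character(seq_len(max(lab)))])
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Segment clustering sites around detected spots
#'
#' Pixels inside the mask with intensity strictly above the threshold form a
#' binary map; its 8-connected components that contain at least one detected
#' spot become clustering sites (spotless components are discarded; a
#' component holding several spots is one site). The background is the
#' median over in-mask pixels outside all retained sites, and each site's
#' IFSc is `max(0, sum(intensity - background))` over its pixels (the floor
#' is applied per site, not per pixel). Site ids are assigned row-major by
#' each component's first pixel.
#'
#' @param image numeric intensity matrix (red channel).
#' @param mask logical matrix, TRUE inside the cell.
#' @param spots data.frame from [detectSpots()] on the same image.
#' @param threshold numeric scalar, or `"auto"` for Otsu's method over the
#'   in-mask pixels.
#' @param pixelSizeUm microns per pixel, for physical areas.
#' @param greenImage optional registered scaffold channel; when supplied the
#'   `coloc` column is filled via [colocalize()] with `colocFactor`.
#' @param colocFactor ratio >= 1 for the co-localization rule (default 2).
#' @param connectivity 8 (default) or 4.
#' @return A [ClusterSet-class]. Empty (with a warning) when the threshold
#'   is at or above the image maximum.
#' @export
segmentClusters <- function(image, mask, spots, threshold = "auto",
                            pixelSizeUm, greenImage = NULL, colocFactor = 2,
                            connectivity = 8L) {
  stopifnot(pixelSizeUm > 0)
  if (identical(threshold, "auto")) threshold <- otsuMaskThreshold(image, mask)
  emptySet <- function(bg) new("ClusterSet",
    table = data.frame(cluster_id = integer(), n_pixels = integer(),
                       area_um2 = numeric(), ifs_c = numeric(),
                       density = numeric(), coloc = logical(),
                       n_spots = integer()),
    labels = matrix(0L, nrow(image), ncol(image)),
    background = bg, threshold = threshold, pixelSizeUm = pixelSizeUm)
  if (threshold >= max(image)) {
    warning("threshold at or above the image maximum; no clusters")
    return(emptySet(estimateBackground(image, mask)))
  }
  bin <- mask & image > threshold
  lab <- labelComponents(bin, connectivity)
  if (nrow(spots)) {
    spotLab <- lab[cbind(spots$row, spots$col)]
    keepIds <- unique(spotLab[spotLab > 0L])
  } else keepIds <- integer()
  if (!length(keepIds)) return(emptySet(estimateBackground(image, mask)))

  lab[!(lab %in% keepIds)] <- 0L
  bg <- estimateBackground(image, mask, clusterPixels = lab > 0L)

  # row-major rank of each component's first pixel (row-major scan order)
  nr <- nrow(lab)
  rowMajor <- (row(lab) - 1L) * ncol(lab) + col(lab)
  firstPix <- tapply(rowMajor[lab > 0L], lab[lab > 0L], min)
  ordIds <- as.integer(names(sort(firstPix)))

  pxArea <- pixelSizeUm^2
  spotLab <- if (nrow(spots)) lab[cbind(spots$row, spots$col)] else integer()
  rows <- lapply(seq_along(ordIds), function(k) {
    id <- ordIds[k]
    sel <- lab == id
    n <- sum(sel)
    ifsc <- max(0, sum(image[sel] - bg))
    area <- n * pxArea
    data.frame(cluster_id = k, n_pixels = n, area_um2 = area, ifs_c = ifsc,
               density = ifsc / area, coloc = NA,
               n_spots = sum(spotLab == id))
  })
  tab <- do.call(rbind, rows)
  # relabel the label image to the final row-major ids
  relab <- integer(max(ordIds))
  relab[ordIds] <- seq_along(ordIds)
  lab[lab > 0L] <- relab[lab[lab > 0L]]

  cs <- new("ClusterSet", table = tab, labels = lab, background = bg,
            threshold = threshold, pixelSizeUm = pixelSizeUm)
  if (!is.null(greenImage))
    cs <- colocalize(cs, greenImage, mask, factor = colocFactor)
  cs
}

#' Scaffold co-localization of clustering sites
#'
#' A site co-localizes with the scaffold when its mean green intensity
#' exceeds `factor` times the median in-mask green intensity.
#'
#' @param clusters a [ClusterSet-class].
#' @param greenImage scaffold-channel matrix registered with the red channel.
#' @param mask logical cell mask.
#' @param factor ratio >= 1 (default 2).
#' @return The [ClusterSet-class] with its `coloc` column filled.
#' @export
colocalize <- function(clusters, greenImage, mask, factor = 2) {
  stopifnot(factor >= 1)
  tab <- clusterTable(clusters)
  if (!nrow(tab)) return(clusters)
  ref <- stats::median(greenImage[mask])
  lab <- clusterLabels(clusters)
  meanGreen <- tapply(greenImage[lab > 0L], lab[lab > 0L], mean)
  tab$coloc <- as.logical(meanGreen[as.character(tab$cluster_id)] > factor * ref)
  clusters@table <- tab
  validObject(clusters)
  clusters
}
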