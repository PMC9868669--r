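# The five per-cell clustering metrics and their per-condition aggregation.

#' Compute the per-cell clustering metrics
#'
#' IFS_T is the camera-background-corrected total in-mask red signal,
#' `max(0, sum(red - cameraBackground))`, where the camera background is the
#' median intensity outside the cell mask (the image background; it falls
#' back to the in-mask estimate of the [ClusterSet-class] when the mask
#' covers the whole image). IFS_T thus keeps the diffuse, non-clustered
#' channel pool, while each site's IFSc (corrected by the in-mask, diffuse
#' inclusive background) measures the clustered excess — their ratio, the
#' fraction of channels in clusters, is the clustered share of all channel
#' signal (clipped to 1 against rounding). Surface expression is IFS_T per
#' square micron of mask and the normalized cluster count is sites per
#' square micron. With `rawIfsT = TRUE` the uncorrected total is used
#' instead.
#'
#' @param image a [CellImage-class].
#' @param clusters the [ClusterSet-class] segmented from the same image.
#' @param cellId character label for reports.
#' @param rawIfsT logical; use the uncorrected total signal (default FALSE).
#' @return A [CellMetrics-class]. A cell with zero IFS_T but non-empty
#'   clusters is flagged invalid (with a warning) and is excluded by
#'   [aggregateCondition()].
#' @export
cellMetrics <- function(image, clusters, cellId = "cell", rawIfsT = FALSE) {
  validObject(image)
  mask <- cellMask(image)
  red <- redChannel(image)
  bg <- if (any(!mask)) stats::median(red[!mask]) else
    backgroundEstimate(clusters)
  areaUm2 <- sum(mask) * pixelSize(image)^2
  ifsT <- if (rawIfsT) sum(red[mask]) else max(0, sum(red[mask] - bg))
  tab <- clusterTable(clusters)
  sumIfsc <- sum(tab$ifs_c)
  valid <- TRUE
  if (ifsT == 0 && nrow(tab) > 0L) {
    warning(sprintf("cell '%s': zero total signal with non-empty clusters; flagged invalid",
                    cellId))
    valid <- FALSE
  }
  frac <- if (ifsT > 0) min(1, sumIfsc / ifsT) else 0
  new("CellMetrics",
      cellId = cellId,
      cellAreaUm2 = areaUm2,
      ifsT = ifsT,
      surfaceExpression = ifsT / areaUm2,
      nClustersNorm = nrow(tab) / areaUm2,
      fractionInClusters = frac,
      valid = valid,
      clusters = tab)
}

#' Aggregate cell metrics into one condition row
#'
#' Cell-level metrics (surface expression, clusters per um^2, fraction in
#' clusters) are averaged over valid cells with standard errors sd/sqrt(n).
#' Cluster-level metrics (area, density) are pooled over all clusters of all
#' valid cells, matching a design in which thousands of sites per condition
#' carry the cluster-level statistics.
#'
#' @param cells list of [CellMetrics-class] (invalid cells are dropped).
#' @param fA the condition's transfected A-subunit fraction.
#' @return One-row data.frame with columns `f_A`, mean and SE of the three
#'   cell-level metrics, mean and SE of pooled `cluster_area_um2` and
#'   `cluster_density`, plus `n_cells` and `n_clusters`.
#' @export
aggregateCondition <- function(cells, fA) {
  cells <- Filter(function(cm) cm@valid, cells)
  if (length(cells) < 2L)
    stop("aggregateCondition needs at least 2 valid cells")
  se <- function(x) stats::sd(x) / sqrt(length(x))
  surf <- vapply(cells, function(cm) cm@surfaceExpression, numeric(1))
  ncl <- vapply(cells, function(cm) cm@nClustersNorm, numeric(1))
  frac <- vapply(cells, function(cm) cm@fractionInClusters, numeric(1))
  pooled <- do.call(rbind, lapply(cells, function(cm) cm@clusters))
  data.frame(
    f_A = fA,
    surface_expression_mean = mean(surf), surface_expression_se = se(surf),
    n_clusters_norm_mean = mean(ncl), n_clusters_norm_se = se(ncl),
    fraction_in_clusters_mean = mean(frac), fraction_in_clusters_se = se(frac),
    cluster_area_um2_mean = mean(pooled$area_um2),
    cluster_area_um2_se = se(pooled$area_um2),
    cluster_density_mean = mean(pooled$density),
    cluster_density_se = se(pooled$density),
    n_cells = length(cells),
    n_clusters = nrow(pooled)
  )
}
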