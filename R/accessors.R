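# Accessors and show methods. Slot access from user code should go through
# these; the slot layout is not part of the API.

#' @name kvclust-accessors
#' @title Accessors for kvclust classes
#' @description Small read-only accessors for the S4 containers:
#' `redChannel()`, `greenChannel()`, `cellMask()` and `pixelSize()` for
#' [CellImage-class]; `clusterTable()`, `clusterLabels()` and
#' `backgroundEstimate()` for [ClusterSet-class]; `sceneClusters()` and
#' `trueMetrics()` for [SyntheticScene-class]; `metricsRow()` for
#' [CellMetrics-class]; `coef()`-style `slope()`, `intercept()` and
#' `rSquared()` for [RegressionFit-class].
#' @param x an object of the documented class.
#' @return The corresponding component (matrix, data.frame or scalar).
NULL

#' @rdname kvclust-accessors
#' @export
setGeneric("redChannel", function(x) standardGeneric("redChannel"))
#' @rdname kvclust-accessors
#' @export
setGeneric("greenChannel", function(x) standardGeneric("greenChannel"))
#' @rdname kvclust-accessors
#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))
#' @rdname kvclust-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname kvclust-accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname kvclust-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname kvclust-accessors
#' @export
setGeneric("backgroundEstimate", function(x) standardGeneric("backgroundEstimate"))
#' @rdname kvclust-accessors
#' @export
setGeneric("sceneClusters", function(x) standardGeneric("sceneClusters"))
#' @rdname kvclust-accessors
#' @export
setGeneric("trueMetrics", function(x) standardGeneric("trueMetrics"))
#' @rdname kvclust-accessors
#' @export
setGeneric("metricsRow", function(x) standardGeneric("metricsRow"))
#' @rdname kvclust-accessors
#' @export
setGeneric("slope", function(x) standardGeneric("slope"))
#' @rdname kvclust-accessors
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))
#' @rdname kvclust-accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname kvclust-accessors
setMethod("redChannel", "CellImage", function(x) x@red)
#' @rdname kvclust-accessors
setMethod("greenChannel", "CellImage", function(x) x@green)
#' @rdname kvclust-accessors
setMethod("cellMask", "CellImage", function(x) x@mask)
#' @rdname kvclust-accessors
setMethod("cellMask", "SyntheticScene", function(x) x@cellMask)
#' @rdname kvclust-accessors
setMethod("pixelSize", "CellImage", function(x) x@pixelSizeUm)
#' @rdname kvclust-accessors
setMethod("pixelSize", "SceneParams", function(x) x@pixelSizeUm)
#' @rdname kvclust-accessors
setMethod("pixelSize", "SyntheticScene", function(x) x@params@pixelSizeUm)
#' @rdname kvclust-accessors
setMethod("clusterTable", "ClusterSet", function(x) x@table)
#' @rdname kvclust-accessors
setMethod("clusterLabels", "ClusterSet", function(x) x@labels)
#' @rdname kvclust-accessors
setMethod("backgroundEstimate", "ClusterSet", function(x) x@background)
#' @rdname kvclust-accessors
setMethod("sceneClusters", "SyntheticScene", function(x) x@clusters)
#' @rdname kvclust-accessors
setMethod("trueMetrics", "SyntheticScene", function(x) x@trueMetrics)

#' @rdname kvclust-accessors
setMethod("metricsRow", "CellMetrics", function(x) {
  data.frame(
    cell_id = x@cellId,
    cell_area_um2 = x@cellAreaUm2,
    ifs_t = x@ifsT,
    surface_expression = x@surfaceExpression,
    n_clusters_norm = x@nClustersNorm,
    fraction_in_clusters = x@fractionInClusters,
    n_clusters = nrow(x@clusters),
    valid = x@valid,
    stringsAsFactors = FALSE
  )
})

#' @rdname kvclust-accessors
setMethod("slope", "RegressionFit", function(x) x@slope)
#' @rdname kvclust-accessors
setMethod("intercept", "RegressionFit", function(x) x@intercept)
#' @rdname kvclust-accessors
setMethod("rSquared", "RegressionFit", function(x) x@rSquared)

setMethod("show", "SceneParams", function(object) {
  cat("SceneParams:", paste(object@imageShape, collapse = " x "), "px @",
      object@pixelSizeUm, "um/px\n")
  cat("  cell semi-axes (px):", paste(signif(object@cellAxes, 4), collapse = ", "),
      "| cluster rate:", object@clusterRate, "/um^2\n")
  cat("  radius lognormal(meanlog =", signif(object@radiusLogMean, 4),
      ", sdlog =", signif(object@radiusLogSd, 4), ") um\n")
  cat("  mean density:", format(object@meanDensity, big.mark = ","),
      "IFS/um^2 (CV", object@densityCV, ")\n")
  cat("  diffuse/background/noise:", object@diffuseLevel, "/",
      object@backgroundLevel, "/", object@noiseSd,
      "| coloc prob:", object@scaffoldColocProb,
      "| seed:", object@seed, "\n")
})

setMethod("show", "SyntheticScene", function(object) {
  tm <- object@trueMetrics
  cat("SyntheticScene:", nrow(object@clusters), "clusters on a",
      signif(tm$cell_area_um2, 5), "um^2 cell\n")
  cat("  true fraction in clusters:", signif(tm$fraction_in_clusters, 4),
      "| true mean density:", signif(tm$mean_cluster_density, 6), "IFS/um^2\n")
})

setMethod("show", "CellImage", function(object) {
  cat("CellImage:", paste(dim(object@red), collapse = " x "), "px @",
      object@pixelSizeUm, "um/px;", sum(object@mask), "mask px\n")
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", nrow(object@table), "clustering sites; background =",
      signif(object@background, 6), "; threshold =",
      signif(object@threshold, 6), "\n")
  if (nrow(object@table))
    cat("  mean area:", signif(mean(object@table$area_um2), 4),
        "um^2 | mean density:", signif(mean(object@table$density), 6),
        "IFS/um^2 | coloc:", signif(mean(object@table$coloc), 3), "\n")
})

setMethod("show", "CellMetrics", function(object) {
  cat("CellMetrics [", object@cellId, "]",
      if (!object@valid) "(INVALID)", "\n")
  cat("  area:", signif(object@cellAreaUm2, 5), "um^2 | IFS_T:",
      signif(object@ifsT, 6), "| surface expr:",
      signif(object@surfaceExpression, 5), "/um^2\n")
  cat("  clusters/um^2:", signif(object@nClustersNorm, 4),
      "| fraction in clusters:", signif(object@fractionInClusters, 4),
      "(", nrow(object@clusters), "sites )\n")
})

setMethod("show", "RegressionFit", function(object) {
  cat("RegressionFit: y =", signif(object@intercept, 6), "+",
      signif(object@slope, 6), "* f_A ; R^2 =", signif(object@rSquared, 4),
      "(", object@nPoints, "points",
      if (object@degenerate) "; degenerate", ")\n")
})

setMethod("show", "AssumptionReport", function(object) {
  cat("AssumptionReport (alpha =", object@alpha, ")\n")
  cat("  normality p:", paste(signif(object@normalityP, 3), collapse = ", "),
      "->", if (object@normalityOk) "ok" else "violated", "\n")
  cat("  Levene p:", signif(object@leveneP, 3), "->",
      if (object@homoscedasticityOk) "ok" else "violated", "\n")
})

setMethod("show", "StatsReport", function(object) {
  cat("StatsReport [", object@metric, "]: test =", object@selectedTest,
      "; transform =", object@transformation, "\n")
  cat("  statistic =", signif(object@statistic, 5), "; p =",
      format.pval(object@pValue, digits = 3), ";",
      if (object@reject) "REJECT" else "retain", "at alpha =",
      object@alpha, "\n")
  if (!is.null(object@tukey)) {
    cat("  Tukey HSD pairwise comparisons:\n")
    print(object@tukey, row.names = FALSE, digits = 4)
  }
})
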