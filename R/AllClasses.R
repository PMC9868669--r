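#' @import methods
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Parameters of a synthetic two-channel cell scene
#'
#' Describes one simulated cell: acquisition geometry (image size, pixel pitch
#' emulating ~150 nm Nyquist sampling), an elliptical cell mask, and the
#' statistical structure of its clustering sites (Poisson count, lognormal
#' radii, Gamma-distributed per-cluster channel density) plus diffuse signal,
#' camera background and read noise. Intensities are in arbitrary fluorescence
#' units per pixel; densities in intensity units per square micron.
#'
#' @slot imageShape integer(2), image rows and columns in pixels.
#' @slot pixelSizeUm numeric, pixel pitch in microns per pixel.
#' @slot cellAxes numeric(2), ellipse semi-axes of the cell mask in pixels
#'   (jittered a few percent per seed).
#' @slot clusterRate numeric, expected clustering sites per square micron of
#'   cell area.
#' @slot radiusLogMean,radiusLogSd numeric, meanlog/sdlog of the lognormal
#'   cluster radius distribution (microns).
#' @slot meanDensity numeric, target mean per-cluster channel density
#'   (intensity per square micron).
#' @slot densityCV numeric in [0,1), coefficient of variation of per-cluster
#'   density (Gamma distributed).
#' @slot diffuseLevel numeric, mean diffuse (non-clustered) red intensity per
#'   in-mask pixel.
#' @slot backgroundLevel numeric, camera offset added everywhere.
#' @slot noiseSd numeric, additive Gaussian read-noise sd (values clamped at 0).
#' @slot greenLevel numeric, scaffold (green) disk amplitude over background.
#' @slot scaffoldColocProb numeric in [0,1], probability a cluster carries
#'   scaffold signal.
#' @slot seed integer RNG seed; scenes are bit-reproducible given the seed.
#' @seealso [sceneParams()], [makeScene()]
#' @exportClass SceneParams
setClass("SceneParams",
  representation(
    imageShape = "integer",
    pixelSizeUm = "numeric",
    cellAxes = "numeric",
    clusterRate = "numeric",
    radiusLogMean = "numeric",
    radiusLogSd = "numeric",
    meanDensity = "numeric",
    densityCV = "numeric",
    diffuseLevel = "numeric",
    backgroundLevel = "numeric",
    noiseSd = "numeric",
    greenLevel = "numeric",
    scaffoldColocProb = "numeric",
    seed = "integer"
  )
)

setValidity("SceneParams", function(object) {
  msg <- character()
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    msg <- c(msg, "imageShape must be two integers >= 8")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (length(object@cellAxes) != 2L || any(object@cellAxes <= 0))
    msg <- c(msg, "cellAxes must be two positive semi-axes (px)")
  nonneg <- c(clusterRate = object@clusterRate, meanDensity = object@meanDensity,
              diffuseLevel = object@diffuseLevel,
              backgroundLevel = object@backgroundLevel,
              noiseSd = object@noiseSd, greenLevel = object@greenLevel)
  if (any(nonneg < 0))
    msg <- c(msg, paste("negative rate/level:",
                        paste(names(nonneg)[nonneg < 0], collapse = ", ")))
  if (object@radiusLogSd < 0) msg <- c(msg, "radiusLogSd must be >= 0")
  if (object@densityCV < 0 || object@densityCV >= 1)
    msg <- c(msg, "densityCV must lie in [0, 1)")
  if (object@scaffoldColocProb < 0 || object@scaffoldColocProb > 1)
    msg <- c(msg, "scaffoldColocProb must lie in [0, 1]")
  if (is.na(object@seed) || object@seed < 0L)
    msg <- c(msg, "seed must be a non-negative integer")
  if (length(msg)) msg else TRUE
})

#' A ground-truth-annotated synthetic scene
#'
#' The generative truth for one simulated cell: the parameters, the boolean
#' cell mask, one row per clustering site (continuous center in pixel
#' coordinates, radius in microns, true channel density, scaffold
#' co-localization flag), and the five clustering metrics computed analytically
#' from the truth (no rendering or segmentation involved).
#'
#' @slot params a [SceneParams-class].
#' @slot cellMask logical matrix, TRUE inside the cell.
#' @slot clusters data.frame with columns `row`, `col`, `radius_um`,
#'   `density`, `coloc`.
#' @slot trueMetrics named list: `cell_area_um2`, `ifs_t`,
#'   `surface_expression`, `n_clusters_norm`, `fraction_in_clusters`,
#'   `mean_cluster_area_um2`, `mean_cluster_density`.
#' @seealso [makeScene()], [renderScene()]
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(
    params = "SceneParams",
    cellMask = "matrix",
    clusters = "data.frame",
    trueMetrics = "list"
  )
)

setValidity("SyntheticScene", function(object) {
  msg <- character()
  cl <- object@clusters
  need <- c("row", "col", "radius_um", "density", "coloc")
  if (!all(need %in% names(cl)))
    return(paste("clusters must have columns", paste(need, collapse = ", ")))
  if (nrow(cl)) {
    idx <- cbind(pmax(1L, pmin(nrow(object@cellMask), round(cl$row))),
                 pmax(1L, pmin(ncol(object@cellMask), round(cl$col))))
    if (!all(object@cellMask[idx]))
      msg <- c(msg, "every cluster center must lie inside the cell mask")
    if (any(cl$density <= 0)) msg <- c(msg, "true densities must be > 0")
    if (any(cl$radius_um <= 0)) msg <- c(msg, "radii must be > 0")
  }
  if (!any(object@cellMask)) msg <- c(msg, "cell mask is empty")
  if (length(msg)) msg else TRUE
})

#' A two-channel cell image with mask
#'
#' One registered acquisition of the basal membrane plane: red = Kv-channel
#' associated signal, green = scaffold (PSD-95) associated signal, plus the
#' boolean cell mask and the physical pixel size.
#'
#' @slot red,green numeric matrices of identical dimension (intensity units).
#' @slot mask logical matrix, TRUE inside the cell.
#' @slot pixelSizeUm numeric, microns per pixel.
#' @seealso [renderScene()], [readCellImage()], [detectSpots()]
#' @exportClass CellImage
setClass("CellImage",
  representation(
    red = "matrix",
    green = "matrix",
    mask = "matrix",
    pixelSizeUm = "numeric"
  )
)

setValidity("CellImage", function(object) {
  msg <- character()
  d <- dim(object@red)
  if (!identical(d, dim(object@green)) || !identical(d, dim(object@mask)))
    msg <- c(msg, "red, green and mask must share dimensions")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Segmented clustering sites of one cell
#'
#' Output of [segmentClusters()]: one row per clustering site, the label image
#' mapping pixels to sites, and the background estimate / threshold used so
#' that downstream per-cell metrics can reuse exactly the same correction.
#'
#' @slot table data.frame with columns `cluster_id`, `n_pixels`, `area_um2`,
#'   `ifs_c` (background-corrected integrated signal), `density`
#'   (= ifs_c / area_um2), `coloc`, `n_spots`.
#' @slot labels integer matrix, 0 outside any retained site.
#' @slot background numeric, the in-mask background estimate subtracted
#'   per pixel.
#' @slot threshold numeric, the segmentation threshold applied.
#' @slot pixelSizeUm numeric, microns per pixel.
#' @seealso [segmentClusters()], [cellMetrics()]
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(
    table = "data.frame",
    labels = "matrix",
    background = "numeric",
    threshold = "numeric",
    pixelSizeUm = "numeric"
  )
)

setValidity("ClusterSet", function(object) {
  tab <- object@table
  need <- c("cluster_id", "n_pixels", "area_um2", "ifs_c", "density",
            "coloc", "n_spots")
  if (!all(need %in% names(tab)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(tab)) {
    if (any(tab$area_um2 <= 0)) msg <- c(msg, "area_um2 must be > 0")
    if (any(tab$ifs_c < 0)) msg <- c(msg, "ifs_c must be >= 0")
    if (any(abs(tab$density - tab$ifs_c / tab$area_um2) >
            1e-8 * pmax(1, tab$density)))
      msg <- c(msg, "density must equal ifs_c / area_um2")
  }
  if (length(msg)) msg else TRUE
})

#' Per-cell clustering metrics
#'
#' The five per-cell quantities compared across transfection ratios:
#' total background-corrected signal (IFS_T), normalized surface expression
#' (IFS_T per square micron), clusters per square micron, fraction of channels
#' in clusters (sum IFSc / IFS_T), and the per-site table.
#'
#' @slot cellId character label.
#' @slot cellAreaUm2,ifsT,surfaceExpression,nClustersNorm,fractionInClusters
#'   numeric scalars.
#' @slot valid logical; FALSE flags a degenerate cell (zero total signal with
#'   non-empty clusters) excluded from aggregation.
#' @slot clusters data.frame, the per-site table of the cell.
#' @seealso [cellMetrics()], [aggregateCondition()]
#' @exportClass CellMetrics
setClass("CellMetrics",
  representation(
    cellId = "character",
    cellAreaUm2 = "numeric",
    ifsT = "numeric",
    surfaceExpression = "numeric",
    nClustersNorm = "numeric",
    fractionInClusters = "numeric",
    valid = "logical",
    clusters = "data.frame"
  )
)

setValidity("CellMetrics", function(object) {
  msg <- character()
  if (object@fractionInClusters < 0 || object@fractionInClusters > 1)
    msg <- c(msg, "fractionInClusters must lie in [0, 1]")
  if (object@nClustersNorm < 0) msg <- c(msg, "nClustersNorm must be >= 0")
  if (object@surfaceExpression < 0)
    msg <- c(msg, "surfaceExpression must be >= 0")
  if (length(msg)) msg else TRUE
})

#' One simulated transfection condition
#'
#' A transfected high-affinity subunit fraction f_A together with the number
#' of cells to simulate and the density endpoints d_B (f_A = 0) and d_A
#' (f_A = 1) between which the condition's target mean cluster density is
#' linearly interpolated.
#'
#' @slot fA numeric in [0,1], molar transfected fraction of the A subunit.
#' @slot nCells integer, cells to simulate.
#' @slot dB,dA numeric, mean cluster densities at f_A = 0 and 1.
#' @slot baseScene a [SceneParams-class] whose `meanDensity` and `seed` are
#'   overridden per cell.
#' @seealso [conditionSpec()], [generateCondition()]
#' @exportClass ConditionSpec
setClass("ConditionSpec",
  representation(
    fA = "numeric",
    nCells = "integer",
    dB = "numeric",
    dA = "numeric",
    baseScene = "SceneParams"
  )
)

setValidity("ConditionSpec", function(object) {
  msg <- character()
  if (object@fA < 0 || object@fA > 1) msg <- c(msg, "fA must lie in [0, 1]")
  if (object@dA <= 0 || object@dB <= 0) msg <- c(msg, "dA, dB must be > 0")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ordinary least-squares fit of mean cluster density on f_A
#'
#' @slot slope,intercept numeric, density units per unit f_A and at f_A = 0.
#' @slot rSquared numeric in [0,1]; defined as 0 (with `degenerate = TRUE`)
#'   when the responses have zero variance.
#' @slot nPoints integer, points fitted.
#' @slot degenerate logical.
#' @seealso [fitDensityVsFraction()]
#' @exportClass RegressionFit
setClass("RegressionFit",
  representation(
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    nPoints = "integer",
    degenerate = "logical"
  )
)

setValidity("RegressionFit", function(object) {
  msg <- character()
  if (object@rSquared < 0 || object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Assumption checks preceding the omnibus test
#'
#' Per-group normality p-values (Lilliefors-corrected Kolmogorov-Smirnov,
#' Monte-Carlo null) and a Levene homoscedasticity p-value across groups,
#' with pass/fail flags at the stated alpha.
#'
#' @slot normalityP named numeric, one Lilliefors p per group.
#' @slot leveneP numeric, Levene (center = mean) p across groups.
#' @slot normalityOk,homoscedasticityOk logical flags at `alpha`.
#' @slot alpha numeric, assumption-check significance level.
#' @slot zeroVariance logical, per-group degenerate-sample flags (normality p
#'   forced to 0).
#' @seealso [assessAssumptions()], [selectTest()]
#' @exportClass AssumptionReport
setClass("AssumptionReport",
  representation(
    normalityP = "numeric",
    leveneP = "numeric",
    normalityOk = "logical",
    homoscedasticityOk = "logical",
    alpha = "numeric",
    zeroVariance = "logical"
  )
)

setValidity("AssumptionReport", function(object) {
  p <- c(object@normalityP, object@leveneP)
  if (any(p < 0 | p > 1, na.rm = TRUE)) "p-values must lie in [0, 1]" else TRUE
})

#' Result of the test-selection cascade for one metric
#'
#' @slot metric character, metric name.
#' @slot assumptions the [AssumptionReport-class] of the (possibly
#'   transformed) data actually tested.
#' @slot selectedTest character: "anova", "welch" or "kruskal".
#' @slot transformation character: "none", "log" or "sqrt".
#' @slot statistic,pValue numeric, omnibus statistic and p.
#' @slot alpha numeric, rejection level (0.01 in the study design).
#' @slot reject logical, `pValue < alpha`.
#' @slot tukey data.frame of Tukey HSD pairwise comparisons, or NULL when the
#'   omnibus null is not rejected.
#' @seealso [statsCascade()]
#' @exportClass StatsReport
setClass("StatsReport",
  representation(
    metric = "character",
    assumptions = "AssumptionReport",
    selectedTest = "character",
    transformation = "character",
    statistic = "numeric",
    pValue = "numeric",
    alpha = "numeric",
    reject = "logical",
    tukey = "data.frameOrNULL"
  )
)

setValidity("StatsReport", function(object) {
  msg <- character()
  if (!object@selectedTest %in% c("anova", "welch", "kruskal"))
    msg <- c(msg, "selectedTest must be anova, welch or kruskal")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (!identical(object@reject, object@pValue < object@alpha))
    msg <- c(msg, "reject must equal pValue < alpha")
  if (!object@reject && !is.null(object@tukey))
    msg <- c(msg, "tukey table only present when the omnibus null is rejected")
  if (length(msg)) msg else TRUE
})
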