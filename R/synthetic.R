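# Synthetic two-channel scenes with exact ground truth.
#
# Clustering sites are uniform-intensity disks (not Gaussians): the disk
# amplitude is chosen so that background-corrected integrated signal / area
# equals the drawn true density exactly, which makes every downstream metric
# checkable against an analytic truth. Geometry and intensities are drawn
# once in makeScene(); renderScene() only rasterizes and adds noise.

#' Construct scene parameters
#'
#' Defaults emulate the study conditions of the clustering analysis the
#' package implements: 150 nm pixels (Nyquist sampling of a high-resolution
#' confocal acquisition), a ~600 um^2 elliptical cell, ~0.25 clustering sites
#' per um^2 (so ~23 cells yield 3000-5000 sites per condition), per-site
#' channel densities of order 16-21 x 10^4 IFS/um^2 with 30% CV, and a
#' diffuse (non-clustered) pool putting the fraction of channels in clusters
#' near 0.13-0.20. Site radii are lognormal with median 0.33 um (~2.2 px) so
#' that threshold segmentation can recover areas and densities accurately;
#' see the methods vignette for why sub-pixel sites are not the default.
#'
#' @param imageShape integer(2) image size in pixels (rows, cols).
#' @param pixelSizeUm microns per pixel.
#' @param cellAxes ellipse semi-axes of the cell mask in pixels; jittered
#'   uniformly by +/-5 percent per seed.
#' @param clusterRate expected clustering sites per square micron of cell.
#' @param radiusLogMean,radiusLogSd lognormal radius parameters (microns).
#' @param meanDensity target mean per-site channel density (IFS/um^2).
#' @param densityCV coefficient of variation of per-site density, in [0,1);
#'   densities are Gamma distributed with this mean and CV.
#' @param diffuseLevel mean diffuse red intensity per in-mask pixel.
#' @param backgroundLevel camera offset added to every pixel.
#' @param noiseSd additive Gaussian read-noise sd (pixels clamped at 0).
#' @param greenLevel scaffold (green) disk amplitude over background.
#' @param scaffoldColocProb probability a site carries scaffold signal.
#' @param seed non-negative integer; scenes are bit-reproducible given it.
#' @return A validated [SceneParams-class].
#' @examples
#' p <- sceneParams(imageShape = c(96L, 96L), cellAxes = c(36, 30), seed = 7L)
#' p
#' @export
sceneParams <- function(imageShape = c(256L, 256L),
                        pixelSizeUm = 0.15,
                        cellAxes = c(100, 85),
                        clusterRate = 0.25,
                        radiusLogMean = log(0.33),
                        radiusLogSd = 0.12,
                        meanDensity = 1.84e5,
                        densityCV = 0.30,
                        diffuseLevel = 1800,
                        backgroundLevel = 400,
                        noiseSd = 200,
                        greenLevel = 2000,
                        scaffoldColocProb = 0.9,
                        seed = 1L) {
  new("SceneParams",
      imageShape = as.integer(imageShape),
      pixelSizeUm = as.numeric(pixelSizeUm),
      cellAxes = as.numeric(cellAxes),
      clusterRate = as.numeric(clusterRate),
      radiusLogMean = as.numeric(radiusLogMean),
      radiusLogSd = as.numeric(radiusLogSd),
      meanDensity = as.numeric(meanDensity),
      densityCV = as.numeric(densityCV),
      diffuseLevel = as.numeric(diffuseLevel),
      backgroundLevel = as.numeric(backgroundLevel),
      noiseSd = as.numeric(noiseSd),
      greenLevel = as.numeric(greenLevel),
      scaffoldColocProb = as.numeric(scaffoldColocProb),
      seed = as.integer(seed))
}

# Axis-aligned elliptical mask centred in the image.
ellipseMask <- function(shape, axes) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  co <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  c0 <- (shape + 1) / 2
  ((r - c0[1]) / axes[1])^2 + ((co - c0[2]) / axes[2])^2 <= 1
}

# Pixel set of a disk: pixels whose (integer) centre lies within radiusPx of
# the continuous centre. Returns an n x 2 matrix of (row, col).
diskPixels <- function(row, col, radiusPx, shape) {
  r0 <- max(1L, floor(row - radiusPx)); r1 <- min(shape[1], ceiling(row + radiusPx))
  c0 <- max(1L, floor(col - radiusPx)); c1 <- min(shape[2], ceiling(col + radiusPx))
  if (r0 > r1 || c0 > c1) return(matrix(integer(), 0L, 2L))
  rr <- r0:r1; cc <- c0:c1
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - row)^2 + (g$col - col)^2 <= radiusPx^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Draw a ground-truth scene
#'
#' Draws the cell mask (jittered ellipse), a Poisson number of clustering
#' sites (rate x cell area in um^2), lognormal radii, Gamma per-site
#' densities, and Bernoulli scaffold co-localization flags; places sites by
#' rejection sampling with minimum centre distance equal to the sum of the
#' two radii (resolvable puncta) and the whole disk inside the mask. The
#' five clustering metrics implied by the draw are stored analytically in
#' `trueMetrics`.
#'
#' @param params a [SceneParams-class].
#' @return A [SyntheticScene-class]; identical `(params, seed)` give
#'   identical scenes.
#' @examples
#' sc <- makeScene(sceneParams(imageShape = c(96L, 96L), cellAxes = c(36, 30),
#'                             seed = 7L))
#' sc
#' @export
makeScene <- function(params) {
  validObject(params)
  px <- params@pixelSizeUm
  withr::with_seed(params@seed, {
    axes <- params@cellAxes * stats::runif(2, 0.95, 1.05)
    mask <- ellipseMask(params@imageShape, axes)
    if (!any(mask)) stop("cell mask is empty for the given image/axes")
    areaUm2 <- sum(mask) * px^2
    n <- stats::rpois(1L, params@clusterRate * areaUm2)
    radii <- if (n) stats::rlnorm(n, params@radiusLogMean, params@radiusLogSd)
             else numeric()
    dens <- if (n == 0L) numeric()
            else if (params@densityCV == 0) rep(params@meanDensity, n)
            else {
              shape <- 1 / params@densityCV^2
              stats::rgamma(n, shape = shape, rate = shape / params@meanDensity)
            }
    coloc <- if (n) stats::runif(n) < params@scaffoldColocProb else logical()

    rows <- cols <- numeric(n)
    placed <- 0L
    attempts <- 0L
    maxAttempts <- 100L * max(1L, n)
    while (placed < n) {
      if (attempts >= maxAttempts)
        stop(sprintf(paste("could not place clusters without overlap:",
                           "placed %d of %d after %d attempts"),
                     placed, n, attempts))
      attempts <- attempts + 1L
      i <- placed + 1L
      rp <- radii[i] / px
      r <- stats::runif(1, 1, params@imageShape[1])
      co <- stats::runif(1, 1, params@imageShape[2])
      if (placed > 0L) {
        dmin <- sqrt((rows[seq_len(placed)] - r)^2 +
                     (cols[seq_len(placed)] - co)^2)
        if (any(dmin < (radii[seq_len(placed)] + radii[i]) / px)) next
      }
      pixd <- diskPixels(r, co, rp, params@imageShape)
      if (nrow(pixd) == 0L || !all(mask[pixd])) next
      rows[i] <- r; cols[i] <- co
      placed <- i
    }
  })

  clusters <- data.frame(row = rows, col = cols, radius_um = radii,
                         density = dens, coloc = coloc)
  trueArea <- pi * radii^2
  clusterSignal <- sum(dens * trueArea)
  ifsT <- params@diffuseLevel * sum(mask) + clusterSignal
  trueMetrics <- list(
    cell_area_um2 = areaUm2,
    ifs_t = ifsT,
    surface_expression = ifsT / areaUm2,
    n_clusters_norm = n / areaUm2,
    fraction_in_clusters = if (ifsT > 0) clusterSignal / ifsT else 0,
    mean_cluster_area_um2 = if (n) mean(trueArea) else NA_real_,
    mean_cluster_density = if (n) mean(dens) else NA_real_
  )
  new("SyntheticScene", params = params, cellMask = mask,
      clusters = clusters, trueMetrics = trueMetrics)
}

#' Rasterize a scene into a two-channel image
#'
#' Red channel: background + diffuse level inside the mask + one uniform disk
#' per clustering site whose per-pixel amplitude is `density * pixelSize^2`,
#' so the disk's background-corrected integrated signal divided by its
#' pixelated area equals the true density exactly. Green channel: background
#' plus disks only for co-localized sites. Gaussian read noise (sd
#' `noiseSd`) is added to both channels and pixel values are clamped at 0.
#' Noise is seeded from the scene seed, so re-rendering is deterministic.
#'
#' @param scene a [SyntheticScene-class].
#' @return A [CellImage-class].
#' @examples
#' sc <- makeScene(sceneParams(imageShape = c(96L, 96L), cellAxes = c(36, 30),
#'                             seed = 7L))
#' img <- renderScene(sc)
#' img
#' @export
renderScene <- function(scene) {
  validObject(scene)
  p <- scene@params
  px <- p@pixelSizeUm
  shape <- p@imageShape
  red <- matrix(p@backgroundLevel, shape[1], shape[2])
  red[scene@cellMask] <- red[scene@cellMask] + p@diffuseLevel
  green <- matrix(p@backgroundLevel, shape[1], shape[2])
  cl <- scene@clusters
  if (nrow(cl)) {
    for (i in seq_len(nrow(cl))) {
      pixd <- diskPixels(cl$row[i], cl$col[i], cl$radius_um[i] / px, shape)
      red[pixd] <- red[pixd] + cl$density[i] * px^2
      if (cl$coloc[i]) green[pixd] <- green[pixd] + p@greenLevel
    }
  }
  if (p@noiseSd > 0) {
    withr::with_seed(p@seed + 7919L, {
      red <- red + stats::rnorm(length(red), 0, p@noiseSd)
      green <- green + stats::rnorm(length(green), 0, p@noiseSd)
    })
    red <- pmax(red, 0)
    green <- pmax(green, 0)
  }
  new("CellImage", red = red, green = green, mask = scene@cellMask,
      pixelSizeUm = px)
}

#' Construct a transfection-condition specification
#'
#' @param fA transfected high-affinity (A) subunit fraction in [0,1].
#' @param nCells number of cells to simulate (23 matches the study scale).
#' @param dB,dA mean cluster channel densities at `fA = 0` and `fA = 1`
#'   (IFS/um^2); defaults are the measured homo-tetramer endpoints,
#'   16.51 and 20.33 x 10^4.
#' @param baseScene [SceneParams-class] shared by all cells; `meanDensity`
#'   and `seed` are overridden per cell.
#' @return A validated [ConditionSpec-class].
#' @export
conditionSpec <- function(fA, nCells = 23L, dB = 16.51e4, dA = 20.33e4,
                          baseScene = sceneParams()) {
  new("ConditionSpec", fA = as.numeric(fA), nCells = as.integer(nCells),
      dB = as.numeric(dB), dA = as.numeric(dA), baseScene = baseScene)
}

#' Expected mean cluster density under the additive subunit model
#'
#' With binomial tetramer assembly at subunit fraction `fA` and a density
#' contribution linear in the number of high-affinity subunits, the expected
#' mean cluster density collapses to the linear law
#' `dB + (dA - dB) * fA` (the binomial expectation of `dB + (dA-dB) k/4`
#' over k ~ Binomial(4, fA)). This is the generative closure used for
#' simulation; empirically the linear dependence is what the clustering data
#' show.
#'
#' @param fA subunit fraction(s) in [0,1] (vectorized).
#' @param dB,dA densities at `fA = 0` and `fA = 1`; both must be > 0.
#' @return Expected mean density, same length as `fA`.
#' @examples
#' expectedMeanDensity(0.5, dB = 16.51e4, dA = 20.33e4)  # 18.42e4
#' @export
expectedMeanDensity <- function(fA, dB, dA) {
  stopifnot(dB > 0, dA > 0)
  dB + (dA - dB) * fA
}

# Distinct per-cell seed derived from one master seed (stays below 2^31).
deriveSeed <- function(master, k) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(k)) %% 2147483629)
}

#' Simulate all cells of one condition
#'
#' Every cell's target mean density is set to
#' `expectedMeanDensity(fA, dB, dA)`; per-cell seeds are derived
#' deterministically from the base scene's seed.
#'
#' @param spec a [ConditionSpec-class].
#' @return A list of length `nCells` (possibly empty); each element is a list
#'   with components `image` ([CellImage-class]) and `scene`
#'   ([SyntheticScene-class]).
#' @export
generateCondition <- function(spec) {
  validObject(spec)
  if (spec@nCells == 0L) return(list())
  target <- expectedMeanDensity(spec@fA, spec@dB, spec@dA)
  lapply(seq_len(spec@nCells), function(i) {
    p <- spec@baseScene
    p@meanDensity <- target
    p@seed <- deriveSeed(spec@baseScene@seed, i)
    scene <- makeScene(p)
    list(image = renderScene(scene), scene = scene)
  })
}
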