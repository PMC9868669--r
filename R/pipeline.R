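# End-to-end orchestration: simulate -> detect -> segment -> metrics ->
# aggregate -> stats -> density regression, with reproducible on-disk
# artifacts. Every CSV starts with a "# config <hash>" comment line tying the
# file to the configuration that produced it; read them with
# read.csv(..., comment.char = "#").

#' Build a pipeline configuration
#'
#' @param mode "full" (simulate in memory, analyze, stats), "simulate"
#'   (write images + ground truth only), "analyze" (read images from
#'   `inputDir`, compute metrics + summary), or "stats" (read per-cell and
#'   per-cluster CSVs from `inputDir`, run inference only).
#' @param outDir output directory.
#' @param seed master seed; every random draw in the run derives from it.
#' @param fA distinct transfected A-subunit fractions in [0,1], one
#'   condition each.
#' @param nCells cells per condition.
#' @param dB,dA mean cluster density endpoints at `fA = 0` and 1 (IFS/um^2).
#' @param scene base [SceneParams-class] for simulation.
#' @param boxSize,noiseTolerance spot-detection parameters
#'   (see [detectSpots()]).
#' @param threshold,colocFactor segmentation parameters
#'   (see [segmentClusters()]).
#' @param writeImages in "full" mode, also write the per-cell TIFFs.
#' @param inputDir input directory for "analyze"/"stats" modes.
#' @param pixelSizeUm pixel pitch used when reading external TIFFs.
#' @param alpha,assumptionAlpha,lillieforsB,mapping inference settings
#'   (see [statsCascade()]).
#' @return A validated configuration list of class `kvclustConfig`.
#' @export
pipelineConfig <- function(mode = c("full", "simulate", "analyze", "stats"),
                           outDir = tempfile("kvclust_run_"),
                           seed = 1L,
                           fA = c(0, 0.25, 0.5, 0.75, 1),
                           nCells = 23L,
                           dB = 16.51e4, dA = 20.33e4,
                           scene = sceneParams(),
                           boxSize = 5L, noiseTolerance = "auto",
                           threshold = "auto", colocFactor = 2,
                           writeImages = FALSE,
                           inputDir = NULL,
                           pixelSizeUm = 0.15,
                           alpha = 0.01, assumptionAlpha = 0.05,
                           lillieforsB = 10000L,
                           mapping = c("study", "conventional")) {
  mode <- match.arg(mode)
  mapping <- match.arg(mapping)
  if (anyDuplicated(fA) || any(fA < 0 | fA > 1))
    stop("fA values must be distinct and lie in [0, 1]")
  if (mode %in% c("analyze", "stats")) {
    if (is.null(inputDir) || !dir.exists(inputDir))
      stop("mode '", mode, "' requires an existing inputDir")
  }
  structure(list(
    mode = mode, outDir = outDir, seed = as.integer(seed), fA = fA,
    nCells = as.integer(nCells), dB = dB, dA = dA, scene = scene,
    boxSize = as.integer(boxSize), noiseTolerance = noiseTolerance,
    threshold = threshold, colocFactor = colocFactor,
    writeImages = writeImages, inputDir = inputDir,
    pixelSizeUm = pixelSizeUm, alpha = alpha,
    assumptionAlpha = assumptionAlpha, lillieforsB = as.integer(lillieforsB),
    mapping = mapping), class = "kvclustConfig")
}

#' Analyze one cell image through detection, segmentation and metrics
#'
#' @param image a [CellImage-class].
#' @param cellId character label.
#' @param boxSize,noiseTolerance see [detectSpots()].
#' @param threshold,colocFactor see [segmentClusters()].
#' @return list with `spots` (data.frame), `clusters` ([ClusterSet-class])
#'   and `metrics` ([CellMetrics-class]).
#' @export
analyzeCellImage <- function(image, cellId = "cell", boxSize = 5L,
                             noiseTolerance = "auto", threshold = "auto",
                             colocFactor = 2) {
  spots <- detectSpots(redChannel(image), cellMask(image),
                       boxSize = boxSize, noiseTolerance = noiseTolerance)
  clusters <- segmentClusters(redChannel(image), cellMask(image), spots,
                              threshold = threshold,
                              pixelSizeUm = pixelSize(image),
                              greenImage = greenChannel(image),
                              colocFactor = colocFactor)
  metrics <- cellMetrics(image, clusters, cellId = cellId)
  list(spots = spots, clusters = clusters, metrics = metrics)
}

condSeed <- function(seed, ci) {
  as.integer((as.numeric(seed) + 22695477 * as.numeric(ci)) %% 2147483629)
}

faTag <- function(fA) sprintf("fA_%s", gsub("\\.", "p", format(fA)))

writeCsvWithHash <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# config ", hash, "; areas via pixel_size_um^2;",
                    " 0-based image indices are not used (R convention:",
                    " 1-based, row-major, origin top-left)"), con)
  utils::write.csv(df, con, row.names = FALSE)
}

configToList <- function(config) {
  p <- config$scene
  out <- unclass(config)
  out$scene <- list(
    image_shape = p@imageShape, pixel_size_um = p@pixelSizeUm,
    cell_axes_px = p@cellAxes, cluster_rate = p@clusterRate,
    radius_log_mean = p@radiusLogMean, radius_log_sd = p@radiusLogSd,
    mean_density = p@meanDensity, density_cv = p@densityCV,
    diffuse_level = p@diffuseLevel, background_level = p@backgroundLevel,
    noise_sd = p@noiseSd, green_level = p@greenLevel,
    scaffold_coloc_prob = p@scaffoldColocProb, seed = p@seed)
  out
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(configToList(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

assumptionsToList <- function(a) {
  list(normality_p = as.list(a@normalityP), levene_p = a@leveneP,
       normality_ok = a@normalityOk, homoscedasticity_ok = a@homoscedasticityOk,
       alpha = a@alpha)
}

statsReportToList <- function(sr) {
  list(metric = sr@metric, selected_test = sr@selectedTest,
       transformation = sr@transformation, statistic = sr@statistic,
       p_value = sr@pValue, alpha = sr@alpha, reject = sr@reject,
       assumptions = assumptionsToList(sr@assumptions),
       tukey = sr@tukey)
}

regressionToList <- function(fit) {
  list(slope = slope(fit), intercept = intercept(fit),
       r_squared = rSquared(fit), n_points = fit@nPoints,
       degenerate = fit@degenerate)
}

#' Run the clustering pipeline end to end
#'
#' Executes the stages selected by the configuration's mode and writes, as
#' applicable: per-cell TIFFs with ground-truth CSVs and parameter sidecars,
#' a spots CSV, a clusters CSV, a per-cell metrics CSV, a condition summary
#' CSV (one row per f_A; the five metrics as mean and SE), a stats-report
#' JSON (one cascade per metric), a density-vs-f_A regression JSON, and a
#' run manifest with the config hash. Re-running with the same configuration
#' reproduces all CSV/JSON artifacts byte-identically.
#'
#' @param config a `kvclustConfig` from [pipelineConfig()].
#' @return Invisibly, a list with the in-memory results: `summary`
#'   (condition table), `statsReports` (list of [StatsReport-class]),
#'   `regression` ([RegressionFit-class]), `files` (paths written).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "kvclustConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  files <- character()
  mode <- config$mode

  cellsByCondition <- NULL
  if (mode %in% c("full", "simulate")) {
    cellsByCondition <- lapply(seq_along(config$fA), function(ci) {
      spec <- conditionSpec(config$fA[ci], nCells = config$nCells,
                            dB = config$dB, dA = config$dA,
                            baseScene = local({
                              s <- config$scene
                              s@seed <- condSeed(config$seed, ci)
                              s
                            }))
      generateCondition(spec)
    })
    names(cellsByCondition) <- faTag(config$fA)
    if (mode == "simulate" || isTRUE(config$writeImages)) {
      for (ci in seq_along(config$fA)) {
        dir <- file.path(config$outDir, "images", faTag(config$fA[ci]))
        for (i in seq_along(cellsByCondition[[ci]])) {
          cell <- cellsByCondition[[ci]][[i]]
          files <- c(files, writeScene(cell$scene, dir,
                                       id = sprintf("cell_%02d", i),
                                       image = cell$image))
        }
      }
    }
    if (mode == "simulate") {
      manifest <- list(config = configToList(config), config_hash = hash,
                       files = basename(files))
      mf <- file.path(config$outDir, "manifest.json")
      jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      return(invisible(list(files = c(files, mf))))
    }
  }

  if (mode == "analyze") {
    cellsByCondition <- lapply(config$fA, function(f) {
      dir <- file.path(config$inputDir, "images", faTag(f))
      if (!dir.exists(dir)) dir <- file.path(config$inputDir, faTag(f))
      tifs <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
      tifs <- tifs[!grepl("_mask\\.tiff?$", tifs)]
      lapply(tifs, function(tp) {
        list(image = readCellImage(tp, pixelSizeUm = config$pixelSizeUm),
             scene = NULL, id = sub("\\.tiff?$", "", basename(tp)))
      })
    })
    names(cellsByCondition) <- faTag(config$fA)
  }

  if (mode %in% c("full", "analyze")) {
    spotsAll <- list(); clustersAll <- list(); metricsAll <- list()
    summaryRows <- list()
    for (ci in seq_along(config$fA)) {
      f <- config$fA[ci]
      cms <- list()
      for (i in seq_along(cellsByCondition[[ci]])) {
        cell <- cellsByCondition[[ci]][[i]]
        id <- if (!is.null(cell$id)) cell$id else
          sprintf("%s_cell_%02d", faTag(f), i)
        res <- analyzeCellImage(cell$image, cellId = id,
                                boxSize = config$boxSize,
                                noiseTolerance = config$noiseTolerance,
                                threshold = config$threshold,
                                colocFactor = config$colocFactor)
        if (nrow(res$spots))
          spotsAll[[length(spotsAll) + 1L]] <-
            cbind(f_A = f, cell_id = id, res$spots)
        tab <- clusterTable(res$clusters)
        if (nrow(tab))
          clustersAll[[length(clustersAll) + 1L]] <-
            cbind(f_A = f, cell_id = id, tab)
        metricsAll[[length(metricsAll) + 1L]] <-
          cbind(f_A = f, metricsRow(res$metrics))
        cms[[length(cms) + 1L]] <- res$metrics
      }
      if (sum(vapply(cms, function(cm) cm@valid, logical(1))) >= 2L) {
        summaryRows[[length(summaryRows) + 1L]] <- aggregateCondition(cms, f)
      } else {
        warning(sprintf("condition f_A = %g has < 2 valid cells; excluded", f))
      }
    }
    spotsDf <- do.call(rbind, spotsAll)
    clustersDf <- do.call(rbind, clustersAll)
    metricsDf <- do.call(rbind, metricsAll)
    summaryDf <- do.call(rbind, summaryRows)

    writeCsvWithHash(spotsDf, fp <- file.path(config$outDir, "spots.csv"), hash)
    files <- c(files, fp)
    writeCsvWithHash(clustersDf,
                     fp <- file.path(config$outDir, "clusters.csv"), hash)
    files <- c(files, fp)
    writeCsvWithHash(metricsDf,
                     fp <- file.path(config$outDir, "cell_metrics.csv"), hash)
    files <- c(files, fp)
    writeCsvWithHash(summaryDf[, 1:11],
                     fp <- file.path(config$outDir, "condition_summary.csv"),
                     hash)
    files <- c(files, fp)
  } else {
    metricsDf <- utils::read.csv(file.path(config$inputDir, "cell_metrics.csv"),
                                 comment.char = "#")
    clustersDf <- utils::read.csv(file.path(config$inputDir, "clusters.csv"),
                                  comment.char = "#")
    summaryDf <- NULL
  }

  # inference: cell-level metrics grouped by condition; cluster-level pooled
  groupsOf <- function(df, col) {
    split(df[[col]], factor(faTag(df$f_A), levels = faTag(sort(unique(df$f_A)))))
  }
  mv <- metricsDf[metricsDf$valid, ]
  cascades <- list(
    statsCascade(groupsOf(mv, "surface_expression"),
                 metric = "surface_expression", metricType = "generic",
                 alpha = config$alpha,
                 assumptionAlpha = config$assumptionAlpha,
                 mapping = config$mapping, B = config$lillieforsB),
    statsCascade(groupsOf(mv, "n_clusters_norm"),
                 metric = "n_clusters_norm", metricType = "generic",
                 alpha = config$alpha,
                 assumptionAlpha = config$assumptionAlpha,
                 mapping = config$mapping, B = config$lillieforsB),
    statsCascade(groupsOf(mv, "fraction_in_clusters"),
                 metric = "fraction_in_clusters", metricType = "generic",
                 alpha = config$alpha,
                 assumptionAlpha = config$assumptionAlpha,
                 mapping = config$mapping, B = config$lillieforsB),
    statsCascade(groupsOf(clustersDf, "area_um2"),
                 metric = "cluster_area_um2", metricType = "area",
                 alpha = config$alpha,
                 assumptionAlpha = config$assumptionAlpha,
                 mapping = config$mapping, B = config$lillieforsB),
    statsCascade(groupsOf(clustersDf, "density"),
                 metric = "cluster_density", metricType = "density",
                 alpha = config$alpha,
                 assumptionAlpha = config$assumptionAlpha,
                 mapping = config$mapping, B = config$lillieforsB)
  )
  names(cascades) <- vapply(cascades, function(x) x@metric, character(1))
  sf <- file.path(config$outDir, "stats_report.json")
  jsonlite::write_json(list(config_hash = hash,
                            reports = lapply(cascades, statsReportToList)),
                       sf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, sf)

  # density-vs-fraction regression on condition means
  densityMeans <- if (!is.null(summaryDf)) {
    data.frame(f_A = summaryDf$f_A, density = summaryDf$cluster_density_mean)
  } else {
    agg <- stats::aggregate(density ~ f_A, data = clustersDf, FUN = mean)
    data.frame(f_A = agg$f_A, density = agg$density)
  }
  regression <- fitDensityVsFraction(densityMeans)
  rf <- file.path(config$outDir, "regression.json")
  jsonlite::write_json(c(list(config_hash = hash),
                         regressionToList(regression)),
                       rf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, rf)

  manifest <- list(config = configToList(config), config_hash = hash,
                   files = basename(files))
  mf <- file.path(config$outDir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, mf)

  invisible(list(summary = summaryDf, statsReports = cascades,
                 regression = regression, files = files))
}
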