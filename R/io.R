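# TIFF / CSV / JSON input-output. Convention: two-page 16-bit grayscale TIFF,
# page 1 = red (Kv channel), page 2 = green (scaffold); the cell mask is a
# separate one-page TIFF (0/1). Intensities are stored as value/65535 and
# clamped to [0, 65535] on write. Row-major, origin top-left.

INTENSITY_MAX <- 65535

#' Write a two-channel cell image (and its mask) as 16-bit TIFF
#'
#' @param image a [CellImage-class].
#' @param path output TIFF path (two pages: red, green).
#' @param maskPath output path for the one-page mask TIFF; defaults to
#'   `path` with a `_mask.tif` suffix.
#' @return Invisibly, `c(path, maskPath)`.
#' @export
writeCellImage <- function(image, path, maskPath = NULL) {
  validObject(image)
  if (is.null(maskPath)) maskPath <- sub("\\.tiff?$", "_mask.tif", path)
  clamp <- function(m) pmin(pmax(round(m), 0), INTENSITY_MAX) / INTENSITY_MAX
  tiff::writeTIFF(list(clamp(redChannel(image)), clamp(greenChannel(image))),
                  path, bits.per.sample = 16L)
  tiff::writeTIFF(cellMask(image) * 1, maskPath, bits.per.sample = 8L)
  invisible(c(path, maskPath))
}

#' Read a two-channel cell image and its mask
#'
#' @param path two-page TIFF (red, green). A file with fewer than two pages
#'   raises a missing-channel error.
#' @param maskPath mask TIFF path; defaults to the `_mask.tif` sibling.
#' @param pixelSizeUm microns per pixel of the acquisition.
#' @return A [CellImage-class] with intensities on the original 0..65535
#'   scale.
#' @export
readCellImage <- function(path, maskPath = NULL, pixelSizeUm = 0.15) {
  if (is.null(maskPath)) maskPath <- sub("\\.tiff?$", "_mask.tif", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L)
    stop(sprintf("%s: expected 2 channels (red, green), found %d",
                 path, length(pages)))
  mask <- tiff::readTIFF(maskPath) > 0.5
  new("CellImage",
      red = pages[[1L]] * INTENSITY_MAX,
      green = pages[[2L]] * INTENSITY_MAX,
      mask = mask,
      pixelSizeUm = pixelSizeUm)
}

#' Write a scene's image, ground truth and parameters to disk
#'
#' Writes `<id>.tif` (+ `<id>_mask.tif`), a ground-truth CSV with one row per
#' clustering site (cell id, centre row/col, radius in microns, true density,
#' co-localization flag) and a JSON sidecar with the scene parameters and the
#' channel convention.
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory (created if needed).
#' @param id character cell identifier used in file names.
#' @param image optional pre-rendered [CellImage-class]; rendered if NULL.
#' @return Invisibly, the paths written.
#' @export
writeScene <- function(scene, dir, id = "cell", image = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(image)) image <- renderScene(scene)
  tifPath <- file.path(dir, paste0(id, ".tif"))
  paths <- writeCellImage(image, tifPath)
  truth <- sceneClusters(scene)
  truthPath <- file.path(dir, paste0(id, "_truth.csv"))
  utils::write.csv(cbind(cell_id = id, truth), truthPath, row.names = FALSE)
  p <- scene@params
  sidecar <- list(
    cell_id = id,
    channels = list(`1` = "red (Kv channel)", `2` = "green (scaffold)"),
    pixel_size_um = p@pixelSizeUm,
    image_shape = p@imageShape,
    params = list(
      cell_axes_px = p@cellAxes, cluster_rate = p@clusterRate,
      radius_log_mean = p@radiusLogMean, radius_log_sd = p@radiusLogSd,
      mean_density = p@meanDensity, density_cv = p@densityCV,
      diffuse_level = p@diffuseLevel, background_level = p@backgroundLevel,
      noise_sd = p@noiseSd, green_level = p@greenLevel,
      scaffold_coloc_prob = p@scaffoldColocProb, seed = p@seed),
    true_metrics = trueMetrics(scene))
  jsonPath <- file.path(dir, paste0(id, "_params.json"))
  jsonlite::write_json(sidecar, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, truthPath, jsonPath))
}
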