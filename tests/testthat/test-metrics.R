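emptyClusterSet <- function(img) {
  suppressWarnings(segmentClusters(redChannel(img), cellMask(img),
                                   data.frame(row = integer(), col = integer(),
                                              peak = numeric(),
                                              prominence = numeric()),
                                   threshold = max(redChannel(img)) + 1,
                                   pixelSizeUm = pixelSize(img)))
}

test_that("a cell without clusters has zero clustered fraction and count", {
  img <- renderScene(makeScene(smallParams(clusterRate = 0, seed = 2L)))
  cm <- cellMetrics(img, emptyClusterSet(img))
  expect_identical(cm@fractionInClusters, 0)
  expect_identical(cm@nClustersNorm, 0)
  expect_gt(cm@surfaceExpression, 0)
})

test_that("a cell whose whole signal is one cluster has fraction 1", {
  sc <- singleDiskScene(radiusUm = 0.6, density = 2e5, diffuseLevel = 0,
                        noiseSd = 0, backgroundLevel = 100)
  img <- renderScene(sc)
  res <- analyzeCellImage(img, threshold = 150, noiseTolerance = 10)
  expect_identical(nrow(clusterTable(res$clusters)), 1L)
  expect_equal(res$metrics@fractionInClusters, 1, tolerance = 1e-10)
})

test_that("an 80/20 diffuse/clustered split is recovered across 50 cells", {
  # diffuse level chosen so the expected clustered share of total signal is 0.20:
  # diffuse_per_px = 4 * rate * meanDensity * E[cluster area] * px^2
  rate <- 0.25; meanDensity <- 1.84e5
  eArea <- pi * exp(2 * log(0.33) + 2 * 0.12^2)
  diffuse <- 4 * rate * meanDensity * eArea * 0.15^2
  fracs <- numeric(50)
  for (i in 1:50) {
    sc <- makeScene(smallParams(clusterRate = rate, meanDensity = meanDensity,
                                diffuseLevel = diffuse, seed = 400L + i))
    res <- analyzeCellImage(renderScene(sc))
    fracs[i] <- res$metrics@fractionInClusters
  }
  expect_lt(abs(mean(fracs) - 0.20), 0.02)
})

test_that("clustered signal never exceeds the cell total", {
  for (seed in c(31L, 32L, 33L)) {
    img <- renderScene(makeScene(smallParams(seed = seed)))
    res <- analyzeCellImage(img)
    expect_lte(sum(clusterTable(res$clusters)$ifs_c), res$metrics@ifsT)
    expect_true(validObject(res$metrics))
  }
})

test_that("metrics are offset invariant and scale equivariant", {
  sc <- makeScene(smallParams(seed = 44L))
  img <- renderScene(sc)
  base <- analyzeCellImage(img)

  shift <- function(im, c) new("CellImage", red = redChannel(im) + c,
                               green = greenChannel(im) + c,
                               mask = cellMask(im),
                               pixelSizeUm = pixelSize(im))
  scaled <- function(im, s) new("CellImage", red = redChannel(im) * s,
                                green = greenChannel(im) * s,
                                mask = cellMask(im),
                                pixelSizeUm = pixelSize(im))

  off <- analyzeCellImage(shift(img, 300))
  expect_equal(clusterTable(off$clusters)$area_um2,
               clusterTable(base$clusters)$area_um2)
  expect_equal(clusterTable(off$clusters)$ifs_c,
               clusterTable(base$clusters)$ifs_c)
  expect_equal(off$metrics@ifsT, base$metrics@ifsT)
  expect_equal(off$metrics@fractionInClusters,
               base$metrics@fractionInClusters)

  s <- 2.5
  sc2 <- analyzeCellImage(scaled(img, s))
  expect_equal(clusterTable(sc2$clusters)$area_um2,
               clusterTable(base$clusters)$area_um2)
  expect_equal(clusterTable(sc2$clusters)$ifs_c,
               s * clusterTable(base$clusters)$ifs_c)
  expect_equal(sc2$metrics@ifsT, s * base$metrics@ifsT)
  expect_equal(sc2$metrics@fractionInClusters,
               base$metrics@fractionInClusters)
})

test_that("condition aggregation computes means and standard errors", {
  mk <- function(id, surf, ncl, frac, clusters = 3L) {
    tab <- data.frame(cluster_id = seq_len(clusters), n_pixels = 10L,
                      area_um2 = 0.2 + 0.1 * seq_len(clusters),
                      ifs_c = 1000 * seq_len(clusters),
                      density = 1000 * seq_len(clusters) /
                        (0.2 + 0.1 * seq_len(clusters)),
                      coloc = TRUE, n_spots = 1L)
    new("CellMetrics", cellId = id, cellAreaUm2 = 100, ifsT = 1e6,
        surfaceExpression = surf, nClustersNorm = ncl,
        fractionInClusters = frac, valid = TRUE, clusters = tab)
  }
  same <- list(mk("a", 5, 0.2, 0.1), mk("b", 5, 0.2, 0.1),
               mk("c", 5, 0.2, 0.1))
  agg <- aggregateCondition(same, fA = 0.5)
  expect_identical(agg$surface_expression_se, 0)
  expect_identical(agg$n_clusters_norm_se, 0)
  expect_identical(agg$n_clusters, 9L)

  two <- list(mk("a", 4, 0.2, 0.1), mk("b", 6, 0.2, 0.1))
  agg2 <- aggregateCondition(two, fA = 0.25)
  expect_identical(agg2$surface_expression_mean, 5)
  expect_identical(agg2$surface_expression_se, 1)

  expect_error(aggregateCondition(two[1], fA = 0), "at least 2")
  invalid <- mk("z", 9, 9, 0.5)
  invalid@valid <- FALSE
  expect_identical(aggregateCondition(c(two, list(invalid)), 0.25)$n_cells, 2L)
})

test_that("a zero-signal cell with clusters is flagged invalid", {
  img <- renderScene(makeScene(smallParams(clusterRate = 0, diffuseLevel = 0,
                                           noiseSd = 0, backgroundLevel = 50,
                                           seed = 2L)))
  cs <- emptyClusterSet(img)
  tab <- data.frame(cluster_id = 1L, n_pixels = 4L, area_um2 = 0.09,
                    ifs_c = 10, density = 10 / 0.09, coloc = FALSE,
                    n_spots = 1L)
  cs@table <- tab
  expect_warning(cm <- cellMetrics(img, cs), "invalid")
  expect_false(cm@valid)
})
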