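test_that("background estimation is the median over non-cluster mask pixels", {
  img <- matrix(3, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  clpix <- matrix(FALSE, 10, 10); clpix[4:6, 4:6] <- TRUE
  img[clpix] <- 50
  expect_identical(estimateBackground(img, mask, clpix), 3)
  expect_identical(estimateBackground(img, mask), median(img))
  # gradient fixture against direct enumeration over the same pixel set
  grad <- outer(1:10, 1:10, function(r, c) r + 2 * c + 0.25)
  expect_identical(estimateBackground(grad, mask, clpix),
                   median(grad[mask & !clpix]))
  # cluster pixels covering the whole mask fall back to the mask median
  expect_identical(estimateBackground(grad, mask, mask), median(grad))
  expect_error(estimateBackground(img, mask & FALSE), "empty")
})

test_that("a uniform square around one spot segments by construction", {
  img <- matrix(0, 20, 20)
  img[8:11, 8:11] <- 10
  mask <- matrix(TRUE, 20, 20)
  spots <- data.frame(row = 9L, col = 9L, peak = 10, prominence = 10)
  cs <- segmentClusters(img, mask, spots, threshold = 5, pixelSizeUm = 0.1)
  tab <- clusterTable(cs)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$n_pixels, 16L)
  expect_equal(tab$area_um2, 16 * 0.01)
  expect_equal(tab$ifs_c, 160)
  expect_equal(tab$density, 160 / 0.16)
  expect_identical(tab$n_spots, 1L)
})

test_that("a threshold above the image maximum yields no clusters", {
  img <- matrix(1, 10, 10); img[5, 5] <- 9
  spots <- data.frame(row = 5L, col = 5L, peak = 9, prominence = 8)
  expect_warning(
    cs <- segmentClusters(img, matrix(TRUE, 10, 10), spots, threshold = 20,
                          pixelSizeUm = 0.1),
    "threshold")
  expect_identical(nrow(clusterTable(cs)), 0L)
  # spotless components are discarded silently
  cs2 <- segmentClusters(img, matrix(TRUE, 10, 10),
                         spots[0, , drop = FALSE], threshold = 5,
                         pixelSizeUm = 0.1)
  expect_identical(nrow(clusterTable(cs2)), 0L)
})

test_that("two spots in one connected component give one cluster record", {
  img <- matrix(0, 20, 20)
  img[10, 5:15] <- 10  # a bar connecting both spot positions
  mask <- matrix(TRUE, 20, 20)
  spots <- data.frame(row = c(10L, 10L), col = c(6L, 14L),
                      peak = c(10, 10), prominence = c(10, 10))
  tab <- clusterTable(segmentClusters(img, mask, spots, threshold = 5,
                                      pixelSizeUm = 0.1))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$n_spots, 2L)
  expect_identical(tab$n_pixels, 11L)
})

test_that("diagonal components merge under 8- but not 4-connectivity", {
  img <- matrix(0, 12, 12)
  diagpix <- cbind(4:8, 4:8)
  img[diagpix] <- 10
  mask <- matrix(TRUE, 12, 12)
  spots <- data.frame(row = 6L, col = 6L, peak = 10, prominence = 10)
  tab8 <- clusterTable(segmentClusters(img, mask, spots, threshold = 5,
                                       pixelSizeUm = 0.1, connectivity = 8L))
  expect_identical(tab8$n_pixels, 5L)
  tab4 <- clusterTable(segmentClusters(img, mask, spots, threshold = 5,
                                       pixelSizeUm = 0.1, connectivity = 4L))
  expect_identical(tab4$n_pixels, 1L)
})

test_that("cluster pixel sets are disjoint, in-mask, and offset invariant", {
  sc <- makeScene(smallParams(seed = 9L))
  img <- renderScene(sc)
  red <- redChannel(img); mask <- cellMask(img)
  spots <- detectSpots(red, mask)
  cs <- segmentClusters(red, mask, spots, pixelSizeUm = pixelSize(img))
  lab <- clusterLabels(cs)
  expect_true(all(mask[lab > 0L]))           # union within the mask
  expect_identical(sort(unique(lab[lab > 0L])),
                   clusterTable(cs)$cluster_id)  # labels partition the sites
  # global offset: same pixel sets, same areas, same ifs_c
  off <- 250
  spots2 <- detectSpots(red + off, mask,
                        noiseTolerance = autoNoiseTolerance(red, mask))
  cs2 <- segmentClusters(red + off, mask, spots2,
                         threshold = cs@threshold + off,
                         pixelSizeUm = pixelSize(img))
  expect_identical(clusterLabels(cs2), lab)
  expect_equal(clusterTable(cs2)$ifs_c, clusterTable(cs)$ifs_c)
  expect_equal(clusterTable(cs2)$area_um2, clusterTable(cs)$area_um2)
})

test_that("noise-free scenes recover per-cluster area and density within 10%", {
  sc <- makeScene(smallParams(seed = 21L, noiseSd = 0))
  img <- renderScene(sc)
  res <- analyzeCellImage(img)
  lab <- clusterLabels(res$clusters)
  tab <- clusterTable(res$clusters)
  truth <- sceneClusters(sc)
  pxUm <- pixelSize(img)
  idAt <- lab[cbind(round(truth$row), round(truth$col))]
  claimed <- table(idAt[idAt > 0L])
  for (i in seq_len(nrow(truth))) {
    if (truth$radius_um[i] < 2 * pxUm) next
    id <- idAt[i]
    if (id == 0L || claimed[as.character(id)] > 1L) next
    row <- tab[tab$cluster_id == id, ]
    if (row$n_spots > 1L) next  # merged neighbours: no single-site truth
    expect_lt(abs(row$area_um2 / (pi * truth$radius_um[i]^2) - 1), 0.10)
    expect_lt(abs(row$density / truth$density[i] - 1), 0.10)
  }
})

test_that("scaffold co-localization follows the factor rule", {
  img <- matrix(0, 20, 20); img[8:11, 8:11] <- 10
  mask <- matrix(TRUE, 20, 20)
  spots <- data.frame(row = 9L, col = 9L, peak = 10, prominence = 10)
  cs <- segmentClusters(img, mask, spots, threshold = 5, pixelSizeUm = 0.1)
  flat <- matrix(5, 20, 20)
  expect_false(clusterTable(colocalize(cs, flat, mask))$coloc)
  disk <- flat; disk[8:11, 8:11] <- 50  # 10x background over the cluster
  expect_true(clusterTable(colocalize(cs, disk, mask))$coloc)
  expect_error(colocalize(cs, disk, mask, factor = 0.5), "factor")
})

test_that("simulated co-localization probability is recovered", {
  flags <- logical()
  for (seed in 1:4) {
    sc <- makeScene(sceneParams(scaffoldColocProb = 0.7, seed = seed))
    res <- analyzeCellImage(renderScene(sc))
    flags <- c(flags, clusterTable(res$clusters)$coloc)
  }
  expect_gt(length(flags), 500L)
  phat <- mean(flags)
  ci <- 1.96 * sqrt(0.7 * 0.3 / length(flags))
  expect_lt(abs(phat - 0.7), ci + 0.02)  # small allowance for merged sites
})
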