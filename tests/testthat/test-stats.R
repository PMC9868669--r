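# Monte-Carlo sizes are kept small here; they only need enough resolution to
# classify at the 0.05 assumption level.
B <- 400L

test_that("assumption checks hold their nominal level under the null", {
  normP <- numeric(); levP <- numeric(); bothOk <- 0L
  for (i in 1:100) {
    set.seed(9000L + i)
    rep <- assessAssumptions(list(a = rnorm(200), b = rnorm(200)), B = B)
    normP <- c(normP, rep@normalityP)
    levP <- c(levP, rep@leveneP)
    bothOk <- bothOk + (rep@normalityOk && rep@homoscedasticityOk)
  }
  # per-test rejection rates near the nominal 5% (200 and 100 draws)
  expect_gte(mean(normP < 0.05), 0.02); expect_lte(mean(normP < 0.05), 0.08)
  expect_gte(mean(levP < 0.05), 0.01); expect_lte(mean(levP < 0.05), 0.10)
  # jointly, all three checks pass in a clear majority of replicates
  # (expected rate (1 - 0.05)^3 ~ 0.857)
  expect_gte(bothOk, 80L)
})

test_that("the normality test detects an exponential sample", {
  set.seed(7)
  rep <- assessAssumptions(list(a = rexp(500), b = rnorm(500)), B = B)
  expect_false(rep@normalityOk)
  expect_lt(rep@normalityP[["a"]], 0.05)
  expect_gt(rep@normalityP[["b"]], 0.05)
})

test_that("Levene detects a 25-fold variance ratio", {
  set.seed(8)
  rep <- assessAssumptions(list(a = rnorm(200, sd = 1),
                                b = rnorm(200, sd = 5)), B = B)
  expect_false(rep@homoscedasticityOk)
})

test_that("a zero-variance group is flagged with normality p = 0", {
  set.seed(9)
  rep <- assessAssumptions(list(a = rep(3, 10), b = rnorm(10)), B = B)
  expect_identical(rep@normalityP[["a"]], 0)
  expect_true(rep@zeroVariance[["a"]])
  expect_false(rep@normalityOk)
})

test_that("the Lilliefors statistic matches the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(10)
  for (x in list(rnorm(80), rexp(120), runif(60))) {
    mine <- lillieforsTest(x, B = 2000L)
    ref <- nortest::lillie.test(x)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
  # in the far tail both agree on the verdict
  y <- rexp(500)
  expect_lt(lillieforsTest(y, B = 2000L)$p.value, 0.01)
  expect_lt(nortest::lillie.test(y)$p.value, 0.01)
})

test_that("test selection follows the study mapping, with a conventional switch", {
  mkRep <- function(nOk, hOk) new("AssumptionReport",
    normalityP = c(a = if (nOk) 0.5 else 0.001),
    leveneP = if (hOk) 0.5 else 0.001,
    normalityOk = nOk, homoscedasticityOk = hOk,
    alpha = 0.05, zeroVariance = c(a = FALSE))
  expect_identical(selectTest(mkRep(TRUE, TRUE))$test, "anova")
  expect_identical(selectTest(mkRep(FALSE, TRUE))$test, "welch")
  expect_identical(selectTest(mkRep(TRUE, FALSE))$test, "kruskal")
  both <- selectTest(mkRep(FALSE, FALSE), metricType = "density")
  expect_identical(both$test, "transform")
  expect_identical(both$transform, "sqrt")
  expect_identical(selectTest(mkRep(FALSE, FALSE), metricType = "area")$transform,
                   "log")
  expect_identical(selectTest(mkRep(FALSE, TRUE),
                              mapping = "conventional")$test, "kruskal")
  expect_identical(selectTest(mkRep(TRUE, FALSE),
                              mapping = "conventional")$test, "welch")
})

test_that("omnibus tests handle degenerate and two-group cases", {
  idn <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  om <- omnibusTest(lapply(idn, function(x) x * 0 + 2), "anova")
  expect_identical(om$statistic, 0)
  expect_identical(om$p.value, 1)
  # two-group ANOVA F equals the squared pooled t statistic
  set.seed(12)
  g <- list(a = rnorm(15, 0), b = rnorm(20, 1))
  om2 <- omnibusTest(g, "anova")
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(om2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(om2$p.value, tt$p.value, tolerance = 1e-10)
  # Welch two-group F equals squared Welch t
  om3 <- omnibusTest(g, "welch")
  tw <- t.test(g$a, g$b, var.equal = FALSE)
  expect_equal(om3$statistic, unname(tw$statistic)^2, tolerance = 1e-10)
})

test_that("Kruskal-Wallis is invariant under monotone transformations", {
  set.seed(13)
  g <- list(a = rexp(30), b = rexp(30, 0.5), c = rexp(30, 2))
  h0 <- omnibusTest(g, "kruskal")
  for (f in list(exp, function(x) x^3, function(x) log(x + 1))) {
    h1 <- omnibusTest(lapply(g, f), "kruskal")
    expect_equal(h1$statistic, h0$statistic, tolerance = 1e-12)
    expect_equal(h1$p.value, h0$p.value, tolerance = 1e-12)
  }
})

test_that("Tukey post-hoc matches its k = 2 and degenerate identities", {
  # identical groups: all adjusted p = 1 (q = 0)
  idn <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_true(all(tukeyPosthoc(idn)$p_adj == 1))
  # identical constant groups: defined as 1 by continuity
  expect_true(all(tukeyPosthoc(list(a = c(2, 2), b = c(2, 2)))$p_adj == 1))
  # two groups: Tukey p equals the pooled two-sample t p
  set.seed(14)
  g <- list(a = rnorm(12), b = rnorm(12, 0.8))
  expect_equal(tukeyPosthoc(g)$p_adj,
               t.test(g$a, g$b, var.equal = TRUE)$p.value,
               tolerance = 1e-8)
  expect_error(tukeyPosthoc(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("only comparisons with a strongly shifted group are rejected", {
  set.seed(15)
  g <- lapply(1:5, function(i) rnorm(30, mean = if (i == 3) 5 else 0))
  names(g) <- paste0("g", 1:5)
  tk <- tukeyPosthoc(g)
  hits <- grepl("g3", tk$comparison)
  expect_true(all(tk$p_adj[hits] < 0.01))
  expect_true(all(tk$p_adj[!hits] >= 0.01))
})

test_that("the cascade transforms once when both assumptions fail", {
  set.seed(16)
  g <- list(a = rlnorm(200, 0, 0.5), b = rlnorm(200, 0.5, 1.0),
            c = rlnorm(200, 1.0, 1.5))
  sr <- suppressWarnings(statsCascade(g, metric = "density",
                                      metricType = "density", B = B))
  expect_identical(sr@transformation, "sqrt")
  expect_s4_class(sr, "StatsReport")
  expect_identical(sr@reject, sr@pValue < sr@alpha)
  if (sr@reject) expect_s3_class(sr@tukey, "data.frame") else
    expect_null(sr@tukey)
  # p-values invariant to group relabelling
  sr2 <- suppressWarnings(statsCascade(rev(g), metric = "density",
                                       metricType = "density", B = B))
  expect_equal(sr2@pValue, sr@pValue, tolerance = 1e-9)
})

test_that("the cascade rejects at the measured effect scale of the study", {
  # five conditions of pooled cluster densities, means linear between the
  # homo-tetramer endpoints, Gamma noise at the generator's 30% CV
  fAs <- c(0, 0.25, 0.5, 0.75, 1)
  rejects <- 0L
  for (rep in 1:20) {
    set.seed(5000L + rep)
    g <- lapply(fAs, function(f) {
      m <- expectedMeanDensity(f, 16.51e4, 20.33e4)
      shape <- 1 / 0.3^2
      rgamma(200, shape = shape, rate = shape / m)
    })
    names(g) <- paste0("fA", fAs)
    sr <- suppressWarnings(statsCascade(g, metric = "cluster_density",
                                        metricType = "density", B = 200L))
    rejects <- rejects + sr@reject
  }
  expect_gte(rejects, 19L)
})

test_that("transforming non-positive values shifts with a warning", {
  x <- c(-2, 0, 1, 5)
  expect_warning(y <- kvclust:::transformValues(x, "log"), "shifting")
  expect_true(all(is.finite(y)))
  expect_identical(kvclust:::transformValues(x, "none"), x)
})
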