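# Assumption checks, omnibus test selection, post-hoc comparisons.
#
# The test-selection mapping follows the study design literally: both
# assumptions ok -> one-way ANOVA; only normality violated -> Welch's
# heteroscedastic F; only homoscedasticity violated -> Kruskal-Wallis; both
# violated -> transform once (log for area-type metrics, sqrt for
# density-type) and re-assess. That mapping is unconventional (Welch targets
# unequal variances, Kruskal-Wallis non-normality); mapping = "conventional"
# swaps the two branches.

.lillieforsCache <- new.env(parent = emptyenv())

lillieforsStatistic <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

lillieforsNull <- function(n, B, seed) {
  key <- sprintf("n%d_B%d_s%d", n, B, seed)
  if (!is.null(.lillieforsCache[[key]])) return(.lillieforsCache[[key]])
  D <- withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n * B), n, B)
    cm <- colMeans(m)
    csd <- sqrt((colSums(m^2) - n * cm^2) / (n - 1))
    s <- apply(m, 2L, sort)
    z <- stats::pnorm((s - rep(cm, each = n)) / rep(csd, each = n))
    i <- seq_len(n)
    apply(pmax(i / n - z, z - (i - 1) / n), 2L, max)
  })
  .lillieforsCache[[key]] <- D
  D
}

#' Lilliefors-corrected normality test with Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov test of normality with mean and sd estimated from the
#' sample (Lilliefors correction). The null distribution of the statistic is
#' simulated (`B` standard-normal samples of the same size, each
#' re-standardized by its own estimates) under a fixed seed, and
#' `p = (1 + #[D_null >= D]) / (B + 1)`. Null tables are cached per
#' `(n, B, seed)`.
#'
#' @param x numeric sample, length >= 4, non-degenerate.
#' @param B Monte-Carlo replicates (default 10000).
#' @param mcSeed seed for the null simulation (fixed so reports are
#'   reproducible independent of the caller's RNG state).
#' @return list with `statistic` and `p.value`.
#' @export
lillieforsTest <- function(x, B = 10000L, mcSeed = 1234L) {
  if (length(x) < 4L) stop("need n >= 4 for the normality test")
  if (stats::sd(x) == 0) stop("sample has zero variance")
  D <- lillieforsStatistic(x)
  Dnull <- lillieforsNull(length(x), as.integer(B), as.integer(mcSeed))
  list(statistic = D, p.value = (1 + sum(Dnull >= D)) / (B + 1))
}

#' Check normality and homoscedasticity across groups
#'
#' Per-group [lillieforsTest()] normality p-values (a zero-variance group is
#' flagged and its p set to 0) and a Levene test (center = mean) of equal
#' variances across groups.
#'
#' @param groups named list of numeric vectors, each of length >= 4.
#' @param alpha assumption-check significance level (default 0.05; the study
#'   alpha of 0.01 applies to hypothesis rejection, not to these checks).
#' @param B,mcSeed Monte-Carlo settings passed to [lillieforsTest()].
#' @return An [AssumptionReport-class]. `normalityOk` requires every group
#'   to pass at `alpha`.
#' @export
assessAssumptions <- function(groups, alpha = 0.05, B = 10000L,
                              mcSeed = 1234L) {
  groups <- normalizeGroups(groups)
  if (any(lengths(groups) < 4L)) stop("each group needs n >= 4")
  zeroVar <- vapply(groups, function(x) stats::sd(x) == 0, logical(1))
  normP <- vapply(seq_along(groups), function(i) {
    if (zeroVar[i]) 0
    else lillieforsTest(groups[[i]], B = B, mcSeed = mcSeed)$p.value
  }, numeric(1))
  names(normP) <- names(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  lev <- suppressWarnings(car::leveneTest(values, g, center = mean))
  levP <- lev[["Pr(>F)"]][1L]
  if (is.na(levP)) levP <- 1  # all deviations identical: no heteroscedasticity signal
  new("AssumptionReport",
      normalityP = normP,
      leveneP = levP,
      normalityOk = all(normP >= alpha),
      homoscedasticityOk = levP >= alpha,
      alpha = alpha,
      zeroVariance = zeroVar)
}

#' Select the omnibus test from an assumption report
#'
#' @param report an [AssumptionReport-class].
#' @param metricType "area" metrics transform by log, "density" metrics by
#'   sqrt when both assumptions fail; "generic" defaults to log.
#' @param mapping `"study"` applies the study's literal mapping (see the
#'   file-level note); `"conventional"` maps non-normality to Kruskal-Wallis
#'   and heteroscedasticity to Welch.
#' @return list with `test` ("anova", "welch", "kruskal" or "transform") and
#'   `transform` ("none", "log" or "sqrt").
#' @export
selectTest <- function(report,
                       metricType = c("generic", "area", "density"),
                       mapping = c("study", "conventional")) {
  metricType <- match.arg(metricType)
  mapping <- match.arg(mapping)
  nOk <- report@normalityOk
  hOk <- report@homoscedasticityOk
  if (nOk && hOk) return(list(test = "anova", transform = "none"))
  if (!nOk && !hOk) {
    tr <- switch(metricType, area = "log", density = "sqrt", generic = "log")
    return(list(test = "transform", transform = tr))
  }
  if (mapping == "study") {
    if (!nOk) list(test = "welch", transform = "none")
    else list(test = "kruskal", transform = "none")
  } else {
    if (!nOk) list(test = "kruskal", transform = "none")
    else list(test = "welch", transform = "none")
  }
}

# Log/sqrt transformation with a shift for non-positive values.
transformValues <- function(x, transform) {
  if (transform == "none") return(x)
  lim <- if (transform == "log") 0 else -1e-300
  if (min(x) <= lim) {
    eps <- diff(range(x)) * 1e-6
    if (eps == 0) eps <- 1e-8
    warning(sprintf("%s transform on non-positive values; shifting by %g",
                    transform, -min(x) + eps))
    x <- x - min(x) + eps
  }
  switch(transform, log = log(x), sqrt = sqrt(x))
}

normalizeGroups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' Omnibus group comparison
#'
#' Classical one-way ANOVA F, Welch's heteroscedastic F, or the
#' Kruskal-Wallis H, with their standard reference distributions. When every
#' value in every group is the same constant the statistic is 0 and p = 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param test one of "anova", "welch", "kruskal".
#' @return list with `test`, `statistic` and `p.value`.
#' @export
omnibusTest <- function(groups, test = c("anova", "welch", "kruskal")) {
  test <- match.arg(test)
  groups <- normalizeGroups(groups)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    return(list(test = test, statistic = 0, p.value = 1))
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  res <- switch(test,
    anova = stats::oneway.test(values ~ g, var.equal = TRUE),
    welch = stats::oneway.test(values ~ g, var.equal = FALSE),
    kruskal = stats::kruskal.test(values, g))
  list(test = test, statistic = unname(res$statistic),
       p.value = unname(res$p.value))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range all-pairs comparison after a rejected omnibus test.
#' When all groups are identical constants (zero residual variance and zero
#' differences) the adjusted p-values are 1 by continuity (q = 0).
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return data.frame with `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukeyPosthoc <- function(groups) {
  groups <- normalizeGroups(groups)
  if (any(lengths(groups) < 2L))
    stop("Tukey post-hoc needs n >= 2 in every group")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  hsd <- stats::TukeyHSD(stats::aov(values ~ g))$g
  out <- data.frame(comparison = rownames(hsd), diff = hsd[, "diff"],
                    lwr = hsd[, "lwr"], upr = hsd[, "upr"],
                    p_adj = hsd[, "p adj"], row.names = NULL)
  degenerate <- is.nan(out$p_adj) & out$diff == 0
  out$p_adj[degenerate] <- 1
  out
}

#' Run the full test-selection cascade on one metric
#'
#' Assumption checks, the study's test-selection mapping, at most one
#' transformation round with re-assessment (falling back to Kruskal-Wallis
#' with a warning if both assumptions still fail), the selected omnibus test
#' at `alpha`, and Tukey HSD pairwise comparisons when the null is rejected.
#'
#' @param groups named list of numeric vectors, one per condition.
#' @param metric character metric name for the report.
#' @param metricType "generic", "area" (log transform) or "density" (sqrt).
#' @param alpha omnibus rejection level (0.01 in the study design).
#' @param assumptionAlpha level for the assumption checks (0.05).
#' @param mapping see [selectTest()].
#' @param B,mcSeed Monte-Carlo settings for the normality test.
#' @return A [StatsReport-class].
#' @export
statsCascade <- function(groups, metric = "metric",
                         metricType = c("generic", "area", "density"),
                         alpha = 0.01, assumptionAlpha = 0.05,
                         mapping = c("study", "conventional"),
                         B = 10000L, mcSeed = 1234L) {
  metricType <- match.arg(metricType)
  mapping <- match.arg(mapping)
  groups <- normalizeGroups(groups)
  report <- assessAssumptions(groups, alpha = assumptionAlpha, B = B,
                              mcSeed = mcSeed)
  sel <- selectTest(report, metricType = metricType, mapping = mapping)
  transformation <- "none"
  if (sel$test == "transform") {
    transformation <- sel$transform
    groups <- lapply(groups, transformValues, transform = transformation)
    report <- assessAssumptions(groups, alpha = assumptionAlpha, B = B,
                                mcSeed = mcSeed)
    sel <- selectTest(report, metricType = metricType, mapping = mapping)
    if (sel$test == "transform") {
      warning("assumptions still violated after one transformation; ",
              "falling back to Kruskal-Wallis")
      sel <- list(test = "kruskal", transform = "none")
    }
  }
  om <- omnibusTest(groups, sel$test)
  reject <- om$p.value < alpha
  new("StatsReport",
      metric = metric,
      assumptions = report,
      selectedTest = sel$test,
      transformation = transformation,
      statistic = om$statistic,
      pValue = om$p.value,
      alpha = alpha,
      reject = reject,
      tukey = if (reject) tukeyPosthoc(groups) else NULL)
}
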