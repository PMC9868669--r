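# Binomial hetero-tetramer composition over the transfection axis, and the
# linear density-vs-fraction fit.

#' Hetero-tetramer subunit composition at a transfected fraction
#'
#' With equiprobable, preference-free assembly of four subunits drawn
#' independently at A-subunit fraction `fA`, the number k of high-affinity A
#' subunits per tetramer is Binomial(4, fA):
#' `P(k) = choose(4, k) * fA^k * (1 - fA)^(4 - k)`. Positional isomers
#' (cis/trans arrangements) are collapsed into k-counts.
#'
#' @param fA A-subunit fraction in [0,1].
#' @return A named list of class `CompositionDistribution` with elements
#'   `fA` and `probs` (length-5 vector for k = 0..4, names "k0".."k4";
#'   sums to 1).
#' @examples
#' compositionDistribution(0.5)$probs  # 1/16, 4/16, 6/16, 4/16, 1/16
#' @export
compositionDistribution <- function(fA) {
  if (!is.numeric(fA) || length(fA) != 1L || is.na(fA) || fA < 0 || fA > 1)
    stop("fA must be a single number in [0, 1]")
  probs <- stats::dbinom(0:4, size = 4L, prob = fA)
  names(probs) <- paste0("k", 0:4)
  structure(list(fA = fA, probs = probs), class = "CompositionDistribution")
}

#' @export
print.CompositionDistribution <- function(x, ...) {
  cat("Tetramer composition at f_A =", x$fA, "\n")
  print(round(x$probs, 6))
  cat("mean A subunits per tetramer:", 4 * x$fA, "\n")
  invisible(x)
}

#' Fit mean cluster density against the transfected fraction
#'
#' Ordinary least squares of condition-mean cluster densities on `f_A`.
#' `R^2 = 1 - SS_res / SS_tot`; when the responses have zero variance
#' (SS_tot = 0) the fit is flagged degenerate and `R^2` is defined as 0.
#'
#' @param points data.frame (or list coercible to one) with columns `f_A`
#'   and `density`; at least two distinct `f_A` values are required.
#' @return A [RegressionFit-class].
#' @examples
#' tab1 <- data.frame(f_A = c(0, 0.25, 0.5, 0.75, 1),
#'                    density = c(16.51, 17.89, 18.81, 20.62, 20.33) * 1e4)
#' fitDensityVsFraction(tab1)
#' @export
fitDensityVsFraction <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("f_A", "density") %in% names(points)))
  if (length(unique(points$f_A)) < 2L)
    stop("need at least 2 distinct f_A values")
  fit <- stats::lm(density ~ f_A, data = points)
  ssTot <- sum((points$density - mean(points$density))^2)
  degenerate <- ssTot == 0
  r2 <- if (degenerate) 0 else 1 - sum(stats::residuals(fit)^2) / ssTot
  new("RegressionFit",
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = min(1, max(0, r2)),
      nPoints = nrow(points),
      degenerate = degenerate)
}
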