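# The classical statistics the pipeline applies, with explicit contracts:
# Pearson r with its two-tailed t test, Fisher r-to-z comparison of two
# correlations, Welch's t test, OLS slope, clock-like signature normalization.
# p values are reported raw; no multiple-testing correction is applied.

#' Pearson correlation with two-tailed t test
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with non-zero
#'   variance.
#' @return List: r, n, t_stat, p_two_sided. With |r| = 1 the t statistic is
#'   infinite and p is 0.
#' @export
pearson_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  t_stat <- if (abs(r) < 1) unname(ct$statistic) else sign(r) * Inf
  p <- if (abs(r) < 1) ct$p.value else 0
  list(r = r, n = n, t_stat = t_stat, p_two_sided = p)
}

#' Fisher r-to-z comparison of two correlation coefficients
#'
#' Treats the two correlations as computed on independent samples:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p. When the two correlations share a variable (e.g. both involve
#' the same SNV counts) this independence assumption is only approximate; the
#' returned `independence_assumed` flag records the caveat.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes, each >= 4.
#' @return List: z, p_two_sided, r1, n1, r2, n2, independence_assumed.
#' @export
compare_correlations_fisher <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 < 4 || n2 < 4) stop("each n must be >= 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_two_sided = 2 * pnorm(-abs(z)),
       r1 = r1, n1 = n1, r2 = r2, n2 = n2, independence_assumed = TRUE)
}

#' Welch's unequal-variance t test (two-tailed)
#'
#' @param a,b Numeric vectors, each of length >= 2 with finite variance; at
#'   least one group must have non-zero variance.
#' @return List: statistic, df (Welch–Satterthwaite), p_two_sided,
#'   mean_a, mean_b, n_a, n_b.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, df = length(a) + length(b) - 2,
                  p_two_sided = 1, mean_a = mean(a), mean_b = mean(b),
                  n_a = length(a), n_b = length(b)))
    stop("both groups have zero variance with different means")
  }
  tt <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

#' Ordinary least-squares slope and intercept
#'
#' @param x,y Numeric vectors of equal length >= 2; x must vary.
#' @return List: slope, intercept.
#' @export
linear_slope <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 points")
  if (sd(x) == 0) stop("x has zero variance")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}

#' Normalize signature counts by the clock-like burden
#'
#' Divides every non-clock-like signature count by the clock-like burden
#' SBS1 + SBS5, which scales with age and cell divisions; the clock-like
#' entries themselves are omitted from the output.
#'
#' @param signature_counts Named numeric vector or list of non-negative SBS
#'   counts; names must include SBS1 and SBS5 with SBS1 + SBS5 > 0.
#' @return Named numeric vector of ratios.
#' @export
normalize_by_clock_like <- function(signature_counts) {
  x <- unlist(signature_counts)
  if (!all(c("SBS1", "SBS5") %in% names(x)))
    stop("signature counts must include SBS1 and SBS5")
  if (any(x < 0)) stop("signature counts must be non-negative")
  denom <- x[["SBS1"]] + x[["SBS5"]]
  if (denom <= 0) stop("clock-like burden SBS1 + SBS5 must be positive")
  out <- x[setdiff(names(x), c("SBS1", "SBS5"))]
  out / denom
}
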