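#' Inter-/intra-observer agreement
#'
#' Computes the paired differences `a - b`, their mean and SD, the
#' Bland-Altman limits of agreement `mean +/- 1.96 * SD`, the Pearson
#' correlation of the two readings, and the coefficient of variation:
#' the SD of the differences divided by the mean of the measurement
#' (taken as the grand mean of both observers pooled, a symmetric
#' choice), expressed in percent.
#'
#' @param a,b numeric vectors of paired measurements (ms), aligned by
#'   subject, length >= 3, no missing pairs.
#' @return A list with `meanDifference`, `sdDifference`, `cov` (%),
#'   `pearsonR`, `limits` (lower, upper), `n`, and `flag`
#'   (`"ok"` or `"cov undefined"` when the pooled mean is zero).
#' @examples
#' set.seed(1)
#' a <- rnorm(45, 58, 4); b <- a + rnorm(45, 0, 1.2)
#' observerAgreement(a, b)$cov
#' @export
observerAgreement <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("observers must be aligned pairs")
  if (length(a) < 3L) stop("need at least 3 pairs")
  if (anyNA(a) || anyNA(b)) stop("missing pairs are not allowed")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  pooled <- mean(c(a, b))
  flag <- "ok"
  cov <- if (pooled == 0) { flag <- "cov undefined"; NA_real_ } else
    s / pooled * 100
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    if (identical(a, b)) 1 else NA_real_
  } else stats::cor(a, b)
  list(meanDifference = m, sdDifference = s, cov = cov, pearsonR = r,
       limits = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
       n = length(a), flag = flag)
}

#' Pearson product-moment regression
#'
#' Product-moment correlation with ordinary least-squares slope and
#' intercept and the two-sided p-value from the t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors, `n >= 3`, neither constant.
#' @return A list of class `regressionResult`: `r`, `slope`,
#'   `intercept`, `pValue`, `n`, `flag`.
#' @examples
#' pearsonRegression(1:10, 2 * (1:10) + 1)
#' @export
pearsonRegression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate regression: constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  structure(list(r = unname(ct$estimate),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pValue = ct$p.value, n = n, flag = "ok"),
            class = "regressionResult")
}

#' Paired or unpaired Student's t-test
#'
#' Classical two-sided Student's t-test: the unpaired form uses the
#' pooled-variance statistic (`welch = TRUE` switches to the Welch
#' form). When both groups are constant with equal means the statistic is
#' 0 and `p = 1` by convention, flagged as degenerate.
#'
#' @param groupA,groupB numeric vectors; paired tests require equal
#'   lengths.
#' @param paired logical.
#' @param welch use the Welch (unequal-variance) form for unpaired tests.
#' @return A list with `meanA`, `sdA`, `meanB`, `sdB`, `t`, `pValue`,
#'   `paired`, `flag`.
#' @examples
#' groupTTest(rnorm(20, 60, 3.5), rnorm(20, 56, 3.5))$pValue
#' @export
groupTTest <- function(groupA, groupB, paired = FALSE, welch = FALSE) {
  .checkFlag(paired, "paired")
  a <- as.numeric(groupA); b <- as.numeric(groupB)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (paired && length(a) != length(b))
    stop("paired test requires equal lengths")
  base <- list(meanA = mean(a), sdA = stats::sd(a), meanB = mean(b),
               sdB = stats::sd(b), paired = paired)
  # essentially-constant data (relative to scale) cannot support a t
  # statistic; apply the p = 1 / p = 0 convention instead of erroring
  eps <- function(x) 1e-10 * (mean(abs(x)) + 1)
  degenerate <- if (paired) stats::sd(a - b) <= eps(a - b) else
    (stats::sd(a) <= eps(a) && stats::sd(b) <= eps(b))
  if (degenerate) {
    equal <- if (paired) abs(mean(a - b)) <= eps(a - b) else
      abs(mean(a) - mean(b)) <= eps(c(a, b))
    if (equal)
      return(c(base, list(t = 0, pValue = 1, flag = "degenerate: zero variance")))
    return(c(base, list(t = if (mean(a) > mean(b)) Inf else -Inf,
                        pValue = 0, flag = "degenerate: zero variance")))
  }
  tt <- stats::t.test(a, b, paired = paired,
                      var.equal = !paired || !welch)
  c(base, list(t = unname(tt$statistic), pValue = tt$p.value,
               flag = "ok"))
}

#' Tissue water fraction from wet and dry weights
#'
#' Water fraction is `(wet - dry) / wet`; with fully hydrated tissue
#' holding `fullWaterFraction` (default 0.63, i.e. 63% relative tissue
#' water mass) that reference is set to 100% tissue water, so the
#' normalized value is `fraction / fullWaterFraction * 100`.
#'
#' @param wetWeight,dryWeight grams; `0 <= dry <= wet`, `wet > 0`.
#'   Vectorized.
#' @param fullWaterFraction the fraction defining 100% tissue water.
#' @return A data frame with `waterFraction` and `percentOfFull`.
#' @examples
#' waterFraction(20, 20 * (1 - 0.63))  # fresh tissue: 100% of full water
#' @export
waterFraction <- function(wetWeight, dryWeight, fullWaterFraction = 0.63) {
  wet <- as.numeric(wetWeight); dry <- as.numeric(dryWeight)
  if (length(dry) == 1L) dry <- rep(dry, length(wet))
  if (length(wet) != length(dry)) stop("weights must be aligned")
  if (any(wet <= 0)) stop("wet weight must be positive")
  if (any(dry < 0)) stop("negative dry weight")
  if (any(dry > wet)) stop("dry weight exceeds wet weight")
  .checkScalar(fullWaterFraction, "fullWaterFraction", lower = 0,
               upper = 1, strict = TRUE)
  frac <- (wet - dry) / wet
  data.frame(waterFraction = frac,
             percentOfFull = frac / fullWaterFraction * 100)
}
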