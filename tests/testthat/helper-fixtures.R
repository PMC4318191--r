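# Shared fixtures and independent brute-force oracles.

te15 <- seq(10, 150, by = 10)

exactSeries <- function(h, t2, y0 = 0, te = te15) h * exp(-te / t2) + y0

# Independent Pearson r via the raw covariance formula.
brutePearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}

# Independent pooled-variance two-sample t statistic.
bruteStudentT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Independent per-pixel angular binning: signed angle between the anchor
# vector (centroid -> RV insertion) and the pixel vector via cross/dot
# products, positive clockwise in image coordinates (y down).
bruteSegmentLabels <- function(mask, geometry) {
  idx <- which(mask, arr.ind = TRUE)
  cx <- mean(idx[, 2]); cy <- mean(idx[, 1])
  ax <- geometry@rvInsertion[1] - cx
  ay <- geometry@rvInsertion[2] - cy
  bx <- idx[, 2] - cx; by <- idx[, 1] - cy
  ang <- atan2(ax * by - ay * bx, ax * bx + ay * by) %% (2 * pi)
  nSect <- if (geometry@sliceLevel == "apical") 4L else 6L
  base <- switch(geometry@sliceLevel, basal = 0L, mid = 6L, apical = 12L)
  lab <- matrix(NA_integer_, nrow(mask), ncol(mask))
  lab[idx] <- as.integer(base + pmin(floor(ang / (2 * pi / nSect)),
                                     nSect - 1L) + 1L)
  lab
}

# Rician magnitude draws around a noiseless level (independent of the
# package's internal sampler).
bruteRician <- function(n, signal, sigma) {
  sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}
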