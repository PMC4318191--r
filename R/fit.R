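#' Estimate the constant noise-floor bias of a stack
#'
#' In magnitude images the Rician noise floor appears as an approximately
#' constant offset `y0` under the exponential decay. It is estimated as
#' the mean background magnitude pooled over every echo, from a background
#' region that by default consists of four corner patches (corners are the
#' standard artefact-free choice when no explicit region is drawn).
#'
#' For pure noise the expected magnitude is `sigma * sqrt(pi / 2)`, so the
#' pooled mean converges to the noise floor the fit must subtract.
#'
#' @param stack an [EchoStack-class].
#' @param background `"auto"` for corner patches, or a logical matrix
#'   marking background pixels.
#' @param patchSize side length (pixels) of each corner patch when
#'   `background = "auto"`.
#' @param objectMask optional logical matrix of known object pixels; a
#'   warning is raised if the background region overlaps it.
#' @return Single numeric `y0` (signal units).
#' @examples
#' sim <- simulateEchoStack(noise = noiseSpec(sigma = 0))
#' estimateBias(sim$stack)  # no noise, empty-background level 0
#' @export
estimateBias <- function(stack, background = "auto", patchSize = 8,
                         objectMask = NULL) {
  stopifnot(is(stack, "EchoStack"))
  d <- dim(stack@data)
  if (identical(background, "auto")) {
    p <- min(as.integer(patchSize), floor(min(d[1:2]) / 2))
    if (p < 1L) stop("grid too small for corner patches")
    bg <- matrix(FALSE, d[1], d[2])
    # the row x col cross product selects exactly the four corner patches
    bg[c(seq_len(p), d[1] - p + seq_len(p)),
       c(seq_len(p), d[2] - p + seq_len(p))] <- TRUE
  } else {
    bg <- background
    if (!is.logical(bg) || !identical(dim(bg), d[1:2]))
      stop("background must be 'auto' or a logical matrix matching the grid")
  }
  if (!any(bg)) stop("background region is empty")
  if (!is.null(objectMask) && any(bg & objectMask))
    warning("background region overlaps the object mask; bias may be inflated")
  mean(stack@data[array(bg, d)])
}

# Vectorized bias-corrected log-linear fit. Y: nPixel x nEcho matrix of
# magnitudes, te: echo times (ms). Points with intensity <= bias are
# dropped per pixel (log of a non-positive residual is undefined, and
# clipping would bias the slope). Returns per-pixel t2, amplitude, rsq,
# n, accepted, reason.
.fitLinearizedMatrix <- function(Y, te, bias, tolerance = c(0.7, 1)) {
  W <- Y > bias
  n <- rowSums(W)
  L <- matrix(0, nrow(Y), ncol(Y))
  L[W] <- log(Y[W] - bias)
  TE <- matrix(te, nrow(Y), ncol(Y), byrow = TRUE)
  St <- rowSums(W * TE)
  Stt <- rowSums(W * TE^2)
  Sl <- rowSums(L)
  Sll <- rowSums(L^2)
  Stl <- rowSums(L * TE)

  ok <- n >= 3
  slope <- rsq <- t2 <- h <- rep(NA_real_, nrow(Y))
  covTL <- Stl - St * Sl / n
  varT <- Stt - St^2 / n
  varL <- Sll - Sl^2 / n
  slope[ok] <- covTL[ok] / varT[ok]
  posVar <- ok & varL > 0
  # mathematically in [0, 1]; clamp roundoff so exact fits pass rsq <= 1
  rsq[posVar] <- pmin(1, pmax(0, covTL[posVar]^2 /
                                   (varT[posVar] * varL[posVar])))
  t2c <- -1 / slope
  hc <- exp(Sl / n - slope * St / n)

  reason <- rep("insufficient points", nrow(Y))
  decaying <- ok & !is.na(slope) & slope < 0
  reason[ok & !decaying] <- "non-decaying"
  inTol <- decaying & !is.na(rsq) & rsq >= tolerance[1] &
    rsq <= tolerance[2]
  reason[decaying & !inTol] <- "poor fit"
  reason[inTol] <- "ok"
  accepted <- inTol
  t2[accepted] <- t2c[accepted]
  h[decaying] <- hc[decaying]
  list(t2 = t2, amplitude = h, rsq = rsq, n = as.integer(n),
       accepted = accepted, reason = reason)
}

#' Bias-corrected log-linearized single-pixel fit
#'
#' Subtracts the constant noise-floor bias `y0`, drops echoes whose
#' intensity is at or below the bias, takes the natural log and fits
#' ordinary least squares of `ln(S - y0)` against echo time. Then
#' `T2 = -1 / slope` and `h = exp(intercept)`. The goodness of fit is the
#' R-squared of this linearized regression; the fit is accepted iff
#' R-squared lies in `tolerance` (default `[0.7, 1]`) *and* the slope is
#' negative — a well-fit rising series would pass the interval but is
#' unphysical.
#'
#' @param intensities numeric vector of magnitudes, one per echo.
#' @param echoTimes numeric vector of echo times, ms.
#' @param bias constant offset `y0` (from [estimateBias()] or known).
#' @param tolerance length-2 R-squared acceptance interval.
#' @return A [FitResult-class].
#' @examples
#' te <- seq(10, 150, by = 10)
#' fitPixelLinearized(800 * exp(-te / 55), te, bias = 0)
#' @export
fitPixelLinearized <- function(intensities, echoTimes, bias = 0,
                               tolerance = c(0.7, 1)) {
  if (length(intensities) != length(echoTimes))
    stop("intensities and echoTimes must have equal length")
  .checkScalar(bias, "bias", lower = 0)
  f <- .fitLinearizedMatrix(matrix(intensities, nrow = 1), echoTimes,
                            bias, tolerance)
  new("FitResult", t2 = f$t2, amplitude = f$amplitude, bias = bias,
      rsq = f$rsq, accepted = f$accepted, nPointsUsed = f$n,
      reason = f$reason)
}

#' Three-parameter nonlinear fit (validation oracle)
#'
#' Direct nonlinear least squares of `S(TE) = h * exp(-TE / T2) + y0` with
#' all three parameters free, via Levenberg-Marquardt. Used as the
#' independent reference the linearized fit is validated against (and via
#' the `--oracle` CLI path); it is not the production per-pixel path.
#'
#' @param intensities numeric vector of magnitudes, one per echo
#'   (>= 4 echoes: three free parameters).
#' @param echoTimes numeric vector of echo times, ms.
#' @param start optional named list `(h, t2, y0)` of starting values;
#'   defaults are derived from the data.
#' @return A [FitResult-class]; `rsq` is the signal-domain R-squared.
#' @examples
#' te <- seq(10, 150, by = 10)
#' fitPixelNLS(800 * exp(-te / 55) + 20, te)
#' @export
fitPixelNLS <- function(intensities, echoTimes, start = NULL) {
  if (length(intensities) != length(echoTimes))
    stop("intensities and echoTimes must have equal length")
  if (length(intensities) < 4L)
    stop("the three-parameter fit needs at least 4 echoes")
  df <- data.frame(S = as.numeric(intensities),
                   TE = as.numeric(echoTimes))
  if (is.null(start)) {
    y0s <- max(min(df$S) * 0.5, 0)
    hs <- max(df$S[1] - y0s, max(df$S) * 0.1, 1e-6)
    # crude slope from first/last point above the floor
    t2s <- {
      s1 <- df$S[1] - y0s; s2 <- df$S[nrow(df)] - y0s
      if (s1 > 0 && s2 > 0 && s1 > s2)
        (df$TE[nrow(df)] - df$TE[1]) / log(s1 / s2)
      else diff(range(df$TE)) / 2
    }
    start <- list(h = hs, t2 = max(t2s, 1), y0 = y0s)
  }
  # a single start can trip spurious rank-deficiency on exact data, so
  # fall back through a small ladder of alternative starts
  starts <- list(start,
                 list(h = max(df$S), t2 = 50, y0 = 0),
                 list(h = max(df$S) * 1.2,
                      t2 = diff(range(df$TE)) / 3,
                      y0 = max(min(df$S) * 0.9, 1e-3)))
  resFn <- function(p) df$S - (p[1] * exp(-df$TE / p[2]) + p[3])
  jacFn <- function(p) {
    e <- exp(-df$TE / p[2])
    -cbind(e, p[1] * df$TE / p[2]^2 * e, 1)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = unlist(st), fn = resFn, jac = jacFn,
                         lower = c(0, 1e-6, 0),
                         upper = c(Inf, Inf, Inf), control = ctrl),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4 &&
        (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best))
    return(new("FitResult", t2 = NA_real_, amplitude = NA_real_,
               bias = NA_real_, rsq = NA_real_, accepted = FALSE,
               nPointsUsed = nrow(df), reason = "no convergence"))
  cf <- c(h = best$par[[1]], t2 = best$par[[2]], y0 = best$par[[3]])
  res <- resFn(unname(cf))
  ssTot <- sum((df$S - mean(df$S))^2)
  rsq <- if (ssTot > 0) 1 - sum(res^2) / ssTot else NA_real_
  new("FitResult", t2 = unname(cf["t2"]), amplitude = unname(cf["h"]),
      bias = unname(cf["y0"]), rsq = rsq, accepted = TRUE,
      nPointsUsed = nrow(df), reason = "ok")
}

#' Pixel-wise T2 map of a multi-echo stack
#'
#' Applies the bias-corrected linearized fit ([fitPixelLinearized()]) to
#' every pixel of the mask (or the full grid), recording per-pixel
#' acceptance and exclusion reasons. T2 values whose log-domain R-squared
#' falls outside the tolerance interval are not considered (marked `NA`).
#'
#' @param stack an [EchoStack-class].
#' @param mask optional logical matrix restricting evaluation (e.g. the
#'   myocardial mask); default evaluates every pixel.
#' @param bias constant `y0`; `NULL` estimates it with [estimateBias()].
#' @param tolerance length-2 R-squared acceptance interval, default
#'   `c(0.7, 1)`.
#' @param ... passed to [estimateBias()] when `bias` is `NULL`.
#' @return A [T2Map-class].
#' @examples
#' sim <- simulateEchoStack(noise = noiseSpec(sigma = 0))
#' map <- computeT2Map(sim$stack, mask = sim$classMask == "myocardium",
#'                     bias = 0)
#' acceptanceStats(map)$nExcluded
#' @export
computeT2Map <- function(stack, mask = NULL, bias = NULL,
                         tolerance = c(0.7, 1), ...) {
  stopifnot(is(stack, "EchoStack"))
  d <- dim(stack@data)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    stop("mask shape mismatch")
  if (is.null(bias)) bias <- estimateBias(stack, ...)
  if (length(tolerance) != 2L || tolerance[1] >= tolerance[2])
    stop("tolerance must be an increasing length-2 interval")

  Y <- matrix(stack@data, d[1] * d[2], d[3])
  idx <- which(as.vector(mask))
  f <- .fitLinearizedMatrix(Y[idx, , drop = FALSE], stack@echoTimes,
                            bias, tolerance)
  blank <- function(v, init) { m <- matrix(init, d[1], d[2]); m[idx] <- v; m }
  new("T2Map",
      t2 = blank(f$t2, NA_real_),
      amplitude = blank(f$amplitude, NA_real_),
      rsq = blank(f$rsq, NA_real_),
      accepted = blank(f$accepted, FALSE),
      nPointsUsed = blank(f$n, 0L),
      reason = blank(f$reason, "not evaluated"),
      bias = bias, tolerance = as.numeric(tolerance),
      echoTimes = stack@echoTimes, evaluated = blank(TRUE, FALSE))
}
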