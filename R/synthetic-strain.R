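#' Specification of a synthetic circumferential strain curve
#'
#' The noiseless curve is piecewise linear: it starts at 0% strain,
#' descends to `peakSystolic` (negative, circumferential shortening) at
#' `endSystoleFrame`, recovers linearly to `diastolicPlateau` at
#' `midDiastoleFrame`, and holds that plateau until the last frame. Only
#' the extrema and the recovery slope are analysed downstream, so this
#' shape carries exactly the features the metrics read out.
#'
#' @param nFrames number of frames (>= 5).
#' @param frameDt frame spacing in ms (default 25, the acquisition
#'   temporal resolution).
#' @param peakSystolic peak systolic strain, % (must be negative).
#' @param endSystoleFrame 1-based frame index of the systolic minimum.
#' @param midDiastoleFrame 1-based frame index at which the recovery
#'   reaches the diastolic plateau; must satisfy
#'   `endSystoleFrame < midDiastoleFrame <= nFrames`.
#' @param diastolicPlateau plateau strain, % (typically slightly
#'   negative).
#' @param noiseSd per-frame additive Gaussian noise SD, %.
#' @param seed integer seed or `NULL`.
#' @return A `strainCurveSpec` list.
#' @export
strainCurveSpec <- function(nFrames = 40, frameDt = 25,
                            peakSystolic = -20, endSystoleFrame = 14,
                            midDiastoleFrame = 21,
                            diastolicPlateau = -2.5, noiseSd = 0.5,
                            seed = NULL) {
  nFrames <- as.integer(nFrames)
  if (nFrames < 5L) stop("nFrames must be >= 5")
  .checkScalar(frameDt, "frameDt", lower = 0, strict = TRUE)
  if (!is.finite(peakSystolic) || peakSystolic >= 0)
    stop("peakSystolic must be negative (circumferential shortening)")
  endSystoleFrame <- as.integer(endSystoleFrame)
  midDiastoleFrame <- as.integer(midDiastoleFrame)
  if (!(endSystoleFrame < midDiastoleFrame && midDiastoleFrame <= nFrames))
    stop("need endSystoleFrame < midDiastoleFrame <= nFrames")
  if (endSystoleFrame < 2L) stop("endSystoleFrame must be >= 2")
  .checkScalar(noiseSd, "noiseSd", lower = 0)
  structure(list(nFrames = nFrames, frameDt = frameDt,
                 peakSystolic = peakSystolic,
                 endSystoleFrame = endSystoleFrame,
                 midDiastoleFrame = midDiastoleFrame,
                 diastolicPlateau = diastolicPlateau, noiseSd = noiseSd,
                 seed = seed),
            class = "strainCurveSpec")
}

#' Simulate a per-segment strain time series
#'
#' @param spec a [strainCurveSpec()].
#' @param segmentNumber optional AHA segment number to stamp on the
#'   series.
#' @return A [StrainSeries-class]. Re-run with `noiseSd = 0` to obtain the
#'   noiseless reference curve.
#' @examples
#' s <- simulateStrainSeries(strainCurveSpec(noiseSd = 0))
#' min(strainValues(s))  # equals peakSystolic
#' @export
simulateStrainSeries <- function(spec = strainCurveSpec(),
                                 segmentNumber = NA_integer_) {
  stopifnot(inherits(spec, "strainCurveSpec"))
  f <- seq_len(spec$nFrames)
  curve <- numeric(spec$nFrames)
  sys <- f <= spec$endSystoleFrame
  curve[sys] <- spec$peakSystolic * (f[sys] - 1) /
    (spec$endSystoleFrame - 1)
  rec <- f > spec$endSystoleFrame & f <= spec$midDiastoleFrame
  curve[rec] <- spec$peakSystolic +
    (spec$diastolicPlateau - spec$peakSystolic) *
    (f[rec] - spec$endSystoleFrame) /
    (spec$midDiastoleFrame - spec$endSystoleFrame)
  curve[f > spec$midDiastoleFrame] <- spec$diastolicPlateau
  noisy <- .withSeed(spec$seed, {
    if (spec$noiseSd > 0)
      curve + stats::rnorm(spec$nFrames, 0, spec$noiseSd)
    else curve
  })
  strainSeries(noisy, frameDt = spec$frameDt,
               segmentNumber = segmentNumber)
}
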