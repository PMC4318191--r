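#' Peak systolic circumferential strain
#'
#' Defined as the minimal strain value over all time frames (the largest
#' circumferential shortening, hence the most negative Ecc).
#'
#' @param series a [StrainSeries-class] or numeric strain vector (%).
#' @return Peak systolic strain, %.
#' @examples
#' peakSystolicStrain(c(0, -5, -18, -12, -3))
#' @export
peakSystolicStrain <- function(series) {
  s <- .strainVector(series)
  min(s)
}

.strainVector <- function(series) {
  s <- if (is(series, "StrainSeries")) strainValues(series) else
    as.numeric(series)
  if (!length(s)) stop("empty strain series")
  s
}

#' Peak diastolic circumferential strain
#'
#' The minimal strain value over the frames following early diastolic
#' relaxation. Relaxation is detected from the global systolic minimum:
#' the onset is the first later frame at which strain has recovered by
#' `recoveryFraction` (default 20%) of the systolic excursion; early
#' relaxation is then taken to end at the running maximum after that
#' onset, and the returned value is the minimum over the frames at and
#' after that end (for a monotone recovery this is the final-frame
#' value; a post-relaxation dip is picked up as the diastolic peak).
#'
#' @param series a [StrainSeries-class] or numeric strain vector (%).
#' @param recoveryFraction fraction of the systolic excursion that must
#'   be regained before relaxation counts as detected.
#' @return Peak diastolic strain (%), with the detected relaxation
#'   `onset` and relaxation-end frame attached as attributes; `NA` with
#'   attribute `reason = "no recovery detected"` when the series never
#'   recovers by the required fraction.
#' @examples
#' peakDiastolicStrain(c(0, -8, -15, -20, -14, -7, -3, -4, -6, -5))
#' @export
peakDiastolicStrain <- function(series, recoveryFraction = 0.2) {
  s <- .strainVector(series)
  .checkScalar(recoveryFraction, "recoveryFraction", lower = 0, upper = 1)
  iMin <- which.min(s)
  peak <- s[iMin]
  excursion <- s[1] - peak
  threshold <- peak + recoveryFraction * excursion
  after <- seq_along(s) > iMin
  onsetIdx <- which(after & s >= threshold)
  if (!length(onsetIdx) || excursion <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "no recovery detected"
    return(out)
  }
  onset <- onsetIdx[1]
  relaxEnd <- (onset:length(s))[which.max(s[onset:length(s)])]
  out <- min(s[relaxEnd:length(s)])
  attr(out, "onset") <- onset
  attr(out, "relaxationEnd") <- relaxEnd
  out
}

#' Early diastolic circumferential strain rate (Ecc/s)
#'
#' The slope of strain versus time from end-systole to mid-diastole,
#' i.e. the strain change between frames divided by the temporal
#' resolution, expressed per second. The slope is estimated by least
#' squares over the whole window (identical to the two-point slope when
#' the recovery is linear, and equal to `delta strain / delta t` for a
#' two-frame window) and reported as a positive magnitude for diastolic
#' recovery, with the raw signed slope in attribute `"signedSlope"`.
#'
#' @param series a [StrainSeries-class] or numeric strain vector (%).
#' @param endSystole 1-based frame index of end-systole; default the
#'   global-minimum frame.
#' @param midDiastole 1-based frame index of mid-diastole; must exceed
#'   `endSystole`.
#' @param frameDt frame spacing in ms; taken from the series when it is a
#'   [StrainSeries-class].
#' @return Strain rate, Ecc per second.
#' @examples
#' s <- c(seq(0, -20, length.out = 9), seq(-17.5, -2.5, length.out = 7))
#' earlyDiastolicStrainRate(s, endSystole = 9, midDiastole = 16,
#'                          frameDt = 25)
#' @export
earlyDiastolicStrainRate <- function(series, endSystole = NULL,
                                     midDiastole, frameDt = 25) {
  s <- .strainVector(series)
  if (is(series, "StrainSeries")) frameDt <- series@frameDt
  if (is.null(endSystole)) endSystole <- which.min(s)
  endSystole <- as.integer(endSystole)
  midDiastole <- as.integer(midDiastole)
  if (!(endSystole < midDiastole && midDiastole <= length(s)))
    stop("need endSystole < midDiastole <= number of frames")
  win <- endSystole:midDiastole
  if (length(win) < 2L) stop("window shorter than 2 frames")
  tSec <- (win - 1) * frameDt / 1000
  slope <- stats::cov(tSec, s[win]) / stats::var(tSec)
  out <- abs(slope)
  attr(out, "signedSlope") <- slope
  out
}

#' Strain rate within the acquisition window
#'
#' Mean absolute frame-to-frame strain rate over a window (typically the
#' end-diastolic frames during which the echo train is read out); used to
#' verify that the myocardium is nearly motionless during acquisition.
#'
#' @param series a [StrainSeries-class] or numeric strain vector (%).
#' @param window integer frame indices of the acquisition window
#'   (>= 2 frames).
#' @param frameDt frame spacing in ms; taken from the series when it is a
#'   [StrainSeries-class].
#' @return Mean `|delta strain| / delta t`, Ecc per second.
#' @export
acquisitionWindowRate <- function(series, window, frameDt = 25) {
  s <- .strainVector(series)
  if (is(series, "StrainSeries")) frameDt <- series@frameDt
  window <- as.integer(window)
  if (length(window) < 2L) stop("window shorter than 2 frames")
  if (any(window < 1L) || any(window > length(s)) ||
      any(diff(window) != 1L))
    stop("window must be consecutive frames within the series")
  mean(abs(diff(s[window]))) / (frameDt / 1000)
}

#' Regression of segmental T2 on segmental strain
#'
#' Pairs per-segment strain metrics with per-segment T2 and runs the
#' Pearson product-moment regression ([pearsonRegression()]), optionally
#' within sex strata, to test whether local wall motion drives local T2.
#'
#' @param segmentMetrics numeric vector of per-segment strain metrics
#'   (e.g. peak systolic strain).
#' @param segmentT2 numeric vector of matching per-segment T2 (ms).
#' @param sex optional factor/character of per-segment sex labels; when
#'   given, one regression per stratum is returned.
#' @return A `regressionResult` list (see [pearsonRegression()]) or a
#'   named list of them, one per stratum. Constant input within a
#'   stratum yields an entry with `flag = "degenerate"` and `NA`
#'   statistics.
#' @export
strainT2Regression <- function(segmentMetrics, segmentT2, sex = NULL) {
  if (length(segmentMetrics) != length(segmentT2))
    stop("metrics and T2 must be paired by segment")
  run <- function(x, y) {
    tryCatch(pearsonRegression(x, y),
             error = function(e) list(r = NA_real_, slope = NA_real_,
                                      intercept = NA_real_,
                                      pValue = NA_real_, n = length(x),
                                      flag = "degenerate"))
  }
  if (is.null(sex)) return(run(segmentMetrics, segmentT2))
  strata <- split(seq_along(sex), sex)
  lapply(strata, function(i) run(segmentMetrics[i], segmentT2[i]))
}
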