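#' @import methods
NULL

#' Multi-echo magnitude image stack
#'
#' An `EchoStack` holds a short-axis multi-echo magnitude image series as a
#' 3-D array (row, column, echo) together with the echo times in
#' milliseconds. It is the input of the pixel-wise T2 fit.
#'
#' @slot data numeric array, `nrow x ncol x nEchoes`, magnitude intensities
#'   (non-negative, arbitrary signal units).
#' @slot echoTimes numeric vector of echo times in ms, strictly increasing,
#'   one per echo plane.
#'
#' @seealso [EchoStack()] for the constructor, [computeT2Map()]
#' @name EchoStack-class
#' @aliases EchoStack-class
#' @exportClass EchoStack
setClass("EchoStack",
  representation(data = "array", echoTimes = "numeric"))

setValidity("EchoStack", function(object) {
  d <- object@data
  te <- object@echoTimes
  if (length(dim(d)) != 3L)
    return("data must be a 3-D array (row, col, echo)")
  if (dim(d)[3] != length(te))
    return(sprintf("echo count mismatch: %d echo planes but %d echo times",
                   dim(d)[3], length(te)))
  if (length(te) < 3L)
    return("at least 3 echoes are required")
  if (any(!is.finite(te)) || any(diff(te) <= 0))
    return("echo times must be finite and strictly increasing")
  if (any(d < 0, na.rm = TRUE))
    return("magnitude intensities must be non-negative")
  TRUE
})

#' Pixel-wise T2 map with acceptance bookkeeping
#'
#' A `T2Map` is the result of applying the bias-corrected log-linearized
#' monoexponential fit to every evaluated pixel of an [EchoStack].
#' Pixels whose fit was rejected (R-squared outside the tolerance interval,
#' non-decaying slope, or too few points above the noise floor) carry `NA`
#' in the `t2` grid and a reason code in `reason`.
#'
#' @slot t2 numeric matrix of fitted T2 (ms); `NA` where excluded or not
#'   evaluated.
#' @slot amplitude numeric matrix of fitted amplitudes h (signal units).
#' @slot rsq numeric matrix of log-domain R-squared values.
#' @slot accepted logical matrix; `TRUE` where the fit passed the filter.
#' @slot nPointsUsed integer matrix; echoes remaining above the bias.
#' @slot reason character matrix; `"ok"`, `"insufficient points"`,
#'   `"non-decaying"`, `"poor fit"`, or `"not evaluated"`.
#' @slot bias single numeric, the constant noise-floor estimate y0
#'   subtracted before linearization.
#' @slot tolerance numeric length-2, the R-squared acceptance interval.
#' @slot echoTimes numeric, echo times (ms) of the fitted stack.
#' @slot evaluated logical matrix; `TRUE` where a fit was attempted
#'   (inside the supplied mask).
#'
#' @seealso [computeT2Map()], [renderT2Map()], [segmentStatistics()]
#' @name T2Map-class
#' @aliases T2Map-class
#' @exportClass T2Map
setClass("T2Map",
  representation(t2 = "matrix", amplitude = "matrix", rsq = "matrix",
                 accepted = "matrix", nPointsUsed = "matrix",
                 reason = "matrix", bias = "numeric", tolerance = "numeric",
                 echoTimes = "numeric", evaluated = "matrix"))

setValidity("T2Map", function(object) {
  dm <- dim(object@t2)
  same <- function(m) identical(dim(m), dm)
  if (!same(object@amplitude) || !same(object@rsq) || !same(object@accepted) ||
      !same(object@nPointsUsed) || !same(object@reason) ||
      !same(object@evaluated))
    return("all result grids must share the t2 grid's dimensions")
  if (length(object@bias) != 1L || object@bias < 0)
    return("bias must be a single non-negative number")
  if (length(object@tolerance) != 2L ||
      object@tolerance[1] >= object@tolerance[2])
    return("tolerance must be an increasing length-2 interval")
  if (any(object@accepted & is.na(object@t2)))
    return("accepted pixels must carry a T2 value")
  if (any(object@accepted & !object@evaluated))
    return("accepted pixels must have been evaluated")
  TRUE
})

#' Endo-/epicardial contours with the RV insertion landmark
#'
#' A `SliceGeometry` carries the manually drawn (or synthetically rendered)
#' closed endocardial and epicardial polygons of one short-axis slice, the
#' posterior right-ventricular insertion point used to anchor the angular
#' segmentation, and the slice level (`"apical"`, `"mid"`, `"basal"`).
#'
#' Coordinates are pixel coordinates `(x, y)` in displayed image
#' convention: `x` = column, `y` = row, origin top-left, rows increasing
#' downward. Polygons are stored as two-column matrices and are implicitly
#' closed.
#'
#' @slot endo two-column numeric matrix, endocardial contour vertices.
#' @slot epi two-column numeric matrix, epicardial contour vertices.
#' @slot rvInsertion numeric length-2, the insertion landmark `(x, y)`.
#' @slot sliceLevel one of `"apical"`, `"mid"`, `"basal"`.
#' @slot sliceLabel free-text identifier.
#'
#' @seealso [sliceGeometry()], [rasterizeMyocardium()], [splitAhaSegments()]
#' @name SliceGeometry-class
#' @aliases SliceGeometry-class
#' @exportClass SliceGeometry
setClass("SliceGeometry",
  representation(endo = "matrix", epi = "matrix", rvInsertion = "numeric",
                 sliceLevel = "character", sliceLabel = "character"))

setValidity("SliceGeometry", function(object) {
  if (ncol(object@endo) != 2L || ncol(object@epi) != 2L)
    return("contours must be two-column (x, y) matrices")
  if (nrow(object@endo) < 3L || nrow(object@epi) < 3L)
    return("contours need at least 3 vertices")
  if (length(object@rvInsertion) != 2L || any(!is.finite(object@rvInsertion)))
    return("rvInsertion must be a finite (x, y) pair")
  if (!object@sliceLevel %in% c("apical", "mid", "basal"))
    return("sliceLevel must be one of 'apical', 'mid', 'basal'")
  if (.pointInPolygon(object@rvInsertion[1], object@rvInsertion[2],
                      object@endo))
    return("rvInsertion must lie outside the endocardial contour")
  if (!all(.pointInPolygon(object@endo[, 1], object@endo[, 2], object@epi)))
    return("endocardial contour must lie strictly inside the epicardial one")
  TRUE
})

#' Rasterized AHA segment labels of one slice
#'
#' Grid of AHA segment numbers covering the myocardial mask of one slice:
#' 1-6 on basal, 7-12 on mid-ventricular, 13-16 on apical slices (the
#' apical cap, segment 17, is not represented on short-axis maps).
#' Background pixels are `NA`. Labels partition the mask exactly.
#'
#' @slot labels integer matrix of AHA segment numbers, `NA` outside the
#'   myocardium.
#' @slot sliceLevel one of `"apical"`, `"mid"`, `"basal"`.
#' @slot startAngle numeric, anchor-ray angle (radians, image convention)
#'   through the RV insertion at which sector 0 begins.
#' @slot direction `"clockwise"` or `"counterclockwise"` in displayed image
#'   coordinates.
#'
#' @seealso [splitAhaSegments()], [segmentStatistics()]
#' @name SegmentLabelMap-class
#' @aliases SegmentLabelMap-class
#' @exportClass SegmentLabelMap
setClass("SegmentLabelMap",
  representation(labels = "matrix", sliceLevel = "character",
                 startAngle = "numeric", direction = "character"))

setValidity("SegmentLabelMap", function(object) {
  lv <- object@sliceLevel
  if (!lv %in% c("apical", "mid", "basal"))
    return("sliceLevel must be one of 'apical', 'mid', 'basal'")
  expected <- switch(lv, basal = 1:6, mid = 7:12, apical = 13:16)
  got <- sort(unique(object@labels[!is.na(object@labels)]))
  if (length(got) && !all(got %in% expected))
    return(sprintf("labels outside the %s-slice AHA range [%d, %d]",
                   lv, min(expected), max(expected)))
  if (!object@direction %in% c("clockwise", "counterclockwise"))
    return("direction must be 'clockwise' or 'counterclockwise'")
  TRUE
})

#' Per-segment circumferential strain time series
#'
#' Circumferential strain (Ecc, percent; negative = shortening) of one
#' myocardial segment sampled at a fixed frame spacing, the raw input of
#' the strain-rate metrics.
#'
#' @slot strain numeric vector of strain values (%), one per frame.
#' @slot frameDt single numeric, frame spacing in ms (default acquisition
#'   resolution 25 ms).
#' @slot segmentNumber integer AHA segment number (or `NA_integer_`).
#'
#' @seealso [strainSeries()], [peakSystolicStrain()],
#'   [earlyDiastolicStrainRate()]
#' @name StrainSeries-class
#' @aliases StrainSeries-class
#' @exportClass StrainSeries
setClass("StrainSeries",
  representation(strain = "numeric", frameDt = "numeric",
                 segmentNumber = "integer"))

setValidity("StrainSeries", function(object) {
  if (length(object@strain) < 5L)
    return("a strain series needs at least 5 frames")
  if (length(object@frameDt) != 1L || object@frameDt <= 0)
    return("frameDt must be a single positive number (ms)")
  if (any(!is.finite(object@strain)))
    return("strain values must be finite")
  TRUE
})

#' Single-pixel fit result
#'
#' Result of fitting one pixel's echo decay, either by the bias-corrected
#' log-linearized fit ([fitPixelLinearized()]) or by the three-parameter
#' nonlinear oracle ([fitPixelNLS()]).
#'
#' @slot t2 fitted T2 (ms); `NA` when the fit was rejected.
#' @slot amplitude fitted amplitude h (signal units).
#' @slot bias noise-floor offset y0 used (fixed for the linearized fit,
#'   estimated for the nonlinear fit).
#' @slot rsq goodness of fit; log-domain R-squared for the linearized fit,
#'   signal-domain R-squared for the nonlinear fit.
#' @slot accepted logical acceptance flag.
#' @slot nPointsUsed number of echoes that entered the fit.
#' @slot reason `"ok"` or the exclusion reason.
#'
#' @name FitResult-class
#' @aliases FitResult-class
#' @exportClass FitResult
setClass("FitResult",
  representation(t2 = "numeric", amplitude = "numeric", bias = "numeric",
                 rsq = "numeric", accepted = "logical",
                 nPointsUsed = "integer", reason = "character"))

setValidity("FitResult", function(object) {
  if (isTRUE(object@accepted) && (is.na(object@t2) || object@t2 <= 0))
    return("accepted fits must carry a positive T2")
  TRUE
})
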