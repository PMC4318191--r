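#' Construct a multi-echo stack
#'
#' @param data numeric 3-D array (row, col, echo) of magnitude intensities.
#' @param echoTimes numeric vector of echo times in ms, strictly
#'   increasing, one per echo plane.
#' @return An [EchoStack-class] object.
#' @examples
#' te <- seq(10, 150, by = 10)
#' arr <- array(rep(800 * exp(-te / 55), each = 16), c(4, 4, 15))
#' stack <- EchoStack(arr, te)
#' nEchoes(stack)
#' @export
EchoStack <- function(data, echoTimes) {
  new("EchoStack", data = data, echoTimes = as.numeric(echoTimes))
}

#' Construct a slice geometry
#'
#' @param endo,epi two-column `(x, y)` matrices of contour vertices in
#'   pixel coordinates (column = x, row = y, origin top-left).
#' @param rvInsertion `(x, y)` of the posterior RV insertion landmark,
#'   on or near the epicardium.
#' @param sliceLevel `"apical"`, `"mid"` or `"basal"`.
#' @param sliceLabel free-text identifier.
#' @return A [SliceGeometry-class] object.
#' @export
sliceGeometry <- function(endo, epi, rvInsertion, sliceLevel,
                          sliceLabel = "slice") {
  new("SliceGeometry", endo = as.matrix(endo), epi = as.matrix(epi),
      rvInsertion = as.numeric(rvInsertion), sliceLevel = sliceLevel,
      sliceLabel = sliceLabel)
}

#' Construct a strain series
#'
#' @param strain numeric vector of circumferential strain (%) per frame;
#'   negative values denote shortening.
#' @param frameDt frame spacing in ms (default 25, the SENC acquisition
#'   resolution).
#' @param segmentNumber optional AHA segment number.
#' @return A [StrainSeries-class] object.
#' @export
strainSeries <- function(strain, frameDt = 25, segmentNumber = NA_integer_) {
  new("StrainSeries", strain = as.numeric(strain),
      frameDt = as.numeric(frameDt),
      segmentNumber = as.integer(segmentNumber))
}

#' Echo times of a stack or map
#' @param x an [EchoStack-class] or [T2Map-class].
#' @return numeric vector of echo times (ms).
#' @name echoTimes
#' @export
setMethod("echoTimes", "EchoStack", function(x) x@echoTimes)

#' @rdname echoTimes
#' @export
setMethod("echoTimes", "T2Map", function(x) x@echoTimes)

#' Number of echoes
#' @param x an [EchoStack-class].
#' @return integer echo count.
#' @name nEchoes
#' @export
setMethod("nEchoes", "EchoStack", function(x) length(x@echoTimes))

#' Fitted T2 grid
#' @param x a [T2Map-class].
#' @return numeric matrix of T2 (ms), `NA` where excluded.
#' @name t2Values
#' @export
setMethod("t2Values", "T2Map", function(x) x@t2)

#' Acceptance mask of a T2 map
#' @param x a [T2Map-class].
#' @return logical matrix, `TRUE` where the pixel fit was accepted.
#' @name acceptedMask
#' @export
setMethod("acceptedMask", "T2Map", function(x) x@accepted)

#' Acceptance bookkeeping of a T2 map
#'
#' @param x a [T2Map-class].
#' @return A list with `nEvaluated`, `nAccepted`, `nExcluded`,
#'   `fractionExcluded` and a table of exclusion `reasons`.
#' @name acceptanceStats
#' @export
setMethod("acceptanceStats", "T2Map", function(x) {
  ev <- x@evaluated
  acc <- x@accepted & ev
  nEval <- sum(ev)
  nAcc <- sum(acc)
  reasons <- table(x@reason[ev & !acc])
  list(nEvaluated = nEval, nAccepted = nAcc, nExcluded = nEval - nAcc,
       fractionExcluded = if (nEval > 0) (nEval - nAcc) / nEval else NA_real_,
       reasons = reasons)
})

#' Segment label grid
#' @param x a [SegmentLabelMap-class].
#' @return integer matrix of AHA labels, `NA` outside the myocardium.
#' @name segmentLabels
#' @export
setMethod("segmentLabels", "SegmentLabelMap", function(x) x@labels)

#' Slice level accessor
#' @param x a [SliceGeometry-class] or [SegmentLabelMap-class].
#' @return `"apical"`, `"mid"` or `"basal"`.
#' @name sliceLevel
#' @export
setMethod("sliceLevel", "SliceGeometry", function(x) x@sliceLevel)

#' @rdname sliceLevel
#' @export
setMethod("sliceLevel", "SegmentLabelMap", function(x) x@sliceLevel)

#' Strain values per frame
#' @param x a [StrainSeries-class].
#' @return numeric vector (%).
#' @name strainValues
#' @export
setMethod("strainValues", "StrainSeries", function(x) x@strain)

#' Frame times of a strain series
#' @param x a [StrainSeries-class].
#' @return numeric vector of frame times in ms, starting at 0.
#' @name frameTimes
#' @export
setMethod("frameTimes", "StrainSeries",
          function(x) (seq_along(x@strain) - 1) * x@frameDt)

setMethod("show", "EchoStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("EchoStack: %d x %d pixels, %d echoes (TE %g..%g ms)\n",
              d[1], d[2], d[3], min(object@echoTimes),
              max(object@echoTimes)))
})

setMethod("show", "T2Map", function(object) {
  st <- acceptanceStats(object)
  cat(sprintf(paste0(
    "T2Map: %d x %d pixels, bias y0 = %.3g, R^2 tolerance [%g, %g]\n",
    "  evaluated %d, accepted %d (%.1f%% excluded)\n"),
    nrow(object@t2), ncol(object@t2), object@bias,
    object@tolerance[1], object@tolerance[2],
    st$nEvaluated, st$nAccepted, 100 * st$fractionExcluded))
  if (st$nAccepted > 0)
    cat(sprintf("  accepted T2: median %.1f ms, range [%.1f, %.1f] ms\n",
                stats::median(object@t2[object@accepted]),
                min(object@t2[object@accepted]),
                max(object@t2[object@accepted])))
})

setMethod("show", "SliceGeometry", function(object) {
  cat(sprintf(paste0("SliceGeometry '%s' (%s): endo %d vertices,",
                     " epi %d vertices, RV insertion (%.1f, %.1f)\n"),
              object@sliceLabel, object@sliceLevel, nrow(object@endo),
              nrow(object@epi), object@rvInsertion[1],
              object@rvInsertion[2]))
})

setMethod("show", "SegmentLabelMap", function(object) {
  labs <- sort(unique(object@labels[!is.na(object@labels)]))
  cat(sprintf("SegmentLabelMap (%s): %d segments {%s}, %d myocardial pixels\n",
              object@sliceLevel, length(labs),
              paste(labs, collapse = ","),
              sum(!is.na(object@labels))))
})

setMethod("show", "StrainSeries", function(object) {
  cat(sprintf(paste0("StrainSeries (segment %s): %d frames at %g ms, ",
                     "range [%.2f, %.2f] %%\n"),
              ifelse(is.na(object@segmentNumber), "?",
                     object@segmentNumber),
              length(object@strain), object@frameDt, min(object@strain),
              max(object@strain)))
})

setMethod("show", "FitResult", function(object) {
  if (isTRUE(object@accepted))
    cat(sprintf(
      "FitResult: T2 = %.3f ms, h = %.3g, y0 = %.3g, R^2 = %.4f (%d points)\n",
      object@t2, object@amplitude, object@bias, object@rsq,
      object@nPointsUsed))
  else
    cat(sprintf("FitResult: excluded (%s)\n", object@reason))
})
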