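#' Specification of a tissue-drying series
#'
#' Emulates the muscle-phantom dehydration experiment: pieces of tissue
#' are dried for increasing durations, weighed wet and (after complete
#' drying) dry, and imaged. Tissue water fraction is
#' `(wet - dry) / wet`; at time 0 it equals `fullWaterFraction` (default
#' 0.63, i.e. 63% relative tissue water mass, which defines 100% tissue
#' water). The remaining-water mass decays linearly at `dryingRate` per
#' hour and reaches exactly 0 at `1 / dryingRate` hours, so late rows form
#' a fully-dried plateau. True T2 tracks water content linearly:
#' `T2 = t2AtFullWater - t2WaterSlope * (100 - percentOfFull)`.
#'
#' @param initialWetWeight wet weight of each piece at time 0, grams.
#' @param fullWaterFraction water fraction of fresh tissue, in (0, 1).
#' @param dryingTimes drying durations in hours, ascending.
#' @param dryingRate fraction of the initial water mass removed per hour;
#'   default 0.05 (complete drying at 20 h).
#' @param t2WaterSlope ms per percent of full tissue water.
#' @param t2AtFullWater T2 at 100% tissue water, ms.
#' @return A `dryingSpec` list.
#' @export
dryingSpec <- function(initialWetWeight = 20, fullWaterFraction = 0.63,
                       dryingTimes = c(0, 0.5, 1, 2, 3, 4, 5, 6, 7, 8,
                                       10, 11, 15, 20, 24),
                       dryingRate = 0.05, t2WaterSlope = 0.4,
                       t2AtFullWater = 60) {
  .checkScalar(initialWetWeight, "initialWetWeight", lower = 0,
               strict = TRUE)
  .checkScalar(fullWaterFraction, "fullWaterFraction", lower = 0,
               upper = 1, strict = TRUE)
  if (any(dryingTimes < 0)) stop("dryingTimes must be non-negative")
  .checkScalar(dryingRate, "dryingRate", lower = 0, strict = TRUE)
  structure(list(initialWetWeight = initialWetWeight,
                 fullWaterFraction = fullWaterFraction,
                 dryingTimes = sort(as.numeric(dryingTimes)),
                 dryingRate = dryingRate, t2WaterSlope = t2WaterSlope,
                 t2AtFullWater = t2AtFullWater),
            class = "dryingSpec")
}

#' Simulate a drying series with known water fraction and T2
#'
#' Deterministic: the drying model has no noise term — measurement noise
#' enters only if the resulting T2 values are re-imaged through
#' [simulateEchoStack()].
#'
#' @param spec a [dryingSpec()].
#' @return A data frame with columns `time` (h), `wetWeight` (g),
#'   `dryWeight` (g, constant), `waterFraction` (of wet weight),
#'   `percentOfFull` (% of full tissue water) and `trueT2` (ms).
#' @examples
#' simulateDryingSeries(dryingSpec())[c(1, 15), ]
#' @export
simulateDryingSeries <- function(spec = dryingSpec()) {
  stopifnot(inherits(spec, "dryingSpec"))
  w0 <- spec$initialWetWeight
  dry <- w0 * (1 - spec$fullWaterFraction)
  waterLeft <- pmax(0, 1 - spec$dryingRate * spec$dryingTimes)
  wet <- dry + w0 * spec$fullWaterFraction * waterLeft
  frac <- (wet - dry) / wet
  # percent of full water on the same wet-basis ratio the weighing
  # analysis computes, so generator and analysis agree row by row
  pct <- frac / spec$fullWaterFraction * 100
  t2 <- spec$t2AtFullWater - spec$t2WaterSlope * (100 - pct)
  data.frame(time = spec$dryingTimes, wetWeight = wet, dryWeight = dry,
             waterFraction = frac, percentOfFull = pct, trueT2 = t2)
}
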