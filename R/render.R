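#' Colour-code a T2 map with a spectral look-up table
#'
#' Maps T2 values through a spectral LUT with 0 ms (range minimum)
#' rendered black and the range maximum (default 150 ms) rendered red;
#' values outside the range are clamped to its ends. Excluded pixels get a
#' sentinel colour outside the table (white by default) so they are never
#' confused with a valid T2.
#'
#' @param map a [T2Map-class], or a plain numeric matrix of T2 values
#'   (`NA` = excluded).
#' @param range length-2 display range in ms, default `c(0, 150)`.
#' @param nColours LUT resolution.
#' @param excludedColour sentinel colour for excluded pixels.
#' @return A numeric array `nrow x ncol x 3` of RGB values in `[0, 1]`,
#'   with the hex LUT attached as attribute `"lut"`.
#' @examples
#' img <- renderT2Map(matrix(c(0, 75, 150, NA), 2, 2))
#' img[1, 1, ]  # black
#' @export
renderT2Map <- function(map, range = c(0, 150), nColours = 256,
                        excludedColour = "#FFFFFF") {
  vals <- if (is(map, "T2Map")) t2Values(map) else as.matrix(map)
  if (length(range) != 2L || range[1] >= range[2])
    stop("range must satisfy min < max")
  lut <- grDevices::colorRampPalette(
    c("black", "#00008B", "blue", "cyan", "green", "yellow",
      "orange", "red"))(nColours)
  clamped <- pmin(pmax(vals, range[1]), range[2])
  idx <- 1 + round((clamped - range[1]) / diff(range) * (nColours - 1))
  cols <- ifelse(is.na(idx), excludedColour, lut[idx])
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, c(nrow(vals), ncol(vals), 3))
  for (k in 1:3) out[, , k] <- matrix(rgb[k, ], nrow(vals), ncol(vals))
  attr(out, "lut") <- lut
  attr(out, "range") <- range
  out
}

#' Write a colour render to PNG
#'
#' @param img array from [renderT2Map()].
#' @param path output file.
#' @return `path`, invisibly. The LUT range is embedded in the PNG text
#'   metadata.
#' @export
writeRenderPNG <- function(img, path) {
  rng <- attr(img, "range")
  png::writePNG(img, target = path,
                text = c(t2_range_ms = paste(rng, collapse = ",")))
  invisible(path)
}
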