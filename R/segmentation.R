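#' Rasterize the myocardial annulus from contours
#'
#' A pixel belongs to the myocardium iff its center lies inside the
#' epicardial polygon and outside the endocardial one (even-odd fill,
#' pixel centers decide membership).
#'
#' @param geometry a [SliceGeometry-class].
#' @param gridSize integer length-2 `(rows, cols)`.
#' @return Logical matrix `rows x cols`; `TRUE` on the myocardium.
#' @examples
#' ph <- phantomSpec()
#' mask <- rasterizeMyocardium(phantomGeometry(ph), ph$gridSize)
#' sum(mask)  # close to pi * (epi^2 - endo^2)
#' @export
rasterizeMyocardium <- function(geometry, gridSize) {
  stopifnot(is(geometry, "SliceGeometry"))
  gridSize <- as.integer(gridSize)
  if (length(gridSize) != 2L || any(gridSize < 1L))
    stop("gridSize must be two positive integers")
  .checkSimplePolygon(geometry@endo)
  .checkSimplePolygon(geometry@epi)
  nr <- gridSize[1]; nc <- gridSize[2]
  px <- rep(seq_len(nc), each = nr)   # x = column of the pixel center
  py <- rep(seq_len(nr), times = nc)  # y = row
  inEpi <- .pointInPolygon(px, py, geometry@epi)
  inEndo <- .pointInPolygon(px, py, geometry@endo)
  mask <- matrix(inEpi & !inEndo, nr, nc)
  if (!any(mask)) stop("degenerate annulus: rasterized myocardium is empty")
  mask
}

# Reject self-intersecting contours (non-adjacent edge crossings).
.checkSimplePolygon <- function(poly) {
  n <- nrow(poly)
  if (n > 200L) return(invisible(TRUE))  # O(n^2) check on small polygons only
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      p <- seg[i, 1:2]; r <- seg[i, 3:4] - p
      q <- seg[j, 1:2]; s <- seg[j, 3:4] - q
      denom <- cross(r[1], r[2], s[1], s[2])
      if (abs(denom) < 1e-12) next
      t <- cross(q[1] - p[1], q[2] - p[2], s[1], s[2]) / denom
      u <- cross(q[1] - p[1], q[2] - p[2], r[1], r[2]) / denom
      if (t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9)
        stop("self-intersecting contour polygon")
    }
  }
  invisible(TRUE)
}

#' Split the myocardium into AHA segments
#'
#' Divides the myocardial mask into angular sectors anchored at the
#' posterior RV insertion: the ray from the mask centroid through the
#' insertion landmark starts sector 0, and sectors sweep clockwise in
#' displayed image coordinates (origin top-left, rows down). Mid and
#' basal slices get 6 sectors of 60 degrees, apical slices 4 sectors of
#' 90 degrees; angular bins are half-open `[start, start + width)`.
#' Sectors are numbered sequentially from the anchor: 1-6 (basal), 7-12
#' (mid), 13-16 (apical).
#'
#' The anterior-insertion counterclockwise AHA convention is available
#' via `direction` and by supplying the anterior landmark instead.
#'
#' @param mask logical myocardial mask (from [rasterizeMyocardium()]).
#' @param geometry a [SliceGeometry-class]; supplies the insertion
#'   landmark and slice level.
#' @param direction `"clockwise"` (default, as segmented here) or
#'   `"counterclockwise"`.
#' @return A [SegmentLabelMap-class].
#' @examples
#' ph <- phantomSpec(sliceLevel = "apical")
#' geo <- phantomGeometry(ph)
#' labs <- splitAhaSegments(rasterizeMyocardium(geo, ph$gridSize), geo)
#' table(segmentLabels(labs))
#' @export
splitAhaSegments <- function(mask, geometry, direction = "clockwise") {
  stopifnot(is(geometry, "SliceGeometry"))
  if (!is.logical(mask) || !any(mask)) stop("mask must be a non-empty logical matrix")
  lv <- geometry@sliceLevel
  nSect <- if (lv == "apical") 4L else 6L
  base <- switch(lv, basal = 0L, mid = 6L, apical = 12L)

  idx <- which(mask, arr.ind = TRUE)
  cx <- mean(idx[, 2]); cy <- mean(idx[, 1])  # centroid (x = col, y = row)
  anchor <- .imageAngle(geometry@rvInsertion[1] - cx,
                        geometry@rvInsertion[2] - cy)
  ang <- .angleFrom(.imageAngle(idx[, 2] - cx, idx[, 1] - cy), anchor,
                    direction)
  sector <- pmin(floor(ang / (2 * pi / nSect)), nSect - 1L)
  labels <- matrix(NA_integer_, nrow(mask), ncol(mask))
  labels[idx] <- base + as.integer(sector) + 1L

  # partition sanity: every mask pixel labelled, nothing outside
  stopifnot(identical(!is.na(labels), mask))
  new("SegmentLabelMap", labels = labels, sliceLevel = lv,
      startAngle = anchor, direction = direction)
}

#' Per-segment and global T2 statistics
#'
#' Mean, median and SD of accepted-pixel T2 per AHA segment, plus the
#' global (all-segment) summary of the slice. Excluded pixels are
#' missing, not zero; a segment whose accepted-pixel count is zero keeps
#' its row with `NA` statistics and raises a warning.
#'
#' @param map a [T2Map-class] (or a numeric T2 matrix with `NA` for
#'   excluded pixels).
#' @param labels a [SegmentLabelMap-class].
#' @return A data frame with one row per segment — `segment`, `nPixels`,
#'   `nExcluded`, `meanT2`, `medianT2`, `sdT2` — and the global slice
#'   summary attached as attribute `"global"` (list with `meanT2`,
#'   `medianT2`, `sdT2`, `nPixels`, `nExcluded`).
#' @export
segmentStatistics <- function(map, labels) {
  stopifnot(is(labels, "SegmentLabelMap"))
  vals <- if (is(map, "T2Map")) t2Values(map) else as.matrix(map)
  lab <- segmentLabels(labels)
  if (!identical(dim(vals), dim(lab))) stop("shape mismatch")
  segs <- sort(unique(lab[!is.na(lab)]))
  rows <- lapply(segs, function(s) {
    v <- vals[!is.na(lab) & lab == s]
    acc <- v[!is.na(v)]
    if (!length(acc))
      warning(sprintf("segment %d has no accepted pixels", s))
    data.frame(segment = s, nPixels = length(v),
               nExcluded = sum(is.na(v)),
               meanT2 = if (length(acc)) mean(acc) else NA_real_,
               medianT2 = if (length(acc)) stats::median(acc) else NA_real_,
               sdT2 = if (length(acc) > 1) stats::sd(acc) else
                 if (length(acc) == 1) 0 else NA_real_)
  })
  out <- do.call(rbind, rows)
  allv <- vals[!is.na(lab)]
  acc <- allv[!is.na(allv)]
  attr(out, "global") <- list(
    meanT2 = if (length(acc)) mean(acc) else NA_real_,
    medianT2 = if (length(acc)) stats::median(acc) else NA_real_,
    sdT2 = if (length(acc) > 1) stats::sd(acc) else NA_real_,
    nPixels = length(allv), nExcluded = sum(is.na(allv)))
  out
}

#' Anteroseptal vs posterolateral sector contrast
#'
#' Pools accepted-pixel means over two configurable segment groups and
#' returns each group's pooled mean and their difference
#' (anteroseptal - posterolateral). Pooling weights segments by accepted
#' pixel count, i.e. it equals the mean over the groups' raw pixels.
#'
#' @param summaries data frame from [segmentStatistics()] (must carry
#'   `segment`, `meanT2`, `nPixels`, `nExcluded`).
#' @param anteroseptal,posterolateral AHA segment numbers of each group.
#' @return List with `anteroseptalMean`, `posterolateralMean`,
#'   `difference` (ms).
#' @export
sectorGroupContrast <- function(summaries,
                                anteroseptal = c(1, 2, 7, 8, 13, 14),
                                posterolateral = c(4, 5, 10, 11, 15, 16)) {
  pool <- function(group) {
    rows <- summaries[summaries$segment %in% group &
                        !is.na(summaries$meanT2), , drop = FALSE]
    if (!nrow(rows)) stop("empty segment group")
    nAcc <- rows$nPixels - rows$nExcluded
    sum(rows$meanT2 * nAcc) / sum(nAcc)
  }
  a <- pool(anteroseptal); p <- pool(posterolateral)
  list(anteroseptalMean = a, posterolateralMean = p, difference = a - p)
}
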