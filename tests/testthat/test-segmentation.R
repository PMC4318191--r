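makeAnnulus <- function(sliceLevel = "mid", rvAngle = 210,
                        grid = c(64, 64), endo = 10, epi = 20) {
  ph <- phantomSpec(gridSize = grid, endoRadius = endo, epiRadius = epi,
                    rvInsertionAngle = rvAngle, sliceLevel = sliceLevel)
  geo <- phantomGeometry(ph)
  list(geometry = geo, mask = rasterizeMyocardium(geo, grid), phantom = ph)
}

test_that("rasterized annulus area matches the analytic value", {
  a <- makeAnnulus(endo = 10, epi = 20)
  analytic <- pi * (20^2 - 10^2)
  expect_lt(abs(sum(a$mask) - analytic) / analytic, 0.02)
  # containment: no myocardial pixel inside the endo polygon
  idx <- which(a$mask, arr.ind = TRUE)
  r <- sqrt((idx[, 2] - 32.5)^2 + (idx[, 1] - 32.5)^2)
  expect_true(all(r >= 10 - 1e-9))
})

test_that("a degenerate annulus is rejected", {
  ph <- phantomSpec(endoRadius = 10, epiRadius = 10.05)
  expect_error(rasterizeMyocardium(phantomGeometry(ph), ph$gridSize),
               "degenerate annulus")
  # self-intersecting polygon
  bow <- cbind(c(10, 30, 30, 10), c(10, 30, 10, 30))
  geo <- makeAnnulus()$geometry
  geoBad <- geo
  geoBad@epi <- bow * 1.5
  geoBad@endo <- bow
  expect_error(rasterizeMyocardium(geoBad, c(64, 64)),
               "self-intersecting")
})

test_that("slice level fixes the sector count and AHA label range", {
  for (cfg in list(list("apical", 13:16), list("mid", 7:12),
                   list("basal", 1:6))) {
    a <- makeAnnulus(sliceLevel = cfg[[1]])
    labs <- segmentLabels(splitAhaSegments(a$mask, a$geometry))
    expect_setequal(unique(labs[!is.na(labs)]), cfg[[2]])
  }
})

test_that("segment labels agree pixel-for-pixel with brute-force binning", {
  for (rvAngle in c(0, 37, 210, 305)) {
    for (lv in c("apical", "mid")) {
      a <- makeAnnulus(sliceLevel = lv, rvAngle = rvAngle)
      labs <- splitAhaSegments(a$mask, a$geometry)
      expect_identical(segmentLabels(labs),
                       bruteSegmentLabels(a$mask, a$geometry))
    }
  }
})

test_that("a pixel 30 degrees clockwise of the insertion ray is AHA 7", {
  a <- makeAnnulus(sliceLevel = "mid", rvAngle = 0)
  labs <- segmentLabels(splitAhaSegments(a$mask, a$geometry))
  idx <- which(a$mask, arr.ind = TRUE)
  cx <- mean(idx[, 2]); cy <- mean(idx[, 1])
  ang <- atan2(idx[, 1] - cy, idx[, 2] - cx) %% (2 * pi)  # anchor at 0
  deg <- ang * 180 / pi
  pick <- which(deg > 25 & deg < 35)
  expect_true(all(labs[idx[pick, , drop = FALSE]] == 7))
})

test_that("segments partition the myocardial mask", {
  a <- makeAnnulus()
  labs <- segmentLabels(splitAhaSegments(a$mask, a$geometry))
  expect_identical(!is.na(labs), a$mask)
  counts <- table(labs)
  expect_equal(sum(counts), sum(a$mask))
})

test_that("per-segment statistics are covariant under a 90-degree rotation", {
  a <- makeAnnulus(rvAngle = 210)
  n <- 64
  set.seed(40)
  t2 <- matrix(NA_real_, n, n)
  t2[a$mask] <- rnorm(sum(a$mask), 60, 3)
  seg <- segmentStatistics(t2, splitAhaSegments(a$mask, a$geometry))

  # rotate image, contours and landmark together by 90 degrees clockwise:
  # (x, y) -> (n + 1 - y, x)
  rot <- function(p) cbind(n + 1 - p[, 2], p[, 1])
  geoR <- sliceGeometry(rot(a$geometry@endo), rot(a$geometry@epi),
                        c(n + 1 - a$geometry@rvInsertion[2],
                          a$geometry@rvInsertion[1]),
                        a$geometry@sliceLevel)
  t2R <- matrix(NA_real_, n, n)
  for (col in seq_len(n)) t2R[col, ] <- rev(t2[, col])
  maskR <- rasterizeMyocardium(geoR, c(n, n))
  segR <- segmentStatistics(t2R, splitAhaSegments(maskR, geoR))
  expect_equal(segR$meanT2, seg$meanT2, tolerance = 1e-9)
  expect_equal(segR$nPixels, seg$nPixels)
})

test_that("segment numbering survives one-pixel erosion of the annulus", {
  a <- makeAnnulus()
  labs <- splitAhaSegments(a$mask, a$geometry)
  eroded <- a$mask
  idx <- which(a$mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    if (!all(a$mask[cbind(r + c(-1, 1, 0, 0), c + c(0, 0, -1, 1))]))
      eroded[r, c] <- FALSE
  }
  labsE <- splitAhaSegments(eroded, a$geometry)
  expect_setequal(unique(segmentLabels(labsE)[eroded]),
                  unique(segmentLabels(labs)[a$mask]))
})

test_that("segment statistics summarise accepted pixels only", {
  a <- makeAnnulus()
  labs <- splitAhaSegments(a$mask, a$geometry)
  t2 <- matrix(NA_real_, 64, 64)
  t2[a$mask] <- 60
  seg <- segmentStatistics(t2, labs)
  expect_equal(seg$meanT2, rep(60, 6))
  expect_equal(seg$medianT2, rep(60, 6))
  expect_equal(seg$sdT2, rep(0, 6))

  # hand-built segment: 10 pixels, 2 excluded, values {50 x4, 70 x4}
  lab1 <- matrix(NA_integer_, 4, 4)
  lab1[1:10] <- 7L
  vals <- matrix(NA_real_, 4, 4)
  vals[1:8] <- c(50, 50, 50, 50, 70, 70, 70, 70)
  s1 <- segmentStatistics(vals, new("SegmentLabelMap", labels = lab1,
                                    sliceLevel = "mid", startAngle = 0,
                                    direction = "clockwise"))
  expect_equal(s1$meanT2, 60)
  expect_equal(s1$medianT2, 60)
  expect_equal(s1$nExcluded, 2)
  expect_equal(s1$nPixels, 10)

  # fully excluded segment keeps its row, with a warning
  vals[] <- NA_real_
  expect_warning(s2 <- segmentStatistics(vals,
    new("SegmentLabelMap", labels = lab1, sliceLevel = "mid",
        startAngle = 0, direction = "clockwise")), "no accepted")
  expect_true(is.na(s2$meanT2))
  expect_equal(s2$nPixels, 10)
})

test_that("sector contrast recovers an injected anteroseptal offset", {
  # +3 ms in sectors 1-2 through the phantom's per-sector T2 table
  ph <- phantomSpec(myocardialT2 = c(63, 63, 60, 60, 60, 60),
                    rvInsertionAngle = 210)
  sim <- simulateEchoStack(ph, echoProtocol(), noiseSpec(sigma = 0))
  mask <- rasterizeMyocardium(sim$geometry, ph$gridSize)
  map <- computeT2Map(sim$stack, mask = mask, bias = 0)
  labs <- splitAhaSegments(mask, sim$geometry)
  seg <- segmentStatistics(map, labs)
  ct <- sectorGroupContrast(seg, anteroseptal = c(7, 8),
                            posterolateral = c(9, 10, 11, 12))
  # rasterized sector edges may disagree with the generator table by a
  # pixel, so the recovered contrast is near 3, not exact
  expect_equal(ct$difference, 3, tolerance = 0.05)

  equal <- seg; equal$meanT2 <- 60
  expect_equal(sectorGroupContrast(equal, c(7, 8), c(10, 11))$difference, 0)
  expect_error(sectorGroupContrast(seg, integer(0), c(10)), "empty")
})

test_that("pooled sector means match brute-force pixel pooling", {
  ph <- phantomSpec()
  sim <- simulateEchoStack(ph, echoProtocol(), noiseSpec(10, seed = 17))
  mask <- rasterizeMyocardium(sim$geometry, ph$gridSize)
  map <- computeT2Map(sim$stack, mask = mask)
  labs <- splitAhaSegments(mask, sim$geometry)
  seg <- segmentStatistics(map, labs)
  grpA <- c(7, 8); grpP <- c(10, 11)
  ct <- sectorGroupContrast(seg, grpA, grpP)
  lab <- segmentLabels(labs)
  t2 <- t2Values(map)
  brute <- mean(t2[lab %in% grpA & !is.na(t2)], na.rm = TRUE) -
    mean(t2[lab %in% grpP & !is.na(t2)], na.rm = TRUE)
  expect_equal(ct$difference, brute, tolerance = 1e-9)
})
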