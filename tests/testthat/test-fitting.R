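test_that("noise-free monoexponential series are recovered exactly", {
  for (h in c(200, 800)) for (t2 in c(20, 55, 120)) for (y0 in c(0, 20)) {
    f <- fitPixelLinearized(exactSeries(h, t2, y0), te15, bias = y0)
    expect_true(f@accepted)
    expect_equal(f@t2, t2, tolerance = 1e-9)
    expect_equal(f@amplitude, h, tolerance = 1e-9)
    expect_equal(f@rsq, 1, tolerance = 1e-12)
  }
})

test_that("linearized and nonlinear fits agree on noise-free data", {
  for (t2 in c(25, 55, 90)) {
    series <- exactSeries(800, t2, 20)
    lin <- fitPixelLinearized(series, te15, bias = 20)
    nls <- fitPixelNLS(series, te15)
    expect_equal(lin@t2, nls@t2, tolerance = 1e-6)
    expect_equal(nls@amplitude, 800, tolerance = 1e-5)
    expect_equal(nls@bias, 20, tolerance = 1e-4)
  }
})

test_that("degenerate series are excluded with a reason", {
  f <- fitPixelLinearized(rep(12, 15), te15, bias = 12)
  expect_false(f@accepted)
  expect_equal(f@reason, "insufficient points")
  # a rising series is well fit in the log domain but unphysical
  rising <- 100 * exp(te15 / 80)
  f2 <- fitPixelLinearized(rising, te15, bias = 0)
  expect_false(f2@accepted)
  expect_equal(f2@reason, "non-decaying")
  expect_true(is.na(f2@t2))
})

test_that("fit is invariant to a common intensity scale", {
  set.seed(8)
  series <- exactSeries(800, 60, 15) + rnorm(15, 0, 5)
  series <- pmax(series, 0.1)
  f1 <- fitPixelLinearized(series, te15, bias = 10)
  f2 <- fitPixelLinearized(series * 3.7, te15, bias = 37)
  expect_equal(f1@t2, f2@t2, tolerance = 1e-12)
  expect_equal(f1@rsq, f2@rsq, tolerance = 1e-12)
  expect_equal(f2@amplitude / f1@amplitude, 3.7, tolerance = 1e-12)
})

test_that("mean absolute T2 error degrades monotonically with noise", {
  ph <- phantomSpec()
  errs <- vapply(c(2, 10, 25, 40), function(sigma) {
    sim <- simulateEchoStack(ph, echoProtocol(),
                             noiseSpec(sigma = sigma, seed = 100))
    myo <- sim$classMask == "myocardium"
    map <- computeT2Map(sim$stack, mask = myo,
                        bias = sigma * sqrt(pi / 2))
    mean(abs(t2Values(map)[acceptedMask(map)] - 60))
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("constant-bias fit carries its characterized noise-floor bias", {
  # Subtracting the full zero-signal Rician floor over-corrects pixels
  # with signal, so the log-linear fit underestimates T2 by an amount
  # that grows with sigma. Expected medians below were computed with an
  # independent per-series lm() simulation at the same seed.
  charBias <- function(sigma) {
    set.seed(31)
    t2hat <- replicate(800, {
      series <- bruteRician(15, exactSeries(800, 60, 0), sigma)
      fitPixelLinearized(series, te15, bias = sigma * sqrt(pi / 2))@t2
    })
    median(t2hat, na.rm = TRUE) - 60
  }
  expect_equal(charBias(10), -4.2777, tolerance = 1e-3)
  expect_equal(charBias(40), -13.595, tolerance = 1e-3)
  # at first-echo SNR ~80 the bias stays under 8% of the true T2
  expect_lt(abs(charBias(10)), 0.08 * 60)
})

test_that("bias estimator reproduces constant and Rician backgrounds", {
  arr <- array(12, c(16, 16, 15))
  expect_equal(estimateBias(EchoStack(arr, te15)), 12)
  expect_equal(estimateBias(EchoStack(array(0, c(16, 16, 15)), te15)), 0)
  # Rician sigma = 10 over >= 1e4 samples: within 1% of sigma*sqrt(pi/2)
  set.seed(12)
  bgArr <- array(bruteRician(40 * 40 * 15, 0, 10), c(40, 40, 15))
  b <- estimateBias(EchoStack(bgArr, te15),
                    background = matrix(TRUE, 40, 40))
  expect_lt(abs(b - 10 * sqrt(pi / 2)) / (10 * sqrt(pi / 2)), 0.01)
})

test_that("bias estimator flags bad background regions", {
  stack <- EchoStack(array(5, c(16, 16, 15)), te15)
  expect_error(estimateBias(stack, background = matrix(FALSE, 16, 16)),
               "empty")
  obj <- matrix(TRUE, 16, 16)
  expect_warning(estimateBias(stack, objectMask = obj), "overlaps")
  expect_error(estimateBias(stack, background = matrix(TRUE, 4, 4)),
               "matching")
})

test_that("T2 map bookkeeping partitions evaluated pixels", {
  sim <- simulateEchoStack(noise = noiseSpec(sigma = 15, seed = 9))
  mask <- sim$classMask != "background"
  map <- computeT2Map(sim$stack, mask = mask)
  st <- acceptanceStats(map)
  expect_equal(st$nAccepted + st$nExcluded, sum(mask))
  expect_equal(st$nEvaluated, sum(mask))
  expect_error(computeT2Map(sim$stack, mask = matrix(TRUE, 2, 2)),
               "mask")
})

test_that("uniform noise-free phantom maps to its true T2 everywhere", {
  sim <- simulateEchoStack(phantomSpec(myocardialT2 = 60),
                           noise = noiseSpec(sigma = 0))
  myo <- sim$classMask == "myocardium"
  map <- computeT2Map(sim$stack, mask = myo, bias = 0)
  expect_equal(acceptanceStats(map)$nExcluded, 0)
  expect_equal(unname(t2Values(map)[myo]), rep(60, sum(myo)),
               tolerance = 1e-9)
})

test_that("noise-only pixels rarely pass the R^2 filter", {
  # subsample of the brute-force null check in the acceptance suite
  set.seed(14)
  n <- 2000
  Y <- matrix(bruteRician(n * 15, 0, 10), n, 15)
  stack <- EchoStack(array(Y, c(n, 1, 15)), te15)
  map <- computeT2Map(stack, bias = 10 * sqrt(pi / 2))
  expect_lt(acceptanceStats(map)$nAccepted / n, 0.05)
})

test_that("spectral rendering honours the range, clamp and sentinel", {
  img <- renderT2Map(matrix(c(0, 150, 200, NA), 2, 2), range = c(0, 150))
  expect_equal(img[1, 1, ], c(0, 0, 0))        # 0 ms -> black
  expect_equal(img[2, 1, ], c(1, 0, 0))        # 150 ms -> red
  expect_equal(img[1, 2, ], img[2, 1, ])       # 200 ms clamps to 150
  sentinel <- img[2, 2, ]
  lut <- attr(img, "lut")
  expect_false(grDevices::rgb(sentinel[1], sentinel[2], sentinel[3]) %in%
                 lut)
  expect_error(renderT2Map(matrix(1), range = c(150, 0)), "range")
})
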