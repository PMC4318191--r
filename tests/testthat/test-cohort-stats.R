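test_that("observer agreement handles identity and constant offsets", {
  a <- c(55, 58, 61, 57, 60)
  idt <- observerAgreement(a, a)
  expect_equal(idt$meanDifference, 0)
  expect_equal(idt$sdDifference, 0)
  expect_equal(idt$cov, 0)
  expect_equal(idt$pearsonR, 1)
  expect_equal(unname(idt$limits), c(0, 0))
  off <- observerAgreement(a, a + 1)
  expect_equal(off$meanDifference, -1)
  expect_equal(off$sdDifference, 0)
  expect_equal(off$cov, 0)
})

test_that("Bland-Altman limits are mean difference +/- 1.96 SD", {
  # differences constructed to have mean 0.004 and SD 1.68 exactly
  d <- c(0.004 - 1.68, 0.004, 0.004 + 1.68)
  a <- c(55, 58, 61)
  res <- observerAgreement(a, a - d)
  expect_equal(res$meanDifference, 0.004, tolerance = 1e-12)
  expect_equal(res$sdDifference, 1.68, tolerance = 1e-12)
  expect_equal(unname(res$limits),
               c(0.004 - 1.96 * 1.68, 0.004 + 1.96 * 1.68),
               tolerance = 1e-12)
  expect_equal(round(unname(res$limits), 3), c(-3.289, 3.297))
})

test_that("agreement is symmetric up to the sign of the mean difference", {
  set.seed(61)
  a <- rnorm(30, 58, 4); b <- a + rnorm(30, 0.3, 1.5)
  ab <- observerAgreement(a, b)
  ba <- observerAgreement(b, a)
  expect_equal(ab$cov, ba$cov)
  expect_equal(ab$sdDifference, ba$sdDifference)
  expect_equal(ab$meanDifference, -ba$meanDifference)
  expect_equal(ab$pearsonR, ba$pearsonR)
  expect_error(observerAgreement(a, b[-1]), "aligned")
  expect_error(observerAgreement(c(1, NA, 3), c(1, 2, 3)), "missing")
})

test_that("Pearson regression recovers exact lines and flags degeneracy", {
  reg <- pearsonRegression(1:10, 2 * (1:10) + 1)
  expect_equal(reg$r, 1)
  expect_equal(reg$slope, 2)
  expect_equal(reg$intercept, 1)
  expect_error(pearsonRegression(rep(3, 5), 1:5), "degenerate")
  # brute-force covariance formula on a 5-point table
  x <- c(24, 31, 45, 58, 72); y <- c(54.2, 55.1, 57.9, 58.4, 61.0)
  reg2 <- pearsonRegression(x, y)
  expect_equal(reg2$r, brutePearson(x, y), tolerance = 1e-12)
  expect_equal(reg2$pValue,
               2 * pt(abs(reg2$r) * sqrt(3 / (1 - reg2$r^2)), 3,
                      lower.tail = FALSE), tolerance = 1e-12)
})

test_that("null regressions at n = 69 rarely show |r| > 0.3", {
  hits <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    r <- pearsonRegression(rnorm(69), rnorm(69))$r
    if (abs(r) < 0.3) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("Pearson r is invariant under positive affine rescaling", {
  set.seed(67)
  x <- rnorm(25); y <- 0.5 * x + rnorm(25)
  r0 <- pearsonRegression(x, y)$r
  expect_equal(pearsonRegression(3 * x + 10, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearsonRegression(x, 0.2 * y - 4)$r, r0, tolerance = 1e-12)
})

test_that("Student's t-test matches hand computation and conventions", {
  a <- c(60, 62, 58, 61, 59); b <- c(55, 57, 54, 56, 58)
  res <- groupTTest(a, b)
  expect_equal(res$t, bruteStudentT(a, b), tolerance = 1e-12)
  expect_equal(res$pValue, 2 * pt(abs(res$t), 8, lower.tail = FALSE),
               tolerance = 1e-12)
  idt <- groupTTest(a, a, paired = TRUE)
  expect_equal(idt$t, 0)
  expect_equal(idt$pValue, 1)
  expect_match(idt$flag, "degenerate")
  expect_error(groupTTest(a, 1), "n >= 2")
  expect_error(groupTTest(a, b[-1], paired = TRUE), "equal lengths")
})

test_that("the t-test has power > 90% for a 4 ms shift at n = 20", {
  set.seed(71)
  reject <- vapply(1:1000, function(i) {
    groupTTest(rnorm(20, 60, 3.5), rnorm(20, 56, 3.5))$pValue < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.9)
})

test_that("water fraction and its normalization follow the weighing rule", {
  wf <- waterFraction(20, 20 * (1 - 0.63))
  expect_equal(wf$waterFraction, 0.63)
  expect_equal(wf$percentOfFull, 100)
  expect_equal(waterFraction(20, 10)$waterFraction, 0.5)
  expect_equal(waterFraction(20, 20)$waterFraction, 0)
  expect_equal(waterFraction(20, 20)$percentOfFull, 0)
  expect_error(waterFraction(10, 12), "exceeds")
  expect_error(waterFraction(10, -1), "negative")
  # round trip against the drying generator, row by row
  d <- simulateDryingSeries(dryingSpec())
  wf2 <- waterFraction(d$wetWeight, d$dryWeight)
  expect_equal(wf2$waterFraction, d$waterFraction, tolerance = 1e-12)
  expect_equal(wf2$percentOfFull, d$percentOfFull, tolerance = 1e-12)
})

test_that("cohort report reproduces a zero-noise additive cohort exactly", {
  co <- simulateCohort(cohortSpec(nSubjects = 24, betweenSubjectSd = 0,
                                  seed = 5))
  sliceT2 <- do.call(rbind, lapply(c("apical", "mid", "basal"),
    function(sl) {
      v <- switch(sl, apical = co$trueT2Apical, mid = co$trueT2Mid,
                  basal = co$trueT2Basal)
      data.frame(subject = co$subject, age = co$age, sex = co$sex,
                 heartRate = co$heartRate, ageGroup = co$ageGroup,
                 slice = sl, meanT2 = v, medianT2 = v)
    }))
  rep <- cohortReport(sliceT2, statistic = "median")
  expect_equal(nrow(rep$table),
               length(unique(co$sex)) * length(unique(co$ageGroup)) * 3)
  # slice offsets (4, 2, 0): apical mean - basal mean = 4 in every stratum
  for (sx in unique(co$sex)) for (ag in unique(co$ageGroup)) {
    sel <- rep$table$sex == sx & rep$table$ageGroup == ag
    ap <- rep$table$meanT2[sel & rep$table$slice == "apical"]
    ba <- rep$table$meanT2[sel & rep$table$slice == "basal"]
    if (!is.na(ap) && !is.na(ba)) expect_equal(ap - ba, 4)
  }
  # paired apical-vs-basal is a constant 4 ms difference
  for (sx in names(rep$apicalVsBasal)) {
    tt <- rep$apicalVsBasal[[sx]]
    if (!is.null(tt$pValue)) expect_match(tt$flag, "degenerate|ok")
  }
  gen <- attr(co, "spec")
  expect_true(abs(rep$ageRegression$slope - gen$ageSlope) < 0.06)
})

test_that("cohort report flags empty cells instead of dropping them", {
  co <- simulateCohort(cohortSpec(nSubjects = 8, sexRatio = 0,
                                  seed = 9))  # all male
  sliceT2 <- data.frame(subject = co$subject, age = co$age, sex = co$sex,
                        heartRate = co$heartRate, ageGroup = co$ageGroup,
                        slice = "mid", meanT2 = co$trueT2Mid,
                        medianT2 = co$trueT2Mid)
  rep <- cohortReport(sliceT2)
  expect_true(any(rep$table$flag == "insufficient cell"))
  expect_true(all(c("apical", "mid", "basal") %in% rep$table$slice))
})
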