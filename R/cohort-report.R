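#' Cohort report: strata tables, group tests, regressions
#'
#' Reproduces the volunteer-analysis layer on a table of per-subject,
#' per-slice T2 summaries: mean +/- SD (and median) per
#' sex x age-group x slice cell, the apical-vs-basal paired t-test within
#' each sex, the male-vs-female unpaired t-test within each slice, and
#' Pearson regressions of global T2 on age and on heart rate. Empty or
#' single-subject cells are flagged, never silently dropped.
#'
#' @param sliceT2 data frame with one row per subject x slice:
#'   columns `subject`, `age`, `sex` (`"F"`/`"M"`), `heartRate`,
#'   `ageGroup`, `slice` (`"apical"`/`"mid"`/`"basal"`), and the T2
#'   summary columns `meanT2` and `medianT2` (ms).
#' @param statistic which summary feeds the tests and tables:
#'   `"median"` (as used for the slice-level reference values) or
#'   `"mean"` (as used for the age regression).
#' @return A list of class `cohortReport`:
#'   \describe{
#'     \item{table}{per sex x age-group x slice `n`, `meanT2`, `sdT2`,
#'       `medianT2`, `flag`;}
#'     \item{apicalVsBasal}{paired t-test per sex;}
#'     \item{maleVsFemale}{unpaired t-test per slice;}
#'     \item{ageRegression, hrRegression}{Pearson regressions of global
#'       (slice-averaged) T2 on age / heart rate;}
#'     \item{statistic}{the summary used.}
#'   }
#' @export
cohortReport <- function(sliceT2, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  need <- c("subject", "age", "sex", "heartRate", "ageGroup", "slice",
            "meanT2", "medianT2")
  if (!all(need %in% names(sliceT2)))
    stop("sliceT2 is missing columns: ",
         paste(setdiff(need, names(sliceT2)), collapse = ", "))
  val <- if (statistic == "median") sliceT2$medianT2 else sliceT2$meanT2

  cells <- expand.grid(sex = sort(unique(sliceT2$sex)),
                       ageGroup = sort(unique(sliceT2$ageGroup)),
                       slice = c("apical", "mid", "basal"),
                       stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- sliceT2$sex == cells$sex[i] &
      sliceT2$ageGroup == cells$ageGroup[i] &
      sliceT2$slice == cells$slice[i]
    v <- val[sel]
    data.frame(cells[i, ], n = length(v),
               meanT2 = if (length(v)) mean(v) else NA_real_,
               sdT2 = if (length(v) > 1) stats::sd(v) else NA_real_,
               medianT2 = if (length(v)) stats::median(v) else NA_real_,
               flag = if (length(v) < 2) "insufficient cell" else "ok",
               row.names = NULL)
  }))

  bySex <- lapply(split(sliceT2, sliceT2$sex), function(d) {
    wide <- merge(d[d$slice == "apical", c("subject", "meanT2", "medianT2")],
                  d[d$slice == "basal", c("subject", "meanT2", "medianT2")],
                  by = "subject", suffixes = c(".apical", ".basal"))
    col <- paste0(if (statistic == "median") "medianT2" else "meanT2")
    if (nrow(wide) < 2) return(list(flag = "insufficient cell"))
    groupTTest(wide[[paste0(col, ".apical")]],
               wide[[paste0(col, ".basal")]], paired = TRUE)
  })

  bySlice <- lapply(split(seq_len(nrow(sliceT2)), sliceT2$slice),
                    function(i) {
    m <- val[i][sliceT2$sex[i] == "M"]
    f <- val[i][sliceT2$sex[i] == "F"]
    if (length(m) < 2 || length(f) < 2)
      return(list(flag = "insufficient cell"))
    groupTTest(f, m, paired = FALSE)
  })

  glob <- stats::aggregate(cbind(t2 = val),
                           by = list(subject = sliceT2$subject), FUN = mean)
  meta <- sliceT2[!duplicated(sliceT2$subject),
                  c("subject", "age", "heartRate")]
  glob <- merge(glob, meta, by = "subject")
  ageReg <- if (nrow(glob) >= 3) pearsonRegression(glob$age, glob$t2)
            else list(flag = "insufficient subjects")
  hrReg <- if (nrow(glob) >= 3) pearsonRegression(glob$heartRate, glob$t2)
           else list(flag = "insufficient subjects")

  structure(list(table = tab, apicalVsBasal = bySex,
                 maleVsFemale = bySlice, ageRegression = ageReg,
                 hrRegression = hrReg, statistic = statistic,
                 global = glob),
            class = "cohortReport")
}

#' Write a cohort report to CSV and a text summary
#'
#' @param report a [cohortReport()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCohortReport <- function(report, dir) {
  stopifnot(inherits(report, "cohortReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tablePath <- file.path(dir, "cohort_strata.csv")
  utils::write.csv(report$table, tablePath, row.names = FALSE, na = "")
  globalPath <- file.path(dir, "cohort_global.csv")
  utils::write.csv(report$global, globalPath, row.names = FALSE, na = "")
  txt <- file.path(dir, "cohort_summary.txt")
  con <- file(txt, "w"); on.exit(close(con))
  fmt <- function(x) if (is.null(x$pValue)) x$flag else
    sprintf("t = %.3f, p = %.4g", x$t, x$pValue)
  writeLines(c(
    sprintf("cohort report (statistic: %s)", report$statistic),
    "apical vs basal (paired, per sex):",
    sprintf("  %s: %s", names(report$apicalVsBasal),
            vapply(report$apicalVsBasal, fmt, "")),
    "female vs male (unpaired, per slice):",
    sprintf("  %s: %s", names(report$maleVsFemale),
            vapply(report$maleVsFemale, fmt, "")),
    if (!is.null(report$ageRegression$r))
      sprintf("age regression: R = %.3f, slope = %.4f ms/y, p = %.4g",
              report$ageRegression$r, report$ageRegression$slope,
              report$ageRegression$pValue) else "age regression: n/a",
    if (!is.null(report$hrRegression$r))
      sprintf("heart-rate regression: R = %.3f, p = %.4g",
              report$hrRegression$r, report$hrRegression$pValue)
    else "heart-rate regression: n/a"), con)
  invisible(c(tablePath, globalPath, txt))
}
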