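#' Write a multi-echo stack as NIfTI plus a sidecar
#'
#' The stack is stored as a NIfTI volume with echoes along the third
#' axis; the echo times go into a JSON sidecar
#' `{"echo_times_ms": [...]}` next to the volume (same basename,
#' extension `.json`).
#'
#' @param stack an [EchoStack-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return Invisibly, `c(nifti = path, sidecar = sidecarPath)`.
#' @export
writeEchoStack <- function(stack, path) {
  stopifnot(is(stack, "EchoStack"))
  RNifti::writeNifti(stack@data, path)
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  jsonlite::write_json(list(echo_times_ms = stack@echoTimes), sidecar,
                       auto_unbox = FALSE, digits = NA)
  invisible(c(nifti = path, sidecar = sidecar))
}

#' Read a multi-echo stack from NIfTI plus sidecar
#'
#' @param path `.nii` / `.nii.gz` volume with echoes along the third
#'   axis; a sidecar `<basename>.json` listing `echo_times_ms` must sit
#'   next to it.
#' @return An [EchoStack-class].
#' @export
readEchoStack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar with echo times: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  te <- as.numeric(meta$echo_times_ms)
  if (!length(te)) stop("sidecar has no echo_times_ms entry")
  vol <- RNifti::readNifti(path)
  arr <- array(as.numeric(vol), dim(vol))
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume with echoes along the third axis")
  if (dim(arr)[3] != length(te))
    stop(sprintf("echo count mismatch: %d planes vs %d echo times",
                 dim(arr)[3], length(te)))
  if (any(diff(te) <= 0)) stop("echo times must be strictly increasing")
  EchoStack(arr, te)
}

#' Write slice contours to a structured-text file
#'
#' YAML with `endo` / `epi` vertex lists, `rv_insertion`, `slice_level`
#' and `slice_label`.
#'
#' @param geometry a [SliceGeometry-class].
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
writeContours <- function(geometry, path) {
  stopifnot(is(geometry, "SliceGeometry"))
  obj <- list(slice_label = geometry@sliceLabel,
              slice_level = geometry@sliceLevel,
              rv_insertion = as.numeric(geometry@rvInsertion),
              endo = list(x = geometry@endo[, 1], y = geometry@endo[, 2]),
              epi = list(x = geometry@epi[, 1], y = geometry@epi[, 2]))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read slice contours from a structured-text file
#'
#' @param path `.yaml` file written by [writeContours()] (or drawn by
#'   hand to the same schema).
#' @return A validated [SliceGeometry-class]; malformed or non-nested
#'   contours are rejected with a descriptive error.
#' @export
readContours <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- yaml::read_yaml(path)
  need <- c("slice_level", "rv_insertion", "endo", "epi")
  if (!all(need %in% names(obj)))
    stop("contour file is missing fields: ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  poly <- function(p, what) {
    if (is.null(p$x) || is.null(p$y) || length(p$x) != length(p$y))
      stop("malformed ", what, " polygon")
    cbind(as.numeric(p$x), as.numeric(p$y))
  }
  sliceGeometry(endo = poly(obj$endo, "endo"), epi = poly(obj$epi, "epi"),
                rvInsertion = as.numeric(obj$rv_insertion),
                sliceLevel = obj$slice_level,
                sliceLabel = obj$slice_label %||% "slice")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
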