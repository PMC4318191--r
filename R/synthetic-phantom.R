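#' Specification of a synthetic annular myocardium phantom
#'
#' Describes a short-axis slice as three hard tissue classes on a pixel
#' grid: an annular myocardium between two concentric circles, blood pool
#' inside the endocardial circle, and background outside the epicardial
#' one. The noiseless signal of a tissue pixel follows the monoexponential
#' decay `S(TE) = h * exp(-TE / T2)`; background pixels carry a constant
#' `backgroundLevel` (default 0, so their magnitude is pure noise floor).
#'
#' `myocardialT2` may be a single value or a vector of per-angular-sector
#' values; sectors are equal angular bins starting at the RV-insertion ray
#' and sweeping clockwise, which lets a known segmental contrast (for
#' example an anteroseptal elevation) be injected as ground truth.
#'
#' @param gridSize integer length-2, grid rows and columns (pixels).
#' @param endoRadius,epiRadius endo-/epicardial radii in pixels;
#'   `epiRadius > endoRadius > 0` and the annulus must fit in the grid.
#' @param center `(x, y)` of the annulus center in pixel coordinates.
#' @param rvInsertionAngle angle (degrees, image convention: 0 = +x,
#'   increasing clockwise on screen) at which the posterior RV insertion
#'   landmark sits on the epicardium.
#' @param myocardialT2 myocardial T2 in ms, scalar or per-sector vector.
#' @param myocardialAmplitude fit amplitude h of myocardium (signal units).
#' @param bloodT2 blood-pool T2 in ms.
#' @param bloodAmplitude blood-pool amplitude (signal units).
#' @param backgroundLevel constant noiseless background intensity.
#' @param sliceLevel `"apical"`, `"mid"` or `"basal"`.
#' @return A validated `phantomSpec` list.
#' @examples
#' ph <- phantomSpec(myocardialT2 = 60)
#' @export
phantomSpec <- function(gridSize = c(64, 64), endoRadius = 10,
                        epiRadius = 16, center = NULL,
                        rvInsertionAngle = 210, myocardialT2 = 60,
                        myocardialAmplitude = 800, bloodT2 = 200,
                        bloodAmplitude = 900, backgroundLevel = 0,
                        sliceLevel = "mid") {
  gridSize <- as.integer(gridSize)
  if (length(gridSize) != 2L || any(gridSize < 4L))
    stop("gridSize must be two integers >= 4")
  if (is.null(center)) center <- (rev(gridSize) + 1) / 2
  .checkScalar(endoRadius, "endoRadius", lower = 0, strict = TRUE)
  .checkScalar(epiRadius, "epiRadius", lower = endoRadius, strict = TRUE)
  if (!all(is.finite(myocardialT2)) || any(myocardialT2 <= 0))
    stop("myocardialT2 must be positive")
  .checkScalar(bloodT2, "bloodT2", lower = 0, strict = TRUE)
  .checkScalar(myocardialAmplitude, "myocardialAmplitude", lower = 0)
  .checkScalar(backgroundLevel, "backgroundLevel", lower = 0)
  if (!sliceLevel %in% c("apical", "mid", "basal"))
    stop("sliceLevel must be 'apical', 'mid' or 'basal'")
  # cols are x, rows are y
  if (center[1] - epiRadius < 1 || center[1] + epiRadius > gridSize[2] ||
      center[2] - epiRadius < 1 || center[2] + epiRadius > gridSize[1])
    stop("geometry error: annulus exceeds the pixel grid")
  structure(list(gridSize = gridSize, endoRadius = endoRadius,
                 epiRadius = epiRadius, center = as.numeric(center),
                 rvInsertionAngle = rvInsertionAngle,
                 myocardialT2 = as.numeric(myocardialT2),
                 myocardialAmplitude = myocardialAmplitude,
                 bloodT2 = bloodT2, bloodAmplitude = bloodAmplitude,
                 backgroundLevel = backgroundLevel,
                 sliceLevel = sliceLevel),
            class = "phantomSpec")
}

#' Echo-train protocol
#'
#' @param nEchoes number of echo images (>= 3); default 15.
#' @param echoSpacing inter-echo spacing in ms; default 10, giving a
#'   150 ms echo train that covers the full myocardial decay.
#' @param firstEcho first echo time in ms; default equals `echoSpacing`.
#' @return An `echoProtocol` list with an `echoTimes` vector.
#' @export
echoProtocol <- function(nEchoes = 15, echoSpacing = 10,
                         firstEcho = echoSpacing) {
  nEchoes <- as.integer(nEchoes)
  if (nEchoes < 3L) stop("nEchoes must be >= 3")
  .checkScalar(echoSpacing, "echoSpacing", lower = 0, strict = TRUE)
  .checkScalar(firstEcho, "firstEcho", lower = 0, strict = TRUE)
  structure(list(nEchoes = nEchoes, echoSpacing = echoSpacing,
                 firstEcho = firstEcho,
                 echoTimes = firstEcho + echoSpacing * (seq_len(nEchoes) - 1)),
            class = "echoProtocol")
}

#' Magnitude-noise specification
#'
#' Noise is Rician: the recorded magnitude is
#' `|S + n_re + i n_im|` with independent Gaussian channels of SD `sigma`.
#' This is what creates the constant noise floor (`y0`) in magnitude MR
#' images: background magnitude has mean `sigma * sqrt(pi / 2)` rather
#' than zero.
#'
#' @param sigma per-channel Gaussian SD (signal units), `>= 0`.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return A `noiseSpec` list.
#' @export
noiseSpec <- function(sigma = 10, seed = NULL) {
  .checkScalar(sigma, "sigma", lower = 0)
  structure(list(sigma = sigma, seed = seed), class = "noiseSpec")
}

# Tissue-class mask and per-pixel true T2 / amplitude grids of a phantom.
.phantomTruth <- function(phantom) {
  nr <- phantom$gridSize[1]; nc <- phantom$gridSize[2]
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)   # column index
  y <- matrix(rep(seq_len(nr), times = nc), nr, nc)  # row index
  dx <- x - phantom$center[1]; dy <- y - phantom$center[2]
  r <- sqrt(dx^2 + dy^2)
  cls <- matrix("background", nr, nc)
  cls[r < phantom$endoRadius] <- "blood"
  cls[r >= phantom$endoRadius & r < phantom$epiRadius] <- "myocardium"

  t2 <- matrix(NA_real_, nr, nc)
  h <- matrix(0, nr, nc)
  myo <- cls == "myocardium"
  t2vals <- phantom$myocardialT2
  if (length(t2vals) == 1L) {
    t2[myo] <- t2vals
  } else {
    anchor <- phantom$rvInsertionAngle * pi / 180
    ang <- .angleFrom(.imageAngle(dx[myo], dy[myo]), anchor)
    sector <- pmin(floor(ang / (2 * pi / length(t2vals))) + 1,
                   length(t2vals))
    t2[myo] <- t2vals[sector]
  }
  h[myo] <- phantom$myocardialAmplitude
  blood <- cls == "blood"
  t2[blood] <- phantom$bloodT2
  h[blood] <- phantom$bloodAmplitude
  list(class = cls, t2 = t2, amplitude = h)
}

#' Slice geometry of a phantom
#'
#' Renders the phantom's endo- and epicardial circles as closed polygons
#' and places the RV-insertion landmark on the epicardium at the
#' configured angle.
#'
#' @param phantom a [phantomSpec()].
#' @param nVertices polygon resolution per contour.
#' @return A [SliceGeometry-class].
#' @export
phantomGeometry <- function(phantom, nVertices = 128) {
  th <- seq(0, 2 * pi, length.out = nVertices + 1)[-(nVertices + 1)]
  circ <- function(r) cbind(phantom$center[1] + r * cos(th),
                            phantom$center[2] + r * sin(th))
  a <- phantom$rvInsertionAngle * pi / 180
  rv <- phantom$center + phantom$epiRadius * c(cos(a), sin(a))
  sliceGeometry(endo = circ(phantom$endoRadius),
                epi = circ(phantom$epiRadius),
                rvInsertion = rv, sliceLevel = phantom$sliceLevel,
                sliceLabel = sprintf("phantom-%s", phantom$sliceLevel))
}

#' Simulate a multi-echo stack from a phantom
#'
#' Renders the noiseless per-pixel decay `h * exp(-TE / T2)` (constant
#' `backgroundLevel` outside the heart) at each echo time and corrupts it
#' with Rician magnitude noise. Ground truth is returned alongside so
#' downstream estimates can be scored exactly.
#'
#' @param phantom a [phantomSpec()].
#' @param protocol an [echoProtocol()].
#' @param noise a [noiseSpec()].
#' @return A list with
#'   \describe{
#'     \item{stack}{the simulated [EchoStack-class];}
#'     \item{trueT2}{matrix of generating T2 (ms), `NA` in background;}
#'     \item{trueAmplitude}{matrix of generating amplitudes h;}
#'     \item{classMask}{character matrix, `"myocardium"` / `"blood"` /
#'       `"background"`;}
#'     \item{geometry}{the matching [SliceGeometry-class];}
#'     \item{phantom, protocol, noise}{the input specifications.}
#'   }
#' @examples
#' sim <- simulateEchoStack(phantomSpec(), echoProtocol(),
#'                          noiseSpec(sigma = 0))
#' range(t2 <- sim$trueT2[sim$classMask == "myocardium"])
#' @export
simulateEchoStack <- function(phantom = phantomSpec(),
                              protocol = echoProtocol(),
                              noise = noiseSpec()) {
  stopifnot(inherits(phantom, "phantomSpec"),
            inherits(protocol, "echoProtocol"),
            inherits(noise, "noiseSpec"))
  truth <- .phantomTruth(phantom)
  nr <- phantom$gridSize[1]; nc <- phantom$gridSize[2]
  te <- protocol$echoTimes
  decay <- matrix(0, nr * nc, length(te))
  tissue <- !is.na(truth$t2)
  hv <- truth$amplitude[tissue]; t2v <- truth$t2[tissue]
  for (k in seq_along(te))
    decay[tissue, k] <- hv * exp(-te[k] / t2v)
  decay[!tissue, ] <- phantom$backgroundLevel

  data <- .withSeed(noise$seed, {
    out <- if (noise$sigma > 0) {
      matrix(.ricianize(as.vector(decay), noise$sigma), nrow = nr * nc)
    } else decay
    out
  })
  stack <- EchoStack(array(data, c(nr, nc, length(te))), te)
  list(stack = stack, trueT2 = truth$t2,
       trueAmplitude = truth$amplitude, classMask = truth$class,
       geometry = phantomGeometry(phantom), phantom = phantom,
       protocol = protocol, noise = noise)
}
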