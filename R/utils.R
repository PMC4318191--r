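# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL means "use the current stream" (callers that orchestrate many
# draws set one seed up front instead).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Even-odd point-in-polygon test at query points (px, py); vectorized over
# points. A point on an edge counts by the half-open crossing rule, which is
# what decides pixel-center membership deterministically.
.pointInPolygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ye[i] > py))
    if (any(crosses)) {
      xint <- xs[i] + (py[crosses] - ys[i]) / (ye[i] - ys[i]) *
        (xe[i] - xs[i])
      idx <- which(crosses)[px[crosses] < xint]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

# Angle of (dx, dy) measured clockwise in displayed image coordinates
# (x right, y down): atan2(dy, dx) increases clockwise on screen.
.imageAngle <- function(dx, dy) atan2(dy, dx)

# Clockwise angular offset from `anchor` in [0, 2*pi).
.angleFrom <- function(angle, anchor, direction = "clockwise") {
  d <- angle - anchor
  if (direction == "counterclockwise") d <- -d
  d %% (2 * pi)
}

# Draw |n| values from the magnitude of a complex Gaussian with per-channel
# SD sigma around a real-valued noiseless signal: Rician magnitude noise.
.ricianize <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

.checkFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

.checkScalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    stop(sprintf("'%s' = %g is outside its valid range", name, x),
         call. = FALSE)
  invisible(x)
}
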