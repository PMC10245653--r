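#' @keywords internal
"_PACKAGE"

# ---- internal helpers -------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_finite <- function(x, what = deparse(substitute(x))) {
  stop_if(!all(is.finite(x)), sprintf("`%s` contains non-finite values", what))
  invisible(x)
}

#' Modified Akima (makima) piecewise-cubic interpolation
#'
#' One-dimensional shape-preserving interpolation using Akima-style slope
#' weighting with the modified weights `w = |d2 - d1| + |d2 + d1|/2`, which
#' damps the overshoot of classic Akima interpolation on flat regions.
#' Outside `range(x)` the first/last value is held constant (flat
#' extrapolation), which is the behaviour wanted when anchoring a slowly
#' varying baseline at window centers.
#'
#' @param x strictly increasing knot locations.
#' @param y values at the knots.
#' @param xi locations at which to evaluate the interpolant.
#' @return numeric vector of interpolated values, `length(xi)`.
#' @export
#' @examples
#' x <- 0:7; y <- c(0, 0, 1, 1, 0, 2, 2, 0)
#' interp_makima(x, y, seq(0, 7, by = 0.25))
interp_makima <- function(x, y, xi) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2, !is.unsorted(x, strictly = TRUE))
  if (n == 2) { # linear segment, flat beyond the ends
    yi <- approx(x, y, pmin(pmax(xi, x[1]), x[2]))$y
    return(yi)
  }
  h <- diff(x)
  delta <- diff(y) / h
  # Akima end extension of segment slopes: two phantom slopes on each side,
  # layout delta_{-1}, delta_0, delta_1..delta_{n-1}, delta_n, delta_{n+1}
  m <- length(delta)
  d_ext <- c(3 * delta[1] - 2 * delta[2],
             2 * delta[1] - delta[2],
             delta,
             2 * delta[m] - delta[m - 1],
             3 * delta[m] - 2 * delta[m - 1])
  t_slope <- numeric(n)
  for (i in seq_len(n)) {
    dm2 <- d_ext[i]       # delta_{i-2}
    dm1 <- d_ext[i + 1]   # delta_{i-1}
    dp0 <- d_ext[i + 2]   # delta_i
    dp1 <- d_ext[i + 3]   # delta_{i+1}
    w1 <- abs(dp1 - dp0) + abs(dp1 + dp0) / 2
    w2 <- abs(dm1 - dm2) + abs(dm1 + dm2) / 2
    t_slope[i] <- if (w1 + w2 == 0) 0 else (w1 * dm1 + w2 * dp0) / (w1 + w2)
  }
  xc <- pmin(pmax(xi, x[1]), x[n])
  idx <- findInterval(xc, x, rightmost.closed = TRUE)
  idx[idx >= n] <- n - 1L
  s <- (xc - x[idx]) / h[idx]
  y0 <- y[idx]; y1 <- y[idx + 1L]
  m0 <- t_slope[idx] * h[idx]; m1 <- t_slope[idx + 1L] * h[idx]
  # cubic Hermite basis
  s2 <- s * s; s3 <- s2 * s
  (2 * s3 - 3 * s2 + 1) * y0 + (s3 - 2 * s2 + s) * m0 +
    (-2 * s3 + 3 * s2) * y1 + (s3 - s2) * m1
}

# Convert a logical frame-wise predicate into maximal TRUE runs.
# Returns data.frame(start, end) of 1-based inclusive frame indices.
runs_true <- function(flag) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

# Fill NA gaps in a numeric vector by linear interpolation, erroring when a
# gap exceeds max_gap consecutive frames or touches the ends.
fill_gaps <- function(x, max_gap = 5L, what = "keypoints") {
  if (!anyNA(x)) return(x)
  r <- rle(is.na(x))
  stop_if(any(r$values & r$lengths > max_gap),
          sprintf("%s contain a gap of > %d frames", what, max_gap))
  stop_if(is.na(x[1]) || is.na(x[length(x)]),
          sprintf("%s start or end with missing values", what))
  idx <- which(!is.na(x))
  approx(idx, x[idx], xout = seq_along(x))$y
}

# Restore the global RNG state on exit; use a locally derived stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
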