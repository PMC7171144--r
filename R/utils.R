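# Shared geometry and numeric helpers.
#
# Coordinate convention used across the package: x increases rightward,
# y increases downward, origin at the field-of-view top-left corner, units
# nm.  Pixel (row i, col j) (0-based in files, 1-based inside R) covers the
# half-open square [ (j-1)*p, j*p ) x [ (i-1)*p, i*p ) so the centre of the
# 1-based pixel (i, j) is at ((j - 0.5)*p, (i - 0.5)*p).

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so library code never perturbs
#' the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic fan-out of a global seed to per-stage seeds, kept within
# 32-bit integer range.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stage) * 7919L
}

#' Polygon area by the shoelace formula
#' @param poly Two-column matrix of vertices (x, y) in nm, not closed.
#' @return Signed-area magnitude in nm^2.
#' @keywords internal
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Vectorized even-odd (ray casting) point-in-polygon test.  Points exactly
# on an edge may land on either side; irrelevant at the densities used here.
points_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Uniform rejection sampling of n points inside a polygon (consumes RNG).
runif_in_polygon <- function(n, poly) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(NA_real_, n, 2L)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    x <- runif(m, xr[1], xr[2]); y <- runif(m, yr[1], yr[2])
    ok <- points_in_polygon(x, y, poly)
    take <- min(sum(ok), n - got)
    if (take > 0L) {
      idx <- which(ok)[seq_len(take)]
      out[got + seq_len(take), ] <- cbind(x[idx], y[idx])
      got <- got + take
    }
  }
  out
}

#' Regular polygon approximating a circle
#'
#' Convenience constructor for nuclear boundaries.
#'
#' @param center `c(x, y)` centre in nm.
#' @param radius Radius in nm.
#' @param n Number of vertices.
#' @return An `n` x 2 vertex matrix.
#' @export
circle_polygon <- function(center, radius, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# 1D normalized Gaussian kernel, truncated at 4 sigma.
gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

#' Separable Gaussian smoothing with replicated edges
#'
#' The kernel is a normalized discrete Gaussian truncated at 4 sigma and
#' image borders are extended by edge replication, so constant images are
#' preserved exactly.
#'
#' @param img Numeric matrix.
#' @param sigma Kernel standard deviation in pixels.
#' @return Smoothed matrix of the same dimension.
#' @export
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  smooth_one_axis <- function(m) {
    # pad rows by replication, then accumulate kernel taps over row shifts
    n <- nrow(m)
    pad <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(k)) {
      out <- out + k[t] * pad[(t - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(smooth_one_axis(t(smooth_one_axis(img))))
}

# Separable 3D Gaussian smoothing (replicated edges) on an array
# [row, col, z]; sigma may be a scalar or per-axis (y, x, z).
gaussian_smooth_3d <- function(vol, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  d <- dim(vol)
  smooth_axis <- function(a, axis, s) {
    if (s <= 0) return(a)
    k <- gauss_kernel_1d(s)
    r <- (length(k) - 1L) / 2L
    n <- dim(a)[axis]
    idx_pad <- c(rep(1L, r), seq_len(n), rep(n, r))
    out <- array(0, dim(a))
    for (t in seq_along(k)) {
      sl <- idx_pad[(t - 1L) + seq_len(n)]
      out <- out + k[t] * switch(axis,
        a[sl, , , drop = FALSE],
        a[, sl, , drop = FALSE],
        a[, , sl, drop = FALSE])
    }
    out
  }
  vol <- smooth_axis(vol, 1L, sigma[1])
  vol <- smooth_axis(vol, 2L, sigma[2])
  smooth_axis(vol, 3L, sigma[3])
}

# Rasterize a polygon (nm) into a logical mask; pixel (i, j) is inside when
# its centre is inside the polygon.
rasterize_polygon <- function(poly, pixel_nm, dim_px, origin = c(0, 0)) {
  nx <- dim_px[2]; ny <- dim_px[1]
  xc <- origin[1] + (seq_len(nx) - 0.5) * pixel_nm
  yc <- origin[2] + (seq_len(ny) - 0.5) * pixel_nm
  g <- expand.grid(y = yc, x = xc)
  matrix(points_in_polygon(g$x, g$y, poly), ny, nx)
}

# Clamp helper.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
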