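# 3D structured-illumination volume analysis: background removal,
# semi-automated 3D nucleus segmentation by radial gradient search, DNA
# occupancy and per-focus heterochromatin intensity.

#' Construct a 3D volume
#'
#' @param data 3D array `[row, col, z]` of intensities.
#' @param voxel_nm Voxel dimensions `c(x, y, z)` in nm (> 0).
#' @return A `volume3d`.
#' @export
volume3d <- function(data, voxel_nm) {
  stopifnot(length(dim(data)) == 3L, all(voxel_nm > 0))
  structure(list(data = data, voxel_nm = voxel_nm,
                 background_level = NA_real_),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d: %dx%dx%d voxels of %gx%gx%g nm\n", d[1], d[2], d[3],
              x$voxel_nm[1], x$voxel_nm[2], x$voxel_nm[3]))
  invisible(x)
}

# Box median over a neighbourhood, evaluated on a coarse grid and
# trilinearly interpolated to the full grid.  Neighbourhood voxels are
# subsampled so each median uses at most ~4000 samples; adequate for the
# slowly varying autofluorescent background this estimates.
box_median_3d <- function(vol, r_vox, stride = NULL) {
  d <- dim(vol)
  r_vox <- pmin(pmax(r_vox, 1L), d)
  if (is.null(stride)) stride <- pmax(1L, r_vox %/% 2L)
  grid <- lapply(1:3, function(a) {
    unique(clamp(c(seq(1L, d[a], by = stride[a]), d[a]), 1L, d[a]))
  })
  sub <- lapply(1:3, function(a) max(1L, floor((2 * r_vox[a] + 1) / 16)))
  est <- array(0, vapply(grid, length, 0L))
  for (iz in seq_along(grid[[3]])) {
    zz <- seq(max(1L, grid[[3]][iz] - r_vox[3]),
              min(d[3], grid[[3]][iz] + r_vox[3]), by = sub[[3]])
    for (iy in seq_along(grid[[1]])) {
      yy <- seq(max(1L, grid[[1]][iy] - r_vox[1]),
                min(d[1], grid[[1]][iy] + r_vox[1]), by = sub[[1]])
      for (ix in seq_along(grid[[2]])) {
        xx <- seq(max(1L, grid[[2]][ix] - r_vox[2]),
                  min(d[2], grid[[2]][ix] + r_vox[2]), by = sub[[2]])
        est[iy, ix, iz] <- median(vol[yy, xx, zz])
      }
    }
  }
  # trilinear interpolation back to the full grid
  interp_axis <- function(a, n, knots) {
    i <- findInterval(seq_len(n), knots, rightmost.closed = TRUE)
    i <- clamp(i, 1L, length(knots) - 1L)
    w <- (seq_len(n) - knots[i]) / pmax(knots[i + 1L] - knots[i], 1L)
    list(lo = i, hi = i + 1L, w = w)
  }
  ay <- interp_axis(1, d[1], grid[[1]])
  ax <- interp_axis(2, d[2], grid[[2]])
  az <- interp_axis(3, d[3], grid[[3]])
  out <- array(0, d)
  for (z in seq_len(d[3])) {
    zl <- az$lo[z]; zh <- az$hi[z]; wz <- az$w[z]
    plane <- (1 - wz) * est[, , zl] + wz * est[, , zh]
    py <- (1 - ay$w) * plane[ay$lo, , drop = FALSE] +
      ay$w * plane[ay$hi, , drop = FALSE]
    out[, , z] <- t((1 - ax$w) * t(py[, ax$lo, drop = FALSE]) +
                    ax$w * t(py[, ax$hi, drop = FALSE]))
  }
  out
}

#' Remove the slowly varying 3D background of a volume
#'
#' Estimates the local autofluorescent background with a 3D median filter
#' of the given radius (default 5 um) and subtracts it, clipping at zero.
#' The mean of the estimated field is recorded as the volume's scalar
#' `background_level` for downstream thresholding.
#'
#' @param vol A [volume3d()].
#' @param radius_nm Median-filter radius in nm (default 5000).
#' @return The corrected `volume3d` with `background_level` and the
#'   estimated `background_field` attached.
#' @export
remove_background_3d <- function(vol, radius_nm = 5000) {
  r_vox <- floor(radius_nm / vol$voxel_nm[c(2, 1, 3)])  # (row, col, z)
  if (any(r_vox < 1L)) stop("median-filter radius smaller than one voxel")
  bg <- box_median_3d(vol$data, r_vox)
  out <- vol
  out$data <- pmax(vol$data - bg, 0)
  out$background_level <- mean(bg)
  out$background_field <- bg
  out
}

# Bilinear sample of one z-plane at fractional (row, col) positions.
sample_plane <- function(plane, ri, ci) {
  nr <- nrow(plane); nc <- ncol(plane)
  r0 <- clamp(floor(ri), 1, nr - 1); c0 <- clamp(floor(ci), 1, nc - 1)
  fr <- ri - r0; fc <- ci - c0
  (1 - fr) * (1 - fc) * plane[cbind(r0, c0)] +
    (1 - fr) * fc * plane[cbind(r0, c0 + 1)] +
    fr * (1 - fc) * plane[cbind(r0 + 1, c0)] +
    fr * fc * plane[cbind(r0 + 1, c0 + 1)]
}

# Border radius per ray on one plane: position of the maximum radial
# intensity-gradient magnitude, searched within [band] (voxel units).
plane_border <- function(plane, center, angles, band, step = 0.25) {
  n_r <- nrow(plane); n_c <- ncol(plane)
  radii <- numeric(length(angles))
  for (k in seq_along(angles)) {
    rmaxk <- band[k, 2]
    rr <- seq(max(band[k, 1], 1), rmaxk, by = step)
    if (length(rr) < 5L) rr <- seq(1, rmaxk, by = step)
    ci <- center[1] + rr * cos(angles[k])
    ri <- center[2] + rr * sin(angles[k])
    ok <- ri >= 1 & ri <= n_r - 1e-9 & ci >= 1 & ci <= n_c - 1e-9
    if (sum(ok) < 5L) { radii[k] <- NA_real_; next }
    v <- sample_plane(plane, ri[ok], ci[ok])
    gradmag <- abs(diff(v)) / step
    # threshold relative to the ray's intensity scale, so segmentation is
    # invariant to global intensity scaling
    if (max(gradmag) <= 1e-9 * max(abs(v), 1e-300)) {
      radii[k] <- NA_real_; next
    }
    radii[k] <- rr[ok][which.max(gradmag)] + step / 2
  }
  # fallback: interpolate rays with no detectable gradient from neighbours
  if (anyNA(radii)) {
    if (all(is.na(radii))) stop("no detectable gradient on any ray")
    idx <- seq_along(radii)
    good <- !is.na(radii)
    radii[!good] <- approx(c(idx[good] - length(radii), idx[good],
                             idx[good] + length(radii)),
                           rep(radii[good], 3L), xout = idx[!good])$y
  }
  radii
}

#' Segment a nucleus in a 3D volume from a manual seed
#'
#' From the seed the axial intensity profile is tracked to find the
#' maximum-intensity plane; there, rays are cast from the centre and the
#' nuclear border placed at the maximum-magnitude intensity gradient
#' along each ray.  The procedure repeats plane by plane above and below,
#' re-centring on each plane and restricting the gradient search to
#' 0.5-1.5x the previous plane's radius, until the plane's peak intensity
#' falls below `stop_frac` of the global axial peak.  A 1-voxel Gaussian
#' pre-smooth stabilises the gradient search.
#'
#' @param vol A [volume3d()] (background-corrected).
#' @param seed `c(col, row)` voxel position of a point inside the nucleus
#'   (any plane).
#' @param n_rays Number of radial rays.
#' @param stop_frac Axial stop criterion as a fraction of the peak.
#' @param presmooth_vox Gaussian pre-smoothing sd in voxels.
#' @return A `nucleus3d`: per-plane border polygons (voxel units), z
#'   range, voxel `mask`, `center`, and `volume_nm3`.
#' @export
segment_nucleus_3d <- function(vol, seed, n_rays = 360L, stop_frac = 0.2,
                               presmooth_vox = 1) {
  d <- dim(vol$data)
  seed <- as.numeric(seed)
  if (seed[1] < 1 || seed[1] > d[2] || seed[2] < 1 || seed[2] > d[1]) {
    stop("seed outside volume")
  }
  sm <- gaussian_smooth_3d(vol$data, presmooth_vox)
  # axial profile around the seed's lateral position
  rr <- clamp(round(seed[2]) + (-2:2), 1L, d[1])
  cc <- clamp(round(seed[1]) + (-2:2), 1L, d[2])
  profile <- vapply(seq_len(d[3]), function(z) mean(sm[rr, cc, z]), 0)
  z0 <- which.max(profile)
  peak <- profile[z0]
  if (peak <= max(mean(sm), 1e-12)) {
    stop("seed region has no signal above the volume mean")
  }
  angles <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  r_max0 <- max(d[1], d[2])
  borders <- vector("list", d[3])
  centers <- matrix(NA_real_, d[3], 2L)

  trace_plane <- function(z, center, prev_radii) {
    band <- if (is.null(prev_radii)) {
      cbind(rep(1, n_rays), rep(r_max0, n_rays))
    } else {
      cbind(pmax(0.5 * prev_radii, 1), 1.5 * prev_radii)
    }
    radii <- plane_border(sm[, , z], center, angles, band)
    poly <- cbind(center[1] + radii * cos(angles),
                  center[2] + radii * sin(angles))
    list(radii = radii, poly = poly,
         center = c(mean(poly[, 1]), mean(poly[, 2])))
  }

  res0 <- trace_plane(z0, seed, NULL)
  borders[[z0]] <- res0$poly
  centers[z0, ] <- res0$center
  for (dir in c(1L, -1L)) {
    prev <- res0
    z <- z0 + dir
    while (z >= 1L && z <= d[3]) {
      pr <- clamp(round(prev$center[2]) + (-2:2), 1L, d[1])
      pc <- clamp(round(prev$center[1]) + (-2:2), 1L, d[2])
      if (mean(sm[pr, pc, z]) < stop_frac * peak) break
      prev <- trace_plane(z, prev$center, prev$radii)
      borders[[z]] <- prev$poly
      centers[z, ] <- prev$center
      z <- z + dir
    }
  }
  z_range <- range(which(!vapply(borders, is.null, TRUE)))
  mask <- array(FALSE, d)
  for (z in z_range[1]:z_range[2]) {
    if (is.null(borders[[z]])) next
    # voxel (i, j) inside when its centre is inside the border polygon
    g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
    inside <- points_in_polygon(g$j, g$i, borders[[z]])
    mask[, , z] <- matrix(inside, d[1], d[2])
  }
  vox_vol <- prod(vol$voxel_nm)
  structure(list(borders = borders, centers = centers, z_range = z_range,
                 z_peak = z0, mask = mask,
                 center = c(centers[z0, ], z0),
                 volume_nm3 = sum(mask) * vox_vol,
                 voxel_nm = vol$voxel_nm),
            class = "nucleus3d")
}

#' @export
print.nucleus3d <- function(x, ...) {
  cat(sprintf("nucleus3d: planes %d..%d (peak %d), volume %.3g um^3\n",
              x$z_range[1], x$z_range[2], x$z_peak, x$volume_nm3 / 1e9))
  invisible(x)
}

#' DNA occupancy of a segmented 3D nucleus
#'
#' Voxels inside the nucleus with intensity above
#' `3 * sqrt(background)` are valid signal; occupancy is their fraction
#' of all nuclear voxels.
#'
#' @param vol A background-corrected [volume3d()].
#' @param nucleus A [segment_nucleus_3d()] result (or a logical voxel
#'   mask).
#' @param background Scalar background level; defaults to the volume's
#'   recorded `background_level`.
#' @param k Threshold multiplier (3 by default).
#' @return Occupancy fraction in `[0, 1]`.
#' @export
dna_occupancy <- function(vol, nucleus, background = NULL, k = 3) {
  mask <- if (inherits(nucleus, "nucleus3d")) nucleus$mask else nucleus
  if (is.null(background)) background <- vol$background_level
  if (!is.finite(background) || background <= 0) {
    if (any(vol$data > 0)) stop("background level must be > 0")
    return(0)
  }
  thr <- k * sqrt(background)
  sum(vol$data[mask] > thr) / sum(mask)
}

# 26-connected components of a logical 3D array (flood fill).
connected_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  idx_all <- which(mask)
  cur <- 0L
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(v, d)
      nb <- cbind(ai[1] + offs[, 1], ai[2] + offs[, 2], ai[3] + offs[, 3])
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      new <- lin[mask[lin] & lab[lin] == 0L]
      lab[new] <- cur
      queue <- c(queue, new)
    }
  }
  lab
}

#' Mean intensity of condensed heterochromatin foci
#'
#' Valid-signal voxels (above `3 * sqrt(background)`) whose intensity also
#' exceeds the `quantile` (default 75th percentile) of valid-signal
#' intensities form the condensed regions; 26-connected components of at
#' least `min_vox` voxels are reported with their mean intensity.
#'
#' @param vol A background-corrected [volume3d()].
#' @param nucleus A [segment_nucleus_3d()] result or logical mask.
#' @param background Scalar background level (default: recorded level).
#' @param condensed_quantile Intensity quantile defining "condensed".
#' @param min_vox Minimum focus size in voxels.
#' @return Numeric vector of per-focus mean intensities (possibly empty).
#' @export
foci_intensity <- function(vol, nucleus, background = NULL,
                           condensed_quantile = 0.75, min_vox = 50L) {
  mask <- if (inherits(nucleus, "nucleus3d")) nucleus$mask else nucleus
  if (is.null(background)) background <- vol$background_level
  thr <- if (is.finite(background) && background > 0) 3 * sqrt(background) else 0
  valid <- mask & vol$data > thr
  if (!any(valid)) return(numeric(0))
  thr2 <- quantile(vol$data[valid], condensed_quantile, names = FALSE)
  condensed <- valid & vol$data >= thr2
  lab <- connected_components_3d(condensed)
  if (max(lab) == 0L) return(numeric(0))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_vox)
  sort(vapply(keep, function(l) mean(vol$data[lab == l]), 0))
}

#' Synthetic 3D nucleus phantoms
#'
#' `sphere_phantom` builds a solid sphere of unit intensity;
#' `nucleus_phantom_3d` builds an ellipsoidal nucleus with condensed
#' heterochromatin foci on a dim euchromatin baseline, on a uniform
#' extranuclear background.  The `"decompact"` preset spreads the same
#' total focus signal over more, larger, dimmer foci.
#'
#' @param radius_nm Sphere radius.
#' @param voxel_nm Voxel size `c(x, y, z)`.
#' @param dim_vox Volume size `(rows, cols, z)`.
#' @param intensity Object intensity.
#' @param background Ambient background level.
#' @return A `volume3d` with attribute `truth` describing the phantom.
#' @export
sphere_phantom <- function(radius_nm = 3000, voxel_nm = c(250, 250, 250),
                           dim_vox = c(40L, 40L, 40L), intensity = 100,
                           background = 0) {
  ctr <- (dim_vox + 1) / 2
  xs <- (seq_len(dim_vox[2]) - ctr[2]) * voxel_nm[1]
  ys <- (seq_len(dim_vox[1]) - ctr[1]) * voxel_nm[2]
  zs <- (seq_len(dim_vox[3]) - ctr[3]) * voxel_nm[3]
  data <- array(background, dim_vox)
  for (z in seq_len(dim_vox[3])) {
    r2 <- outer(ys^2, xs^2, "+") + zs[z]^2
    data[, , z] <- background + intensity * (r2 <= radius_nm^2)
  }
  v <- volume3d(data, voxel_nm)
  attr(v, "truth") <- list(radius_nm = radius_nm,
                           volume_nm3 = 4 / 3 * pi * radius_nm^3,
                           center_vox = ctr)
  v
}

#' @rdname sphere_phantom
#' @param preset `"normal"` (few bright compact foci) or `"decompact"`
#'   (same total focus signal in more, larger, dimmer foci).
#' @param seed Integer seed for focus placement.
#' @export
nucleus_phantom_3d <- function(preset = c("normal", "decompact"),
                               voxel_nm = c(250, 250, 250),
                               dim_vox = c(48L, 48L, 32L),
                               background = 4, seed = 1L) {
  preset <- match.arg(preset)
  par <- switch(preset,
    normal    = list(n_foci = 6L, r_vox = 2.2, intensity = 160),
    # ~2x focus volume each and 2x count at ~1/4 intensity: same total signal
    decompact = list(n_foci = 12L, r_vox = 2.8, intensity = 40))
  ctr <- (dim_vox + 1) / 2
  semi <- c(0.38 * dim_vox[1], 0.38 * dim_vox[2], 0.34 * dim_vox[3])
  data <- array(background, dim_vox)
  ii <- slice.index(data, 1); jj <- slice.index(data, 2)
  kk <- slice.index(data, 3)
  inside <- ((ii - ctr[1]) / semi[1])^2 + ((jj - ctr[2]) / semi[2])^2 +
    ((kk - ctr[3]) / semi[3])^2 <= 1
  baseline <- 2          # euchromatin, below the 3*sqrt(bg) threshold
  data[inside] <- background + baseline
  foci <- with_seed(seed, {
    u <- matrix(runif(par$n_foci * 3L, -0.55, 0.55), ncol = 3L)
    sweep(u, 2L, semi, "*") + matrix(ctr, par$n_foci, 3L, byrow = TRUE)
  })
  for (f in seq_len(par$n_foci)) {
    d2 <- (ii - foci[f, 1])^2 + (jj - foci[f, 2])^2 + (kk - foci[f, 3])^2
    sel <- d2 <= par$r_vox^2 & inside
    data[sel] <- background + par$intensity
  }
  v <- volume3d(data, voxel_nm)
  attr(v, "truth") <- list(preset = preset, foci = foci,
                           focus_intensity = par$intensity,
                           background = background, inside = inside)
  v
}
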