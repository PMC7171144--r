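# Per-nucleus chromatin nanostructure quantification.
#
# All operations take localized point coordinates (nm) or maps derived
# from them at the 13 nm render resolution, and are computed per nucleus.

# ---- helpers ---------------------------------------------------------------

# Normalize a mask argument (polygon matrix, nucleus_mask, or logical
# matrix) to a raster representation.
as_mask_raster <- function(mask, pixel_nm = 13, origin = c(0, 0),
                           points = NULL) {
  if (inherits(mask, "nucleus_mask")) {
    lab <- mask_labels(mask)
    return(list(raster = lab > 0L, pixel_nm = mask$pixel_nm,
                origin = mask$origin))
  }
  if (is.matrix(mask) && is.logical(mask)) {
    return(list(raster = mask, pixel_nm = pixel_nm, origin = origin))
  }
  if (is.matrix(mask) && ncol(mask) == 2L) {   # polygon in nm
    xmax <- max(mask[, 1]); ymax <- max(mask[, 2])
    dim_px <- c(ceiling((ymax - origin[2]) / pixel_nm) + 1L,
                ceiling((xmax - origin[1]) / pixel_nm) + 1L)
    return(list(raster = rasterize_polygon(mask, pixel_nm, dim_px, origin),
                pixel_nm = pixel_nm, origin = origin))
  }
  stop("unsupported mask representation")
}

mask_area_nm2 <- function(mr) sum(mr$raster) * mr$pixel_nm^2

# Raster lookup: TRUE when (x, y) nm falls on a mask pixel.
mask_lookup <- function(mr, x, y) {
  j <- floor((x - mr$origin[1]) / mr$pixel_nm) + 1L
  i <- floor((y - mr$origin[2]) / mr$pixel_nm) + 1L
  ok <- i >= 1L & i <= nrow(mr$raster) & j >= 1L & j <= ncol(mr$raster)
  out <- logical(length(x))
  out[ok] <- mr$raster[cbind(i[ok], j[ok])]
  out
}

# ---- GMM nanoclusters ------------------------------------------------------

# EM over the BIC grid from kmeans starts on the non-noise points, with
# the flagged points seeding the uniform noise component.  Returns an
# Mclust-like list (G, parameters, classification, BIC) or NULL.
gmm_kmeans_em <- function(points, G, model_name, noise0, prior = NULL,
                          nstart = 5L) {
  n <- nrow(points)
  core <- points[!noise0, , drop = FALSE]
  env <- new.env(parent = asNamespace("mclust"))
  env$points <- points; env$model_name <- model_name; env$pri <- prior
  env$vinv <- mclust::hypvol(points, reciprocal = TRUE)
  best <- NULL
  for (g in G) {
    if (nrow(core) < 2L * g) next
    km <- tryCatch(kmeans(core, g, nstart = nstart, iter.max = 50L),
                   error = function(e) NULL)
    if (is.null(km)) next
    z <- matrix(0, n, g + 1L)
    z[cbind(which(!noise0), km$cluster)] <- 1
    z[noise0, g + 1L] <- 1
    env$z <- z
    m <- tryCatch(
      suppressWarnings(
        eval(quote(me(data = points, modelName = model_name, z = z,
                      prior = pri, Vinv = vinv)), env)),
      error = function(e) NULL)
    if (is.null(m) || !is.finite(m$loglik)) next
    df <- mclust::nMclustParams(model_name, d = 2L, G = g, noise = TRUE)
    bic <- 2 * m$loglik - df * log(n)
    if (is.null(best) || bic > best$bic) {
      cl <- apply(m$z, 1L, which.max)
      cl[cl == g + 1L] <- 0L
      best <- list(G = g, parameters = m$parameters,
                   classification = cl, bic = bic, BIC = bic)
    }
  }
  best
}

# Trimmed per-component size: covariance of the component's assigned
# points after iteratively discarding the 10% farthest from the centre.
# A few distant mis-assigned points inflate a fitted variance enough to
# keep themselves plausibly assigned (an EM local optimum); the trim
# removes them.  The trim shrinks even clean Gaussian components by a
# fixed factor, so trimmed sizes are comparable only with each other.
trimmed_component_size <- function(pts_k, floor_nm2, trim = 0.9,
                                   iters = 2L) {
  if (nrow(pts_k) < 5L) {
    v <- if (nrow(pts_k) > 1L) diag(var(pts_k)) else c(0, 0)
    return(2 * sqrt(sqrt(prod(pmax(v, floor_nm2)))))
  }
  keep <- pts_k
  for (i in seq_len(iters)) {
    ctr <- colMeans(keep)
    d2 <- (keep[, 1] - ctr[1])^2 + (keep[, 2] - ctr[2])^2
    keep <- keep[d2 <= quantile(d2, trim), , drop = FALSE]
  }
  ev <- pmax(eigen(var(keep), symmetric = TRUE, only.values = TRUE)$values,
             floor_nm2)
  2 * sqrt(sqrt(prod(ev)))
}

# Initial noise indicator for the mixture fit: points whose distance to
# their k-th nearest neighbour exceeds twice the median of that distance
# are flagged as likely diffuse background.  EM refines the assignment.
knn_noise_guess <- function(points, k = 10L) {
  n <- nrow(points)
  k <- min(k, n - 1L)
  kd <- numeric(n)
  bs <- 512L
  for (i0 in seq(1L, n, by = bs)) {
    ii <- i0:min(i0 + bs - 1L, n)
    d2 <- outer(points[ii, 1], points[, 1], "-")^2 +
      outer(points[ii, 2], points[, 2], "-")^2
    kd[ii] <- sqrt(apply(d2, 1L, function(v) sort(v, partial = k + 1L)[k + 1L]))
  }
  kd > 2 * median(kd)
}

#' Cluster localizations with a Gaussian mixture model
#'
#' Fits Gaussian mixtures over a range of component counts and selects the
#' count by BIC (via \pkg{mclust}, with deterministic model-based
#' hierarchical initialisation).  Each localization is assigned to its
#' maximum-posterior component.  The per-cluster size metric is
#' `2 * sqrt(geometric mean of the covariance eigenvalues)` -- a 2-sigma
#' effective diameter -- with eigenvalues floored at `floor_nm2` so
#' degenerate clusters report the regularisation floor instead of zero.
#'
#' @param points n x 2 matrix of localization coordinates (nm).
#' @param G Candidate component counts (BIC range).
#' @param model_names \pkg{mclust} covariance family (default `"VVV"`,
#'   fully general).
#' @param floor_nm2 Eigenvalue floor in nm^2.
#' @param seed Seed for the stochastic restarts.
#' @param n_restarts EM initialisations per nucleus: the deterministic
#'   full-sample hierarchical initialisation plus `n_restarts - 1` random
#'   500-point subset initialisations; the fit with the best BIC wins.
#'   Restarts stabilise the component count at large G, where a single
#'   poor initialisation can under-split the pattern.
#' @param noise Add a uniform (Poisson) noise component that absorbs
#'   diffuse non-clustered localizations, so they do not inflate the
#'   Gaussian components' covariances.  Noise-assigned points get
#'   `assignment` 0 and do not count toward cluster statistics.
#' @param robust_size Compute sizes from each component's assigned
#'   points after an iterated 90% central trim instead of from the
#'   fitted covariance.  Robust against the few distant mis-assigned
#'   points that EM retains in dense noise, at the cost of a fixed
#'   multiplicative shrink (~0.86 on clean Gaussian clusters): trimmed
#'   sizes are comparable only with other trimmed sizes.
#' @param prior Covariance regularisation via \pkg{mclust}'s conjugate
#'   prior: `FALSE` (none, the default), `TRUE` (`priorControl()` with
#'   its data-scaled covariance target), or a numeric variance scale in
#'   nm^2 (`priorControl(scale = prior)`).  A small fixed scale (for
#'   instance 100) prevents EM failures from components collapsing onto
#'   near-duplicate points without the strong upward size bias the
#'   data-scaled target induces when components are far smaller than the
#'   pattern's overall spread.
#' @return A `cluster_set`: per-cluster centres, size metric (nm) and
#'   localization counts; per-nucleus means of size, localizations per
#'   cluster and nearest-neighbour distance between cluster centres.
#' @export
gmm_clusters <- function(points, G = 1:10, model_names = "VVV",
                         floor_nm2 = 1, seed = 42L, n_restarts = 5L,
                         noise = FALSE, prior = FALSE,
                         robust_size = FALSE) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L * min(G)) {
    stop("need at least ", 2L * min(G), " points for GMM clustering")
  }
  # Mclust resolves its helper functions in the caller's frame, so calls
  # are evaluated in an environment parented by the mclust namespace
  env <- new.env(parent = asNamespace("mclust"))
  env$points <- points; env$G <- G; env$model_names <- model_names
  env$pri <- if (is.numeric(prior)) {
    mclust::priorControl(scale = prior)
  } else if (isTRUE(prior)) {
    mclust::priorControl()
  } else NULL
  fit <- with_seed(seed, {
    noise0 <- if (noise) knn_noise_guess(points) else NULL
    run <- function(init) {
      env$init <- init
      # NA BIC entries at unreachable G are expected and handled here
      tryCatch(
        suppressWarnings(
          eval(quote(Mclust(points, G = G, modelNames = model_names,
                            prior = pri, initialization = init,
                            verbose = FALSE)), env)),
        error = function(e) NULL)
    }
    best <- run(if (noise) list(noise = noise0) else NULL)
    for (r in seq_len(max(0L, n_restarts - 1L))) {
      sub <- sample.int(n, min(n, 500L))
      cand <- run(if (noise) list(subset = sub, noise = noise0)
                  else list(subset = sub))
      if (!is.null(cand) &&
          (is.null(best) || max(cand$BIC, na.rm = TRUE) >
             max(best$BIC, na.rm = TRUE))) {
        best <- cand
      }
    }
    if (noise) {
      # hierarchical initialisation often stalls in a merged local
      # optimum on cluster + uniform-noise mixtures; a kmeans start on
      # the non-noise points regularly reaches a much better BIC
      km <- gmm_kmeans_em(points, G, model_names, noise0,
                          prior = env$pri)
      if (!is.null(km) &&
          (is.null(best) || km$bic > max(best$BIC, na.rm = TRUE))) {
        best <- km
      }
    }
    best
  })
  if (is.null(fit) || fit$G < 1L) {
    # degenerate input (e.g. all points identical): one regularised cluster
    centers <- matrix(colMeans(points), 1L, 2L)
    sizes <- 2 * sqrt(sqrt(floor_nm2 * floor_nm2))
    n_loc <- nrow(points)
    assignment <- rep.int(1L, nrow(points))
  } else {
    k <- fit$G
    centers <- t(fit$parameters$mean)
    sig <- fit$parameters$variance$sigma
    assignment <- fit$classification   # 0 = noise component, if any
    sizes <- vapply(seq_len(k), function(i) {
      if (robust_size && sum(assignment == i) > 0L) {
        trimmed_component_size(points[assignment == i, , drop = FALSE],
                               floor_nm2)
      } else {
        ev <- pmax(eigen(sig[, , i], symmetric = TRUE,
                         only.values = TRUE)$values, floor_nm2)
        2 * sqrt(sqrt(prod(ev)))
      }
    }, 0)
    n_loc <- as.integer(table(factor(assignment, levels = seq_len(k))))
  }
  nnd <- if (nrow(centers) >= 2L) {
    mean(nearest_neighbor_distances(centers)$nnd)
  } else NA_real_
  structure(list(
    centers = centers, sizes = sizes, n_loc = n_loc,
    assignment = assignment,
    mean_size = mean(sizes),
    mean_locs_per_cluster = mean(n_loc),
    mean_nnd = nnd
  ), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters, mean size %.1f nm, mean %.1f locs/cluster\n",
              length(x$sizes), x$mean_size, x$mean_locs_per_cluster))
  invisible(x)
}

#' Nearest-neighbour distances between cluster centres
#'
#' @param centers n x 2 matrix (n >= 2) of positions (nm).
#' @return List with per-centre `nnd` (nm) and its `mean`.
#' @export
nearest_neighbor_distances <- function(centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 2L) stop("need >= 2 centres for nearest-neighbour distances")
  d <- as.matrix(dist(centers))
  diag(d) <- Inf
  nnd <- unname(apply(d, 1L, min))
  list(nnd = nnd, mean = mean(nnd))
}

# ---- pair correlation function --------------------------------------------

#' Radial distribution function (pair correlation) with mask edge correction
#'
#' Estimates `g(r)` as pair counts in annuli `[r, r + dr)` divided by the
#' CSR expectation `N * rho * (annulus area inside the mask)`.  The
#' inside-mask annulus area is evaluated per point by sampling the
#' mid-radius circle at `n_angles` angles against the mask raster.  The
#' correlation length is the smallest radius past the peak at which
#' `g(r) - 1` falls below `(g_peak - 1)/e` (linearly interpolated).
#'
#' @param points n x 2 matrix of coordinates (nm).
#' @param mask Nucleus mask (polygon matrix in nm, `nucleus_mask`, or
#'   logical raster).
#' @param dr Radial bin width (nm).
#' @param r_max Largest radius (nm).
#' @param n_angles Angular samples for the edge correction.
#' @param pixel_nm Raster resolution when `mask` is a polygon.
#' @return An `rdf_curve` data frame (`r`, `g`) with attributes `dr` and
#'   `correlation_length`.
#' @export
rdf <- function(points, mask, dr = 10, r_max = 500, n_angles = 64L,
                pixel_nm = 13) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need >= 2 points for the pair correlation function")
  mr <- as_mask_raster(mask, pixel_nm = pixel_nm)
  area <- mask_area_nm2(mr)
  if (area <= 0) stop("empty mask")
  rho <- n / area
  breaks <- seq(0, r_max, by = dr)
  nb <- length(breaks) - 1L
  # ordered pair counts per annulus, in blocks to bound memory
  counts <- numeric(nb)
  bs <- 256L
  for (i0 in seq(1L, n, by = bs)) {
    ii <- i0:min(i0 + bs - 1L, n)
    dx <- outer(points[ii, 1], points[, 1], "-")
    dy <- outer(points[ii, 2], points[, 2], "-")
    d <- sqrt(dx * dx + dy * dy)
    d <- d[d > 0 & d < r_max]
    if (length(d) > 0L) {
      counts <- counts + tabulate(findInterval(d, breaks), nbins = nb)
    }
  }
  # per-point inside-mask fraction of each mid-radius circle
  th <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  denom <- numeric(nb)
  r_mid <- breaks[-1L] - dr / 2
  full_area <- pi * (breaks[-1L]^2 - breaks[-(nb + 1L)]^2)
  for (k in seq_len(nb)) {
    frac <- numeric(n)
    for (t in th) {
      frac <- frac + mask_lookup(mr, points[, 1] + r_mid[k] * cos(t),
                                 points[, 2] + r_mid[k] * sin(t))
    }
    denom[k] <- rho * full_area[k] * sum(frac) / n_angles
  }
  g <- ifelse(denom > 0, counts / denom, NA_real_)
  out <- data.frame(r = r_mid, g = g)
  attr(out, "dr") <- dr
  attr(out, "correlation_length") <- correlation_length(r_mid, g)
  class(out) <- c("rdf_curve", "data.frame")
  out
}

# 1/e decay radius of g(r) - 1 past the peak, linearly interpolated.
correlation_length <- function(r, g) {
  ok <- is.finite(g)
  r <- r[ok]; g <- g[ok]
  if (length(g) == 0L) return(NA_real_)
  ip <- which.max(g)
  g_peak <- g[ip]
  if (g_peak <= 1) return(NA_real_)
  thr <- 1 + (g_peak - 1) / exp(1)
  below <- which(g <= thr & seq_along(g) >= ip)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1]
  if (i == ip) return(r[i])
  # linear interpolation of the crossing
  r[i - 1] + (r[i] - r[i - 1]) * (g[i - 1] - thr) / (g[i - 1] - g[i])
}

# ---- Voronoi density -------------------------------------------------------

#' Voronoi density map of a localization pattern
#'
#' Tessellates the (unique) point coordinates, computes each polygon's
#' area, and assigns the density `1/area` at the point's raster position;
#' the map is then Gaussian-smoothed (sd 2 px by default).  Cells clipped
#' by the tessellation window (the former unbounded border cells) are
#' flagged and excluded from the summary statistics.
#'
#' @param points n x 2 matrix of coordinates (nm), n >= 4 and not all
#'   collinear.
#' @param mask Nucleus mask; defines the raster extent and the reported
#'   statistics region.
#' @param pixel_nm Raster resolution (default 13 nm).
#' @param smooth_sigma Smoothing sd in pixels.
#' @return A `voronoi_density_map`: raster `map` (smoothed density),
#'   per-point `areas` (nm^2), `density` (nm^-2), `border` flags, and the
#'   raster geometry.
#' @export
voronoi_density <- function(points, mask, pixel_nm = 13, smooth_sigma = 2) {
  points <- unique(as.matrix(points))
  if (nrow(points) < 4L) stop("need >= 4 unique points for Voronoi tessellation")
  if (abs(cor(points[, 1], points[, 2])) > 1 - 1e-12) {
    stop("degenerate (collinear) point pattern")
  }
  mr <- as_mask_raster(mask, pixel_nm = pixel_nm)
  rw <- c(mr$origin[1], mr$origin[1] + ncol(mr$raster) * mr$pixel_nm,
          mr$origin[2], mr$origin[2] + nrow(mr$raster) * mr$pixel_nm)
  dd <- deldir::deldir(points[, 1], points[, 2], rw = rw)
  areas <- dd$summary$dir.area
  border <- logical(nrow(points))
  bp <- dd$dirsgs[dd$dirsgs$bp1 | dd$dirsgs$bp2, c("ind1", "ind2")]
  border[unique(unlist(bp))] <- TRUE
  dens <- 1 / areas
  map <- matrix(0, nrow(mr$raster), ncol(mr$raster))
  j <- clamp(floor((points[, 1] - mr$origin[1]) / mr$pixel_nm) + 1L,
             1L, ncol(map))
  i <- clamp(floor((points[, 2] - mr$origin[2]) / mr$pixel_nm) + 1L,
             1L, nrow(map))
  for (k in seq_len(nrow(points))) {
    map[i[k], j[k]] <- map[i[k], j[k]] + dens[k]
  }
  map <- gaussian_smooth(map, smooth_sigma)
  structure(list(map = map, areas = areas, density = dens, border = border,
                 points = points, pixel_nm = mr$pixel_nm,
                 origin = mr$origin, mask = mr$raster,
                 smooth_sigma = smooth_sigma),
            class = "voronoi_density_map")
}

#' @export
print.voronoi_density_map <- function(x, ...) {
  cat(sprintf(
    "voronoi_density_map: %d points, median density %.3g /nm^2 (%d border cells excluded)\n",
    nrow(x$points), median(x$density[!x$border]), sum(x$border)))
  invisible(x)
}

# ---- watershed nanodomains -------------------------------------------------

# Regional maxima (8-connected, plateau-correct) of a non-negative map.
regional_maxima <- function(map) {
  nr <- nrow(map); nc <- ncol(map)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- map
  nbmax <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nbmax <- pmax(nbmax, pad[2:(nr + 1L) + dr, 2:(nc + 1L) + dc])
  }
  cand <- map >= nbmax & map > 0
  if (!any(cand)) return(cand)
  lab <- EBImage::bwlabel(cand)
  out <- matrix(FALSE, nr, nc)
  for (l in seq_len(max(lab))) {
    px <- which(lab == l, arr.ind = TRUE)
    v <- map[px[1, 1], px[1, 2]]
    # ring of pixels around the plateau
    r0 <- max(1L, min(px[, 1]) - 1L); r1 <- min(nr, max(px[, 1]) + 1L)
    c0 <- max(1L, min(px[, 2]) - 1L); c1 <- min(nc, max(px[, 2]) + 1L)
    sub <- lab[r0:r1, c0:c1]
    subm <- map[r0:r1, c0:c1]
    comp <- sub == l
    grown <- EBImage::dilate(comp, EBImage::makeBrush(3L, "box"))
    ring <- grown & !comp
    if (!any(ring) || all(subm[ring] < v)) out[px] <- TRUE
  }
  out
}

#' Watershed segmentation of a density map into nanodomains
#'
#' Implements the fixed recipe: regional maxima of the smoothed density
#' map; dilation with a disk of diameter 5 px; distance transform of the
#' inverse dilated map; amplification by 2 and addition of the binary
#' (map > 0) support; watershed on the negative of the sum; rejection of
#' segments outside the binary support; rejection of segments under
#' `min_area_px` (20) pixels.  Equivalent diameter is
#' `2 * sqrt(area_px * pixel_nm^2 / pi)`.
#'
#' @param density_map A [voronoi_density()] map, a [rendered_image()], or
#'   a plain matrix (already smoothed).
#' @param mask Optional logical raster restricting the segmentation to a
#'   nucleus.
#' @param min_area_px Minimum retained segment area (px).
#' @param pixel_nm Map pixel size when `density_map` is a plain matrix.
#' @return A `nanodomain_segmentation`: integer `labels` matrix,
#'   `areas_px`, `diameters_nm`, `count`, and `occupied_fraction` of the
#'   mask (or of the map when no mask is given).
#' @export
watershed_domains <- function(density_map, mask = NULL, min_area_px = 20L,
                              pixel_nm = 13) {
  if (inherits(density_map, "voronoi_density_map")) {
    map <- density_map$map
    pixel_nm <- density_map$pixel_nm
    if (is.null(mask)) mask <- density_map$mask
  } else if (inherits(density_map, "rendered_image")) {
    map <- density_map$counts
    pixel_nm <- density_map$pixel_nm
  } else {
    map <- density_map
  }
  if (!is.null(mask)) map[!mask] <- 0
  support <- map > 0
  empty <- structure(list(labels = matrix(0L, nrow(map), ncol(map)),
                          areas_px = integer(0), diameters_nm = numeric(0),
                          count = 0L, occupied_fraction = 0,
                          pixel_nm = pixel_nm),
                     class = "nanodomain_segmentation")
  if (!any(support)) return(empty)
  rmax <- regional_maxima(map)
  if (!any(rmax)) return(empty)
  dil <- EBImage::dilate(rmax, EBImage::makeBrush(5L, "disc"))
  D <- EBImage::distmap(dil)            # distance transform of inverse map
  landscape <- 2 * D + support          # watershed runs on the negative
  labels <- EBImage::imageData(EBImage::watershed(landscape, tolerance = 0.1))
  labels[!support] <- 0L                # reject segments outside the support
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= min_area_px)
  relabel <- integer(length(areas))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  areas <- areas[keep]
  denom <- if (!is.null(mask)) sum(mask) else length(map)
  structure(list(labels = labels, areas_px = areas,
                 diameters_nm = 2 * sqrt(areas * pixel_nm^2 / pi),
                 count = length(areas),
                 occupied_fraction = sum(areas) / denom,
                 pixel_nm = pixel_nm),
            class = "nanodomain_segmentation")
}

#' @export
print.nanodomain_segmentation <- function(x, ...) {
  cat(sprintf("nanodomain_segmentation: %d domains, median diameter %.0f nm\n",
              x$count, if (x$count > 0) median(x$diameters_nm) else NA))
  invisible(x)
}

# ---- coverage and colocalization -------------------------------------------

#' Covered-area fraction of a nucleus
#'
#' Smooths the rendered localization image with a Gaussian (sigma = 1 px)
#' and reports the fraction of mask pixels whose smoothed value exceeds
#' 0.5.
#'
#' @param rendered A [rendered_image()] or count matrix at 13 nm.
#' @param mask Logical matrix of nucleus pixels (same shape).
#' @param smooth_sigma Smoothing sd in pixels.
#' @param threshold Coverage threshold in smoothed counts/pixel.
#' @return Covered fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(rendered, mask, smooth_sigma = 1,
                              threshold = 0.5) {
  img <- if (inherits(rendered, "rendered_image")) rendered$counts else rendered
  if (!any(mask)) stop("empty mask")
  if (!all(dim(img) == dim(mask))) stop("image and mask shapes differ")
  sm <- gaussian_smooth(img, smooth_sigma)
  mean(sm[mask] > threshold)
}

#' Directional overlap of two binary maps
#'
#' @param map_a,map_b Logical matrices of identical shape (channel B
#'   already chromatically registered).
#' @return A `colocalization_result` with `a_over_b` (fraction of A pixels
#'   overlapping B) and `b_over_a`; an empty map makes its direction `NA`
#'   and sets the `undefined` flag.
#' @export
colocalize <- function(map_a, map_b) {
  if (!all(dim(map_a) == dim(map_b))) stop("maps must have the same shape")
  na <- sum(map_a); nb <- sum(map_b)
  both <- sum(map_a & map_b)
  structure(list(
    a_over_b = if (na > 0) both / na else NA_real_,
    b_over_a = if (nb > 0) both / nb else NA_real_,
    undefined = c(a = na == 0, b = nb == 0)
  ), class = "colocalization_result")
}

#' Compare two groups of per-nucleus summaries
#'
#' Two-tailed Mann-Whitney U test (exact for small samples without ties,
#' normal approximation otherwise).
#'
#' @param group1,group2 Numeric vectors (each length >= 2).
#' @return List with the `U` statistic (number of (x, y) pairs with
#'   x > y), `p` value, and group sizes.
#' @export
group_compare <- function(group1, group2) {
  if (length(group1) < 1L || length(group2) < 1L) stop("empty group")
  wt <- suppressWarnings(wilcox.test(group1, group2, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(group1), n2 = length(group2))
}
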