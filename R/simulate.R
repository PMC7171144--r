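# Synthetic chromatin point patterns and blinking-emitter frame stacks.
#
# The generator emulates what tissue SMLM of chromatin looks like to the
# reconstruction code: nucleosome nanoclusters drawn as isotropic Gaussian
# clouds inside a nuclear boundary, a diffuse non-clustered fraction,
# per-frame stochastic blinking, a spatially varying Poisson background,
# camera gain/offset, linear stage drift, and bright always-on fiducial
# beads.  Chromatin decompaction is modelled as fragmentation: more,
# smaller, sparser clusters at fixed total localization count.

#' Generate a ground-truth chromatin point pattern
#'
#' Draws cluster centres uniformly inside the nuclear boundary, scatters
#' `points_per_cluster` emitters around each centre with isotropic Gaussian
#' spread `cluster_sigma`, and adds `background_points` uniform
#' non-clustered emitters.  Emitters falling outside the boundary are
#' redrawn (rejection sampling), so every emitter lies inside the nucleus.
#'
#' @param n_clusters Number of nanoclusters (>= 0).
#' @param cluster_sigma Gaussian spread of each cluster in nm; scalar or
#'   length-`n_clusters` vector.
#' @param points_per_cluster Emitters per cluster; scalar or vector.
#' @param background_points Number of uniform non-clustered emitters.
#' @param nucleus Closed polygon (two-column matrix, nm) bounding the
#'   nucleus.  Default: a 64-gon circle of radius 2500 nm centred at
#'   (3250, 3250) nm.
#' @param seed Integer seed; the same seed yields an identical pattern.
#' @return A `ground_truth_pattern`: list with the nucleus polygon, cluster
#'   centres, per-cluster sigma and counts, emitter positions (`emitters`,
#'   an n x 2 matrix in nm), the generating cluster index per emitter
#'   (`cluster_id`, 0 for background emitters) and the seed.
#' @examples
#' gt <- make_ground_truth(10, 30, 50, background_points = 0, seed = 1)
#' nrow(gt$emitters)  # 500
#' @export
make_ground_truth <- function(n_clusters, cluster_sigma = 50,
                              points_per_cluster = 50,
                              background_points = 0,
                              nucleus = NULL, seed = 1L) {
  if (is.null(nucleus)) nucleus <- circle_polygon(c(3250, 3250), 2500)
  nucleus <- as.matrix(nucleus)
  if (nrow(nucleus) < 3L || polygon_area(nucleus) <= 0) {
    stop("nucleus polygon is degenerate (area 0)")
  }
  if (n_clusters < 0L) stop("n_clusters must be >= 0")
  cluster_sigma <- rep_len(cluster_sigma, max(n_clusters, 1L))[seq_len(n_clusters)]
  points_per_cluster <- rep_len(points_per_cluster,
                                max(n_clusters, 1L))[seq_len(n_clusters)]
  if (any(cluster_sigma <= 0)) stop("cluster_sigma must be > 0")
  if (any(points_per_cluster < 0L)) stop("points_per_cluster must be >= 0")

  with_seed(seed, {
    centers <- runif_in_polygon(n_clusters, nucleus)
    pts <- vector("list", n_clusters + 1L)
    ids <- vector("list", n_clusters + 1L)
    for (k in seq_len(n_clusters)) {
      n_k <- points_per_cluster[k]
      p <- matrix(NA_real_, n_k, 2L)
      need <- seq_len(n_k)
      while (length(need) > 0L) {
        cand <- cbind(rnorm(length(need), centers[k, 1], cluster_sigma[k]),
                      rnorm(length(need), centers[k, 2], cluster_sigma[k]))
        ok <- points_in_polygon(cand[, 1], cand[, 2], nucleus)
        p[need[ok], ] <- cand[ok, , drop = FALSE]
        need <- need[!ok]
      }
      pts[[k]] <- p
      ids[[k]] <- rep.int(k, n_k)
    }
    pts[[n_clusters + 1L]] <- runif_in_polygon(background_points, nucleus)
    ids[[n_clusters + 1L]] <- rep.int(0L, background_points)
    emitters <- do.call(rbind, pts)
    structure(list(
      nucleus = nucleus,
      cluster_centers = centers,
      cluster_sigma = cluster_sigma,
      points_per_cluster = points_per_cluster,
      background_points = background_points,
      emitters = emitters,
      cluster_id = unlist(ids),
      seed = seed
    ), class = "ground_truth_pattern")
  })
}

#' @export
print.ground_truth_pattern <- function(x, ...) {
  cat(sprintf(
    "ground_truth_pattern: %d emitters (%d clusters, %d background), seed %d\n",
    nrow(x$emitters), nrow(x$cluster_centers), x$background_points, x$seed))
  invisible(x)
}

#' Chromatin compaction presets for the simulator
#'
#' Presets emulate the in-silico compaction axis the quantification suite
#' is validated on: progressive fragmentation of heterochromatin at fixed
#' total localization count.  `"normal"` (alias `"compact"`) has few large
#' dense nanoclusters; `"early"` is intermediate; `"tumor"` (alias
#' `"decompact"`) has many small sparse clusters.
#'
#' @param preset One of `"normal"`, `"early"`, `"tumor"`, `"compact"`,
#'   `"decompact"`, or `"easy"` (sparse well-separated uniform emitters,
#'   for reconstruction benchmarks).
#' @param seed Integer seed passed to [make_ground_truth()].
#' @param nucleus Optional nucleus polygon.
#' @return A `ground_truth_pattern`.
#' @export
chromatin_preset <- function(preset = c("normal", "early", "tumor",
                                        "compact", "decompact", "easy"),
                             seed = 1L, nucleus = NULL) {
  preset <- match.arg(preset)
  if (preset == "easy") {
    return(make_ground_truth(0L, background_points = 150L,
                             nucleus = nucleus, seed = seed))
  }
  # fragmentation axis at a fixed total of 1260 localizations: cluster
  # count rises while sigma and per-cluster occupancy fall (smaller,
  # sparser nanoclusters), and the released signal joins the diffuse
  # non-clustered pool (decompacted chromatin spreads over the nucleus)
  par <- switch(preset,
    normal    = ,
    compact   = list(n = 20L, sigma = 50, ppc = 60L, bg = 60L),
    early     = list(n = 25L, sigma = 35, ppc = 42L, bg = 210L),
    tumor     = ,
    decompact = list(n = 30L, sigma = 22, ppc = 28L, bg = 420L))
  make_ground_truth(par$n, par$sigma, par$ppc, background_points = par$bg,
                    nucleus = nucleus, seed = seed)
}

#' Camera / acquisition model for the frame-stack simulator
#'
#' @param psf_sigma PSF standard deviation, nm.
#' @param camera_pixel Camera pixel size, nm/px.
#' @param n_frames Number of frames.
#' @param photons_per_blink Mean photons emitted per blink event.
#' @param photon_dist `"constant"` (every blink emits exactly
#'   `photons_per_blink`) or `"lognormal"` (mean `photons_per_blink`,
#'   sdlog 0.3).
#' @param on_probability Per-emitter per-frame probability of being on.
#' @param background_field Expected background in photons/pixel/frame: a
#'   scalar, a matrix of the field-of-view size, or `function(x_nm, y_nm)`.
#' @param gain Camera gain, counts/photon (> 0).
#' @param offset Camera offset, counts.
#' @param drift_rate Stage drift (dx, dy) in nm/frame (linear), or an
#'   `n_frames` x 2 matrix of cumulative displacements.
#' @param fiducial_positions Optional k x 2 matrix of always-on bead
#'   positions (nm).
#' @param fiducial_photons Photons/frame emitted by each fiducial.
#' @param fov_px Field of view as (n_rows, n_cols) pixels.
#' @param noise If `FALSE`, Poisson noise is disabled and frames carry the
#'   expected photon counts (used by tests for exact photometry).
#' @param seed Integer seed.
#' @return An `acquisition_model` list.
#' @export
acquisition_model <- function(psf_sigma = 130, camera_pixel = 100,
                              n_frames = 100L, photons_per_blink = 1000,
                              photon_dist = c("constant", "lognormal"),
                              on_probability = 0.02,
                              background_field = 10, gain = 2, offset = 100,
                              drift_rate = c(0, 0),
                              fiducial_positions = NULL,
                              fiducial_photons = 5000,
                              fov_px = c(65L, 65L), noise = TRUE, seed = 1L) {
  photon_dist <- match.arg(photon_dist)
  stopifnot(gain > 0, psf_sigma > 0, camera_pixel > 0,
            on_probability > 0, on_probability <= 1)
  structure(list(
    psf_sigma = psf_sigma, camera_pixel = camera_pixel,
    n_frames = as.integer(n_frames),
    photons_per_blink = photons_per_blink, photon_dist = photon_dist,
    on_probability = on_probability, background_field = background_field,
    gain = gain, offset = offset, drift_rate = drift_rate,
    fiducial_positions = fiducial_positions,
    fiducial_photons = fiducial_photons,
    fov_px = as.integer(fov_px), noise = noise, seed = seed
  ), class = "acquisition_model")
}

# Expected photon image of one emitter: 2D Gaussian PSF integrated over
# pixel areas (erf-difference form), evaluated only inside a +-4 sigma
# window.  Returns a list(rows, cols, img) patch or NULL when the emitter
# is outside the field of view.
psf_patch <- function(x_nm, y_nm, photons, sigma_nm, pixel_nm, fov_px) {
  r_px <- ceiling(4 * sigma_nm / pixel_nm)
  ci <- floor(x_nm / pixel_nm) + 1L   # 1-based column of the emitter
  ri <- floor(y_nm / pixel_nm) + 1L
  cols <- max(1L, ci - r_px):min(fov_px[2], ci + r_px)
  rows <- max(1L, ri - r_px):min(fov_px[1], ri + r_px)
  if (ci + r_px < 1L || ci - r_px > fov_px[2] ||
      ri + r_px < 1L || ri - r_px > fov_px[1]) {
    return(NULL)
  }
  ex <- pnorm((cols * pixel_nm - x_nm) / sigma_nm) -
        pnorm(((cols - 1L) * pixel_nm - x_nm) / sigma_nm)
  ey <- pnorm((rows * pixel_nm - y_nm) / sigma_nm) -
        pnorm(((rows - 1L) * pixel_nm - y_nm) / sigma_nm)
  list(rows = rows, cols = cols, img = photons * (ey %o% ex))
}

# Resolve the acquisition background field to a matrix.
resolve_background_field <- function(bg, fov_px, pixel_nm) {
  if (is.function(bg)) {
    xc <- (seq_len(fov_px[2]) - 0.5) * pixel_nm
    yc <- (seq_len(fov_px[1]) - 0.5) * pixel_nm
    b <- outer(yc, xc, bg)
  } else if (is.matrix(bg)) {
    if (!all(dim(bg) == fov_px)) stop("background_field dimensions != fov_px")
    b <- bg
  } else {
    b <- matrix(bg, fov_px[1], fov_px[2])
  }
  if (any(b < 0)) stop("background_field must be >= 0 everywhere")
  b
}

# Cumulative drift per frame as an n x 2 matrix.
drift_track <- function(drift_rate, n_frames) {
  if (is.matrix(drift_rate)) {
    if (nrow(drift_rate) != n_frames) stop("drift trajectory length mismatch")
    return(drift_rate)
  }
  cbind((seq_len(n_frames) - 1L) * drift_rate[1],
        (seq_len(n_frames) - 1L) * drift_rate[2])
}

#' Fast localization-level simulation (skips raw frames)
#'
#' Applies a detection thinning and isotropic Gaussian localization jitter
#' directly to the true emitter positions, bypassing frame synthesis and
#' reconstruction.  Used to test quantification independently of the
#' localization code.
#'
#' @param truth A [make_ground_truth()] pattern.
#' @param precision_nm Localization precision (sd of the isotropic jitter).
#' @param detection_rate Probability that an emitter is detected at all.
#' @param mean_blinks Mean number of blinks per detected emitter (>= 1);
#'   blink count is 1 + Poisson(mean_blinks - 1).
#' @param n_frames Frames over which blinks are spread uniformly.
#' @param photons Photons recorded per localization.
#' @param seed Integer seed.
#' @return A localization table (`loc_table` data frame with columns
#'   `frame, x_nm, y_nm, photons, sigma_nm, bg_photons, channel, keep` and
#'   an `emitter_id` provenance column).
#' @export
simulate_localizations <- function(truth, precision_nm = 10,
                                   detection_rate = 1, mean_blinks = 1,
                                   n_frames = 1000L, photons = 1000,
                                   seed = 1L) {
  stopifnot(precision_nm >= 0, detection_rate > 0, detection_rate <= 1,
            mean_blinks >= 1)
  n <- nrow(truth$emitters)
  if (n == 0L) return(empty_loc_table())
  with_seed(seed, {
    detected <- which(runif(n) <= detection_rate)
    blinks <- 1L + rpois(length(detected), mean_blinks - 1)
    id <- rep.int(detected, blinks)
    m <- length(id)
    x <- truth$emitters[id, 1] + rnorm(m, 0, precision_nm)
    y <- truth$emitters[id, 2] + rnorm(m, 0, precision_nm)
    tab <- loc_table(
      frame = sample.int(n_frames, m, replace = TRUE) - 1L,
      x_nm = x, y_nm = y, photons = rep.int(photons, m),
      sigma_nm = rep.int(NA_real_, m), bg_photons = rep.int(0, m),
      channel = rep.int(0L, m), keep = rep.int(TRUE, m))
    tab$emitter_id <- id
    tab[order(tab$frame), , drop = FALSE]
  })
}

#' Simulate a raw blinking-emitter frame stack
#'
#' Each frame is `gain * Poisson(background + sum of on-emitter PSFs +
#' fiducials) + offset`, with the PSF integrated over pixel areas and the
#' cumulative stage drift applied to all true positions frame by frame.
#' Emitters outside the field of view raise a warning and are clipped from
#' rendering but retained in the truth records.
#'
#' @param truth A [make_ground_truth()] pattern.
#' @param acq An [acquisition_model()].
#' @return A list with `stack` (a [frame_stack()] in camera counts) and
#'   `truth_frames` (data frame: `emitter_id, frame, x_nm, y_nm, photons`;
#'   fiducials carry negative ids).
#' @export
simulate_stack <- function(truth, acq) {
  fov <- acq$fov_px
  p <- acq$camera_pixel
  bg <- resolve_background_field(acq$background_field, fov, p)
  drift <- drift_track(acq$drift_rate, acq$n_frames)
  em <- truth$emitters
  n_em <- nrow(em)
  fov_nm <- c(fov[2] * p, fov[1] * p)
  if (n_em > 0L && (any(em[, 1] < 0 | em[, 1] > fov_nm[1]) ||
                    any(em[, 2] < 0 | em[, 2] > fov_nm[2]))) {
    warning("emitters outside the field of view are clipped from rendering")
  }

  with_seed(acq$seed, {
    frames <- vector("list", acq$n_frames)
    rec <- vector("list", acq$n_frames)
    fid <- acq$fiducial_positions
    for (f in seq_len(acq$n_frames)) {
      expected <- bg
      on <- if (n_em > 0L) which(runif(n_em) <= acq$on_probability) else integer(0)
      ph <- switch(acq$photon_dist,
        constant  = rep.int(acq$photons_per_blink, length(on)),
        lognormal = rlnorm(length(on),
                           log(acq$photons_per_blink) - 0.3^2 / 2, 0.3))
      xs <- em[on, 1] + drift[f, 1]
      ys <- em[on, 2] + drift[f, 2]
      if (length(on) > 0L) {
        for (k in seq_along(on)) {
          patch <- psf_patch(xs[k], ys[k], ph[k], acq$psf_sigma, p, fov)
          if (!is.null(patch)) {
            expected[patch$rows, patch$cols] <-
              expected[patch$rows, patch$cols] + patch$img
          }
        }
      }
      fid_rec <- NULL
      if (!is.null(fid) && nrow(fid) > 0L) {
        fx <- fid[, 1] + drift[f, 1]
        fy <- fid[, 2] + drift[f, 2]
        for (k in seq_len(nrow(fid))) {
          patch <- psf_patch(fx[k], fy[k], acq$fiducial_photons,
                             acq$psf_sigma, p, fov)
          if (!is.null(patch)) {
            expected[patch$rows, patch$cols] <-
              expected[patch$rows, patch$cols] + patch$img
          }
        }
        fid_rec <- data.frame(emitter_id = -seq_len(nrow(fid)),
                              frame = f - 1L, x_nm = fx, y_nm = fy,
                              photons = acq$fiducial_photons)
      }
      photons_img <- if (acq$noise) {
        matrix(rpois(length(expected), expected), fov[1], fov[2])
      } else expected
      counts <- acq$gain * photons_img + acq$offset
      # digitize only the noisy path; noise-disabled stacks keep exact
      # expected values for photometric tests
      frames[[f]] <- if (acq$noise) round(counts) else counts
      rec[[f]] <- rbind(
        if (length(on) > 0L) data.frame(emitter_id = on, frame = f - 1L,
                                        x_nm = xs, y_nm = ys, photons = ph),
        fid_rec)
    }
    data <- array(unlist(frames), dim = c(fov[1], fov[2], acq$n_frames))
    list(
      stack = frame_stack(data, pixel_nm = p, gain = acq$gain,
                          offset = acq$offset, unit = "counts"),
      truth_frames = do.call(rbind, rec)
    )
  })
}
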