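# Emitter detection, neighbour deflation and closed-form sub-pixel fitting.
#
# Detection finds 8-connected local maxima above k*sqrt(background).
# Before fitting, the preliminary Gaussian model of every neighbouring
# candidate is subtracted from the target's region of interest (one pass,
# amplitude-only, brightest candidates first) so overlapping molecules can
# be fit individually without iterative multi-emitter least squares.  The
# centre is then estimated in a single step from the radial-symmetry
# condition on discrete intensity gradients: every gradient vector of an
# ideal spot points through the centre, so the centre is the weighted
# least-squares point of closest approach of all gradient lines
# (closed-form 2x2 solve; inverse-distance weighting).

#' Fitting and filtering configuration
#'
#' @param roi_radius Fit ROI radius in pixels (>= 2).
#' @param threshold_k Detection threshold in multiples of
#'   `sqrt(background)`.
#' @param neighbor_radius Deflation neighbour radius in pixels (default
#'   `2 * roi_radius`).
#' @param min_photons Minimum fitted photons for a valid molecule.
#' @param sigma_range Valid fitted width range as multiples of the PSF
#'   prior.
#' @param render_pixel_nm Render pixel size (nm).
#' @return A `fit_config` list.
#' @export
fit_config <- function(roi_radius = 3L, threshold_k = 3,
                       neighbor_radius = NULL, min_photons = 300,
                       sigma_range = c(0.5, 2.0), render_pixel_nm = 13) {
  if (roi_radius < 2L) stop("roi_radius must be >= 2")
  if (any(sigma_range <= 0) || diff(sigma_range) <= 0) {
    stop("sigma_range must be positive and increasing")
  }
  if (is.null(neighbor_radius)) neighbor_radius <- 2L * roi_radius
  structure(list(roi_radius = as.integer(roi_radius),
                 threshold_k = threshold_k,
                 neighbor_radius = neighbor_radius,
                 min_photons = min_photons, sigma_range = sigma_range,
                 render_pixel_nm = render_pixel_nm),
            class = "fit_config")
}

#' Detect candidate emitters in a background-corrected frame
#'
#' Finds 8-connected local maxima whose amplitude exceeds
#' `threshold_k * sqrt(lambda)` at that pixel.  Equal neighbouring maxima
#' are broken toward the smallest (row, col) in lexicographic order.
#'
#' @param frame Background-corrected photon matrix.
#' @param lambda Background model for the frame: scalar or matrix
#'   (photons/px), used only for the threshold.
#' @param config A [fit_config()].
#' @return Data frame of candidates (`row`, `col` 1-based pixel, `amp`
#'   photon amplitude, `bg` local background), sorted by amplitude
#'   descending.
#' @export
detect_candidates <- function(frame, lambda, config = fit_config()) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (!is.matrix(lambda)) lambda <- matrix(lambda, nr, nc)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- frame
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nb <- function(dr, dc) pad[2:(nr + 1L) + dr, 2:(nc + 1L) + dc]
  # earlier neighbours in (row, col) lexicographic scan need strict >
  is_max <- ctr > nb(-1L, -1L) & ctr > nb(-1L, 0L) & ctr > nb(-1L, 1L) &
    ctr > nb(0L, -1L) &
    ctr >= nb(0L, 1L) & ctr >= nb(1L, -1L) & ctr >= nb(1L, 0L) &
    ctr >= nb(1L, 1L)
  sel <- is_max & (ctr > config$threshold_k * sqrt(pmax(lambda, 0))) & (ctr > 0)
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(row = integer(), col = integer(),
                      amp = numeric(), bg = numeric()))
  }
  out <- data.frame(row = idx[, 1], col = idx[, 2],
                    amp = frame[idx], bg = lambda[idx])
  out[order(-out$amp, out$row, out$col), , drop = FALSE]
}

# Radial-symmetry centre estimate (single closed-form step) on an ROI.
# Returns (dx, dy) in pixels relative to the ROI centre pixel's centre;
# x rightward (columns), y downward (rows).
radial_center <- function(I) {
  ny <- nrow(I); nx <- ncol(I)
  # midpoint grid between pixel centres, coordinates relative to ROI centre
  xm_row <- seq(-(nx - 1) / 2 + 0.5, (nx - 1) / 2 - 0.5, by = 1)
  ym_col <- seq(-(ny - 1) / 2 + 0.5, (ny - 1) / 2 - 0.5, by = 1)
  xm <- matrix(xm_row, ny - 1L, nx - 1L, byrow = TRUE)
  ym <- matrix(ym_col, ny - 1L, nx - 1L)
  # intensity derivatives along the two 45-degree diagonals
  dIdu <- I[1:(ny - 1L), 2:nx] - I[2:ny, 1:(nx - 1L)]
  dIdv <- I[1:(ny - 1L), 1:(nx - 1L)] - I[2:ny, 2:nx]
  # 3x3 boxcar smoothing of the gradient fields (zero-padded)
  box3 <- function(m) {
    p <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
    p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    (p[1:nrow(m), 1:ncol(m)] + p[1:nrow(m), 2:(ncol(m) + 1L)] +
     p[1:nrow(m), 3:(ncol(m) + 2L)] +
     p[2:(nrow(m) + 1L), 1:ncol(m)] + p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] +
     p[2:(nrow(m) + 1L), 3:(ncol(m) + 2L)] +
     p[3:(nrow(m) + 2L), 1:ncol(m)] + p[3:(nrow(m) + 2L), 2:(ncol(m) + 1L)] +
     p[3:(nrow(m) + 2L), 3:(ncol(m) + 2L)]) / 9
  }
  fdu <- box3(dIdu)
  fdv <- box3(dIdv)
  dI2 <- fdu * fdu + fdv * fdv
  if (sum(dI2) <= 0) return(c(0, 0))
  # gradient-line slope in (x, y); the u,v axes are the image diagonals
  m <- -(fdv + fdu) / (fdu - fdv)
  m[!is.finite(m)] <- 1e12
  b <- ym - m * xm
  # inverse-distance weights about the gradient-magnitude centroid
  s <- sum(dI2)
  xc0 <- sum(dI2 * xm) / s
  yc0 <- sum(dI2 * ym) / s
  dcen <- sqrt((xm - xc0)^2 + (ym - yc0)^2)
  dcen[dcen < 1e-6] <- 1e-6
  w <- dI2 / dcen
  # weighted least-squares point nearest all lines y = m x + b
  wm2p1 <- w / (m * m + 1)
  sw <- sum(wm2p1)
  smmw <- sum(m * m * wm2p1)
  smw <- sum(m * wm2p1)
  smbw <- sum(m * b * wm2p1)
  sbw <- sum(b * wm2p1)
  det <- smw * smw - smmw * sw
  if (abs(det) < 1e-12) return(c(xc0, yc0))
  xc <- (smbw * sw - smw * sbw) / det
  yc <- (smbw * smw - smmw * sbw) / det
  c(xc, yc)
}

# Pixel-integrated Gaussian on an ROI grid, unit total photons.
# rows/cols are 1-based pixel indices; centre (x0, y0) in pixel units where
# pixel (i, j) spans [j-1, j) x [i-1, i).
integrated_gaussian <- function(rows, cols, x0, y0, sigma_px) {
  ex <- pnorm((cols - x0) / sigma_px) - pnorm((cols - 1 - x0) / sigma_px)
  ey <- pnorm((rows - y0) / sigma_px) - pnorm((rows - 1 - y0) / sigma_px)
  ey %o% ex
}

#' Deflate neighbouring candidates and fit sub-pixel positions
#'
#' For each candidate (brightest first) the preliminary Gaussian model of
#' every neighbouring candidate within `neighbor_radius` -- amplitude set
#' to the neighbour's observed peak, width to the PSF prior, centre at its
#' pixel centre -- is subtracted from the ROI, and the cleaned ROI is fit
#' in one step: centre by the radial-symmetry gradient condition, photons
#' as the cleaned-ROI sum, width from second moments.  Candidates whose
#' ROI is clipped by the frame edge are flagged `keep = FALSE`.
#'
#' @param frame Background-corrected photon matrix.
#' @param candidates Output of [detect_candidates()].
#' @param psf_sigma_px PSF-width prior in pixels.
#' @param config A [fit_config()].
#' @param pixel_nm Camera pixel size (nm), for the output coordinates.
#' @param frame0 0-based frame index recorded in the output.
#' @return A `loc_table` (positions in nm).
#' @export
deflate_and_fit <- function(frame, candidates, psf_sigma_px,
                            config = fit_config(), pixel_nm = 100,
                            frame0 = 0L) {
  n <- nrow(candidates)
  if (n == 0L) return(empty_loc_table())
  r <- config$roi_radius
  nr <- nrow(frame); nc <- ncol(frame)
  out <- vector("list", n)
  # peak amplitude of a unit-photon integrated Gaussian, to convert peak
  # amplitude to a photon estimate for the subtracted neighbour models
  peak_unit <- (pnorm(0.5 / psf_sigma_px) - pnorm(-0.5 / psf_sigma_px))^2
  for (k in seq_len(n)) {
    ri <- candidates$row[k]; ci <- candidates$col[k]
    edge <- (ri - r < 1L) || (ri + r > nr) || (ci - r < 1L) || (ci + r > nc)
    if (edge) {
      out[[k]] <- data.frame(
        frame = frame0, x_nm = (ci - 0.5) * pixel_nm,
        y_nm = (ri - 0.5) * pixel_nm, photons = candidates$amp[k],
        sigma_nm = NA_real_, bg_photons = candidates$bg[k],
        channel = 0L, keep = FALSE)
      next
    }
    rows <- (ri - r):(ri + r)
    cols <- (ci - r):(ci + r)
    roi <- frame[rows, cols]
    near <- which(abs(candidates$row - ri) <= config$neighbor_radius &
                  abs(candidates$col - ci) <= config$neighbor_radius)
    near <- setdiff(near, k)
    for (j in near) {
      amp_ph <- candidates$amp[j] / peak_unit
      roi <- roi - amp_ph * integrated_gaussian(
        rows, cols, candidates$col[j] - 0.5, candidates$row[j] - 0.5,
        psf_sigma_px)
    }
    ctr <- radial_center(roi)
    # clamp pathological fits to the ROI
    ctr <- clamp(ctr, -r, r)
    x_px <- (ci - 0.5) + ctr[1]
    y_px <- (ri - 0.5) + ctr[2]
    photons <- sum(roi)
    # width from second moments about the fitted centre (clipped ROI)
    pos <- pmax(roi, 0)
    tot <- sum(pos)
    if (tot > 0) {
      xs <- matrix(cols - 0.5, 2L * r + 1L, 2L * r + 1L, byrow = TRUE)
      ys <- matrix(rows - 0.5, 2L * r + 1L, 2L * r + 1L)
      vx <- sum(pos * (xs - x_px)^2) / tot
      vy <- sum(pos * (ys - y_px)^2) / tot
      sigma_px_hat <- sqrt((vx + vy) / 2)
    } else {
      sigma_px_hat <- NA_real_
    }
    out[[k]] <- data.frame(
      frame = frame0, x_nm = x_px * pixel_nm, y_nm = y_px * pixel_nm,
      photons = photons, sigma_nm = sigma_px_hat * pixel_nm,
      bg_photons = candidates$bg[k], channel = 0L, keep = TRUE)
  }
  as_loc_table(do.call(rbind, out))
}

#' Flag valid localizations
#'
#' `keep` is true when the fit was not edge-clipped, the fitted photons
#' reach `min_photons`, and the fitted width lies within `sigma_range`
#' times the PSF prior.  Rows are retained either way.
#'
#' @param table A `loc_table`.
#' @param config A [fit_config()].
#' @param psf_sigma_nm PSF-width prior in nm.
#' @return The table with updated `keep` flags.
#' @export
filter_localizations <- function(table, config, psf_sigma_nm) {
  lo <- config$sigma_range[1] * psf_sigma_nm
  hi <- config$sigma_range[2] * psf_sigma_nm
  keep <- table$keep &
    !is.na(table$photons) & table$photons >= config$min_photons &
    !is.na(table$sigma_nm) & table$sigma_nm >= lo & table$sigma_nm <= hi
  table$keep <- keep
  table
}

#' Render a localization table as a 2D count histogram
#'
#' Accumulates `keep = TRUE` molecules into bins of `render_pixel_nm`
#' (13 nm by default); bin (i, j) counts molecules with
#' `x in [(j-1)*p, j*p)` and `y in [(i-1)*p, i*p)` relative to the extent
#' origin.
#'
#' @param table A `loc_table`.
#' @param render_pixel_nm Render pixel size in nm.
#' @param extent `c(xmin, xmax, ymin, ymax)` in nm; default spans the data.
#' @return A [rendered_image()].
#' @export
render_localizations <- function(table, render_pixel_nm = 13, extent = NULL) {
  pts <- table[table$keep %in% TRUE, , drop = FALSE]
  if (is.null(extent)) {
    if (nrow(pts) == 0L) stop("empty extent: no kept molecules and no extent given")
    extent <- c(0, max(pts$x_nm) + render_pixel_nm,
                0, max(pts$y_nm) + render_pixel_nm)
  }
  if (extent[2] <= extent[1] || extent[4] <= extent[3]) stop("empty extent")
  ncol_px <- ceiling((extent[2] - extent[1]) / render_pixel_nm)
  nrow_px <- ceiling((extent[4] - extent[3]) / render_pixel_nm)
  counts <- matrix(0L, nrow_px, ncol_px)
  if (nrow(pts) > 0L) {
    cj <- floor((pts$x_nm - extent[1]) / render_pixel_nm) + 1L
    ri <- floor((pts$y_nm - extent[3]) / render_pixel_nm) + 1L
    ok <- cj >= 1L & cj <= ncol_px & ri >= 1L & ri <= nrow_px
    if (any(ok)) {
      tab <- table(factor(ri[ok], levels = seq_len(nrow_px)),
                   factor(cj[ok], levels = seq_len(ncol_px)))
      counts <- matrix(as.integer(tab), nrow_px, ncol_px)
    }
  }
  rendered_image(counts, pixel_nm = render_pixel_nm,
                 origin = c(extent[1], extent[3]))
}

#' Localize an entire background-corrected stack
#'
#' Runs [detect_candidates()] and [deflate_and_fit()] frame by frame and
#' applies [filter_localizations()].
#'
#' @param stack Background-corrected `frame_stack` in photons.
#' @param model The `background_model` used for the correction (supplies
#'   per-frame detection thresholds).
#' @param psf_sigma_nm PSF-width prior in nm.
#' @param config A [fit_config()].
#' @param verbose Report per-frame candidate counts.
#' @return A `loc_table` over all frames.
#' @export
localize_stack <- function(stack, model, psf_sigma_nm,
                           config = fit_config(), verbose = FALSE) {
  nf <- n_frames(stack)
  psf_px <- psf_sigma_nm / stack$pixel_nm
  tabs <- vector("list", nf)
  for (f in seq_len(nf)) {
    s <- frame_substack(model, f - 1L)
    cand <- detect_candidates(stack$data[, , f], model$lambda[[s]], config)
    tabs[[f]] <- deflate_and_fit(stack$data[, , f], cand, psf_px, config,
                                 pixel_nm = stack$pixel_nm, frame0 = f - 1L)
    if (verbose) {
      message(sprintf("frame %d: %d candidates, %d fits", f - 1L,
                      nrow(cand), nrow(tabs[[f]])))
    }
  }
  tab <- as_loc_table(do.call(rbind, tabs))
  filter_localizations(tab, config, psf_sigma_nm)
}

#' Cramer-Rao lower bound for the pixel-integrated Gaussian model
#'
#' Numerical Fisher information for the x (= y) coordinate of a
#' pixel-integrated Gaussian spot with constant Poisson background,
#' evaluated on a finite pixel grid.
#'
#' @param photons Expected signal photons.
#' @param bg Background photons per pixel.
#' @param sigma_px PSF sd in pixels.
#' @param roi_radius Half-size of the evaluation grid in pixels.
#' @return Bound on the localization sd, in pixels.
#' @export
crlb_sigma_px <- function(photons, bg, sigma_px, roi_radius = 6L) {
  g <- seq(-roi_radius, roi_radius)   # pixel index offsets; centre at 0.5 in-pixel
  x0 <- 0.5
  ex <- pnorm((g + 1 - x0) / sigma_px) - pnorm((g - x0) / sigma_px)
  dex <- -(dnorm((g + 1 - x0) / sigma_px) - dnorm((g - x0) / sigma_px)) / sigma_px
  mu <- photons * (ex %o% ex) + bg
  dmu_dx <- photons * (ex %o% dex)
  sqrt(1 / sum(dmu_dx^2 / mu))
}
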