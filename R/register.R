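# Fiducial-based drift correction and bead-based chromatic registration.

#' Estimate a drift trajectory from fiducial beads
#'
#' Each fiducial seed is tracked across frames by nearest-neighbour
#' linking within a gate (the search is anchored at the track's last known
#' position).  Per-frame drift is the mean over fiducials of the
#' displacement from each track's first observation; gaps are linearly
#' interpolated and the result is smoothed with a centred moving average.
#' The trajectory is re-anchored so frame 0 has zero drift.
#'
#' @param table A `loc_table` containing the fiducial localizations (other
#'   molecules may be present; the gate isolates the beads).
#' @param fiducial_seeds k x 2 matrix of approximate bead positions (nm).
#' @param gate_nm Linking gate radius (nm).
#' @param smooth_window Moving-average window in frames.
#' @param min_coverage Minimum fraction of frames a track must cover.
#' @return A `drift_trajectory`: data frame (`frame`, `dx_nm`, `dy_nm`)
#'   with the bead tracks attached as an attribute.
#' @export
estimate_drift <- function(table, fiducial_seeds, gate_nm = 500,
                           smooth_window = 10L, min_coverage = 0.5) {
  fiducial_seeds <- as.matrix(fiducial_seeds)
  frames <- 0:max(table$frame)
  nf <- length(frames)
  tracks <- list()
  for (k in seq_len(nrow(fiducial_seeds))) {
    pos <- matrix(NA_real_, nf, 2L)
    last <- fiducial_seeds[k, ]
    for (f in frames) {
      rows <- which(table$frame == f)
      if (length(rows) == 0L) next
      d2 <- (table$x_nm[rows] - last[1])^2 + (table$y_nm[rows] - last[2])^2
      j <- which.min(d2)
      if (d2[j] <= gate_nm^2) {
        pos[f + 1L, ] <- c(table$x_nm[rows[j]], table$y_nm[rows[j]])
        last <- pos[f + 1L, ]
      }
    }
    if (mean(!is.na(pos[, 1])) >= min_coverage) tracks[[length(tracks) + 1L]] <- pos
  }
  if (length(tracks) == 0L) {
    stop("no fiducial track covers >= ", round(100 * min_coverage),
         "% of frames")
  }
  disp <- lapply(tracks, function(p) {
    first <- p[which(!is.na(p[, 1]))[1], ]
    cbind(p[, 1] - first[1], p[, 2] - first[2])
  })
  dx <- rowMeans(do.call(cbind, lapply(disp, function(d) d[, 1])), na.rm = TRUE)
  dy <- rowMeans(do.call(cbind, lapply(disp, function(d) d[, 2])), na.rm = TRUE)
  fill <- function(v) {
    if (all(is.na(v))) stop("no fiducial observations at all")
    approx(x = frames[!is.na(v)], y = v[!is.na(v)], xout = frames,
           rule = 2)$y
  }
  dx <- moving_average(fill(dx), smooth_window)
  dy <- moving_average(fill(dy), smooth_window)
  out <- data.frame(frame = frames, dx_nm = dx - dx[1], dy_nm = dy - dy[1])
  attr(out, "tracks") <- tracks
  attr(out, "smooth_window") <- smooth_window
  class(out) <- c("drift_trajectory", "data.frame")
  out
}

# Local linear (Savitzky-Golay, order 1) smoothing over a sliding window.
# Near the edges the window is shifted, not shrunk, and the linear fit is
# evaluated at the target frame: unbiased for linear drift everywhere,
# including the trajectory endpoints.
moving_average <- function(v, window) {
  if (window <= 1L) return(v)
  n <- length(v)
  w <- min(window, n)
  h <- w %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- clamp(i - h, 1L, n - w + 1L)
    idx <- lo:(lo + w - 1L)
    t <- idx - i
    st <- sum(t); stt <- sum(t * t)
    den <- w * stt - st * st
    if (den == 0) return(mean(v[idx]))
    a <- (stt * sum(v[idx]) - st * sum(t * v[idx])) / den
    a
  }, 0)
}

#' Apply (or undo) a drift trajectory to a localization table
#'
#' Subtracts the per-frame drift from each molecule's position.
#'
#' @param table A `loc_table`.
#' @param trajectory A [estimate_drift()] trajectory covering all frames
#'   of `table`.
#' @param invert Add the drift back instead of removing it.
#' @return The corrected table.
#' @export
apply_drift <- function(table, trajectory, invert = FALSE) {
  idx <- match(table$frame, trajectory$frame)
  if (any(is.na(idx))) stop("frame outside trajectory coverage")
  s <- if (invert) 1 else -1
  table$x_nm <- table$x_nm + s * trajectory$dx_nm[idx]
  table$y_nm <- table$y_nm + s * trajectory$dy_nm[idx]
  table
}

# Mutual nearest-neighbour bead matching between two channels.
match_beads <- function(a, b, gate_nm = 500) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  nn_ab <- apply(d2, 1, which.min)
  nn_ba <- apply(d2, 2, which.min)
  keep <- which(nn_ba[nn_ab] == seq_len(nrow(a)) &
                d2[cbind(seq_len(nrow(a)), nn_ab)] <= gate_nm^2)
  cbind(a_idx = keep, b_idx = nn_ab[keep])
}

poly_design <- function(x, y, degree) {
  if (degree == 1L) cbind(1, x, y) else cbind(1, x, y, x^2, x * y, y^2)
}

#' Fit a chromatic transform from matched bead pairs
#'
#' Least-squares 2D polynomial (degree 1 or 2) mapping channel-B bead
#' coordinates into channel-A space.  Beads are matched by mutual nearest
#' neighbour within 500 nm.  Degree 2 requires at least 6 matched pairs
#' and falls back to degree 1 when fewer (but >= 3) are available.
#'
#' @param beads_A,beads_B Two-column matrices of bead positions (nm).
#' @param degree Polynomial degree, 1 or 2.
#' @return A `chromatic_transform`: coefficients (one column per output
#'   coordinate), degree, in-sample residual RMS (nm), bead count and the
#'   calibrated bounding box.
#' @export
fit_chromatic <- function(beads_A, beads_B, degree = 2L) {
  beads_A <- as.matrix(beads_A); beads_B <- as.matrix(beads_B)
  pairs <- match_beads(beads_A, beads_B)
  n <- nrow(pairs)
  need <- if (degree >= 2L) 6L else 3L
  if (n < 3L) stop("chromatic fit needs >= 3 matched bead pairs, got ", n)
  if (degree >= 2L && n < 6L) degree <- 1L
  a <- beads_A[pairs[, 1], , drop = FALSE]
  b <- beads_B[pairs[, 2], , drop = FALSE]
  X <- poly_design(b[, 1], b[, 2], degree)
  coefs <- qr.solve(X, a)
  resid <- a - X %*% coefs
  # one outlier-rejection pass: mismatched bead pairs (close bead doublets
  # swapped across channels) leave residuals far above the jitter scale
  rr <- sqrt(rowSums(resid^2))
  cut <- 5 * median(rr) + 1e-9
  good <- rr <= cut
  if (any(!good) && sum(good) >= ncol(X)) {
    a <- a[good, , drop = FALSE]
    X <- X[good, , drop = FALSE]
    n <- sum(good)
    coefs <- qr.solve(X, a)
    resid <- a - X %*% coefs
  }
  rms <- sqrt(mean(rowSums(resid^2)))
  structure(list(coefficients = coefs, degree = degree, residual_rms = rms,
                 n_beads = n,
                 bbox = c(range(b[, 1]), range(b[, 2]))),
            class = "chromatic_transform")
}

#' @export
print.chromatic_transform <- function(x, ...) {
  cat(sprintf("chromatic_transform: degree %d, %d beads, residual RMS %.2f nm\n",
              x$degree, x$n_beads, x$residual_rms))
  invisible(x)
}

#' Map coordinates through a chromatic transform
#'
#' @param transform A [fit_chromatic()] transform.
#' @param xy Two-column matrix of channel-B coordinates (nm).
#' @return Transformed coordinates in channel-A space.
#' @export
predict_chromatic <- function(transform, xy) {
  xy <- as.matrix(xy)
  poly_design(xy[, 1], xy[, 2], transform$degree) %*% transform$coefficients
}

#' Apply a chromatic transform to a localization table
#'
#' Rows of the given channel are mapped into the reference channel's
#' coordinate system; other rows are untouched.  A warning is raised when
#' coordinates fall far outside the calibrated field.
#'
#' @param table A `loc_table`.
#' @param transform A [fit_chromatic()] transform.
#' @param channel Channel id to transform (default 1).
#' @param margin_nm Extrapolation margin before warning.
#' @return The registered table.
#' @export
apply_chromatic <- function(table, transform, channel = 1L,
                            margin_nm = 1000) {
  rows <- which(table$channel == channel)
  if (length(rows) == 0L) return(table)
  xy <- cbind(table$x_nm[rows], table$y_nm[rows])
  bb <- transform$bbox
  if (any(xy[, 1] < bb[1] - margin_nm | xy[, 1] > bb[2] + margin_nm |
          xy[, 2] < bb[3] - margin_nm | xy[, 2] > bb[4] + margin_nm)) {
    warning("coordinates far outside the calibrated field; extrapolating")
  }
  mapped <- predict_chromatic(transform, xy)
  table$x_nm[rows] <- mapped[, 1]
  table$y_nm[rows] <- mapped[, 2]
  table
}
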