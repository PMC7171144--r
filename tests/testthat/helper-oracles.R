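# Shared fixtures and independent oracles used across the suite.

# Iterative least-squares fit of a pixel-integrated Gaussian (independent
# oracle for the closed-form gradient fit).  Returns (x0, y0) in pixel
# units; pixel (i, j) spans [j-1, j) x [i-1, i).
ls_fit_gaussian <- function(roi, sigma_px, fit_sigma = FALSE) {
  rows <- seq_len(nrow(roi)); cols <- seq_len(ncol(roi))
  obj <- function(p) {
    s <- if (fit_sigma) p[4] else sigma_px
    ey <- pnorm((rows - p[2]) / s) - pnorm((rows - 1 - p[2]) / s)
    ex <- pnorm((cols - p[1]) / s) - pnorm((cols - 1 - p[1]) / s)
    sum((roi - p[3] * (ey %o% ex))^2)
  }
  start <- c(ncol(roi) / 2, nrow(roi) / 2, sum(roi))
  if (fit_sigma) start <- c(start, sigma_px)
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  fit$par[1:2]
}

# Two-emitter joint least-squares oracle; returns a 2 x 2 matrix of
# centres sorted by x.
ls_fit_two_gaussians <- function(img, sigma_px) {
  rows <- seq_len(nrow(img)); cols <- seq_len(ncol(img))
  model1 <- function(x0, y0, N) {
    ey <- pnorm((rows - y0) / sigma_px) - pnorm((rows - 1 - y0) / sigma_px)
    ex <- pnorm((cols - x0) / sigma_px) - pnorm((cols - 1 - x0) / sigma_px)
    N * (ey %o% ex)
  }
  obj <- function(p) sum((img - model1(p[1], p[2], p[5]) -
                            model1(p[3], p[4], p[6]))^2)
  top <- order(img, decreasing = TRUE)[1:2]
  rc <- arrayInd(top, dim(img))
  start <- c(rc[1, 2] - 0.5, rc[1, 1] - 0.5, rc[2, 2] - 0.5, rc[2, 1] - 0.5,
             sum(img) / 2, sum(img) / 2)
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  ctrs <- rbind(fit$par[1:2], fit$par[3:4])
  ctrs[order(ctrs[, 1]), , drop = FALSE]
}

# Greedy per-frame matching of localizations to truth records within a
# gate; returns recall and false-discovery rate.
match_truth <- function(locs, truth, gate_nm = 50) {
  tp <- 0L; fp <- 0L
  for (f in unique(locs$frame)) {
    L <- locs[locs$frame == f, , drop = FALSE]
    TT <- truth[truth$frame == f, , drop = FALSE]
    if (nrow(TT) == 0L) { fp <- fp + nrow(L); next }
    used <- rep(FALSE, nrow(TT))
    for (i in seq_len(nrow(L))) {
      d <- sqrt((TT$x_nm - L$x_nm[i])^2 + (TT$y_nm - L$y_nm[i])^2)
      d[used] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= gate_nm) {
        used[j] <- TRUE; tp <- tp + 1L
      } else {
        fp <- fp + 1L
      }
    }
  }
  c(recall = tp / nrow(truth), fdr = fp / max(tp + fp, 1L))
}

# Thomas process in a square window [0, W)^2: Poisson parents at intensity
# rho_p (with a 4-sigma guard margin), Poisson(mu) daughters with
# isotropic Gaussian scatter sigma.
sim_thomas <- function(rho_p, sigma, mu, W, seed) {
  set.seed(seed)
  m <- 4 * sigma
  np <- rpois(1, rho_p * (W + 2 * m)^2)
  px <- runif(np, -m, W + m); py <- runif(np, -m, W + m)
  nd <- rpois(np, mu)
  x <- rep(px, nd) + rnorm(sum(nd), 0, sigma)
  y <- rep(py, nd) + rnorm(sum(nd), 0, sigma)
  ok <- x >= 0 & x < W & y >= 0 & y < W
  cbind(x[ok], y[ok])
}

# Fiducial-bead localization table: beads at fixed positions, per-frame
# drift, isotropic jitter.
bead_table <- function(beads, n_frames, drift_per_frame = c(0, 0),
                       precision_nm = 5, drop_frames = NULL, seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(0:(n_frames - 1L), function(f) {
    if (f %in% drop_frames) return(NULL)
    k <- nrow(beads)
    data.frame(frame = f,
               x_nm = beads[, 1] + drift_per_frame[1] * f + rnorm(k, 0, precision_nm),
               y_nm = beads[, 2] + drift_per_frame[2] * f + rnorm(k, 0, precision_nm),
               photons = 5000, sigma_nm = 130, bg_photons = 0,
               channel = 0L, keep = TRUE)
  }))
  nanostorm:::as_loc_table(rows)
}

# Pixel-integrated Gaussian image (truth model shared with the package by
# construction; used to synthesise fitting inputs).
psf_image <- function(nrow_px, ncol_px, x0, y0, sigma_px, photons) {
  rows <- seq_len(nrow_px); cols <- seq_len(ncol_px)
  ey <- pnorm((rows - y0) / sigma_px) - pnorm((rows - 1 - y0) / sigma_px)
  ex <- pnorm((cols - x0) / sigma_px) - pnorm((cols - 1 - x0) / sigma_px)
  photons * (ey %o% ex)
}
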