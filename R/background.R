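# Background estimation from per-pixel temporal minima.
#
# Tissue SMLM stacks carry a strong, slowly varying autofluorescent
# background.  Over a substack short enough that the background is quasi-
# static (default 100 frames), the per-pixel temporal minimum is an order
# statistic of the background alone whenever the pixel is emitter-free in
# at least one frame.  Modelling the Poisson(lambda) background with its
# Gaussian approximation (mean lambda, sd sqrt(lambda)), the expected
# minimum of N frames is lambda + d_N * sqrt(lambda), where d_N < 0 is the
# expected minimum of N standard normal draws.  Inverting that relation on
# the observed minimum m gives the estimator
#   sqrt(lambda_hat) = (|d_N| + sqrt(d_N^2 + 4 m)) / 2.

#' Convert a counts stack to photon units
#'
#' `photons = max(0, (counts - offset) / gain)`; values below the offset
#' clip to zero because downstream detection assumes non-negative
#' intensities.
#'
#' @param stack A `frame_stack` in counts.
#' @return The stack in photon units.
#' @export
counts_to_photons <- function(stack) {
  if (stack$unit != "counts") {
    stop("stack already in photon units (double conversion guard)")
  }
  ph <- pmax((stack$data - stack$offset) / stack$gain, 0)
  frame_stack(ph, pixel_nm = stack$pixel_nm, gain = stack$gain,
              offset = stack$offset, unit = "photons")
}

#' Expected minimum of N standard normal draws
#'
#' Blom's approximation `-qnorm((N - 0.375) / (N + 0.25))` by default;
#' `method = "mc"` estimates it by Monte Carlo (useful as a cross-check).
#'
#' @param N Number of draws (>= 1).
#' @param method `"blom"` or `"mc"`.
#' @param n_mc Monte-Carlo replicates.
#' @return The (negative) expected minimum; 0 for N = 1 under `"blom"` is
#'   replaced by the exact value 0.
#' @export
expected_min_normal <- function(N, method = c("blom", "mc"), n_mc = 20000L) {
  method <- match.arg(method)
  if (N == 1L) return(0)
  if (method == "blom") {
    -qnorm((N - 0.375) / (N + 0.25))
  } else {
    mean(vapply(seq_len(n_mc), function(i) min(rnorm(N)), 0))
  }
}

substack_bounds <- function(n, N) {
  if (n <= N) return(cbind(start = 1L, end = n))
  n_full <- n %/% N
  starts <- (seq_len(n_full) - 1L) * N + 1L
  ends <- starts + N - 1L
  if (n %% N > 0L) {
    starts <- c(starts, n_full * N + 1L)
    ends <- c(ends, n)
  }
  cbind(start = starts, end = ends)
}

# Invert m = lambda - |d|*sqrt(lambda) for lambda >= 0.
invert_min_relation <- function(m, d_abs) {
  ((d_abs + sqrt(d_abs^2 + 4 * pmax(m, 0))) / 2)^2
}

#' Estimate the per-pixel background of a photon stack
#'
#' Segments the stack into substacks of `N` frames (trailing frames form a
#' final shorter substack with its own order-statistics coefficient),
#' takes the per-pixel temporal minimum of each substack, and inverts the
#' expected-minimum relation of the Gaussian-approximated Poisson
#' background.  Pixels whose estimate exceeds their temporal median --
#' the signature of an always-on emitter such as a fiducial bead, whose
#' minimum is not background -- are capped at the substack's per-pixel
#' 10th-percentile temporal value.
#'
#' @param stack A `frame_stack` in photon units.
#' @param N Substack length in frames (default 100, >= 2).
#' @return A `background_model`: list with `lambda` (list of per-substack
#'   matrices), `bounds` (substack frame ranges, 1-based), `d_N` per
#'   substack, and `N`.
#' @export
estimate_background <- function(stack, N = 100L) {
  if (stack$unit != "photons") stop("estimate_background needs photon units")
  N <- as.integer(N)
  if (N < 2L) stop("substack length N must be >= 2")
  nf <- n_frames(stack)
  if (nf < 1L) stop("empty stack")
  bounds <- substack_bounds(nf, as.integer(N))
  lambda <- vector("list", nrow(bounds))
  d_N <- numeric(nrow(bounds))
  for (s in seq_len(nrow(bounds))) {
    idx <- bounds[s, 1]:bounds[s, 2]
    sub <- stack$data[, , idx, drop = FALSE]
    d <- expected_min_normal(length(idx))
    m <- apply(sub, c(1, 2), min)
    lam <- invert_min_relation(m, abs(d))
    if (length(idx) >= 3L) {
      # guard against pixels whose minimum is not background (always-on
      # emitters such as fiducial beads): an estimate far above the
      # temporal median is inconsistent with a Poisson background whose
      # minimum was observed; cap it at the 10th-percentile value
      med <- apply(sub, c(1, 2), median)
      q10 <- apply(sub, c(1, 2), quantile, probs = 0.1, names = FALSE)
      contaminated <- lam > med + 3 * sqrt(med + 1)
      lam[contaminated] <- q10[contaminated]
    }
    lambda[[s]] <- lam
    d_N[s] <- d
  }
  structure(list(lambda = lambda, bounds = bounds, d_N = d_N,
                 N = as.integer(N)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: %d substack(s) of <=%d frames, mean lambda %.2f\n",
              length(x$lambda), x$N, mean(unlist(x$lambda))))
  invisible(x)
}

# Substack index for each 0-based frame number.
frame_substack <- function(model, frame0) {
  f <- frame0 + 1L
  idx <- findInterval(f, model$bounds[, "start"])
  if (any(f < 1L) || any(f > max(model$bounds[, "end"]))) {
    stop("frame outside background model coverage")
  }
  idx
}

#' Subtract an estimated background from a photon stack
#'
#' `corrected = max(0, photons - lambda_hat)` using the frame's substack
#' model.
#'
#' @param stack A `frame_stack` in photon units.
#' @param model A `background_model` covering every frame.
#' @return The corrected `frame_stack`.
#' @export
subtract_background <- function(stack, model) {
  if (stack$unit != "photons") stop("subtract_background needs photon units")
  d <- dim(stack$data)
  if (!all(d[1:2] == dim(model$lambda[[1]]))) {
    stop("background model shape does not match stack")
  }
  if (max(model$bounds[, "end"]) < d[3]) {
    stop("background model does not cover every frame")
  }
  out <- stack$data
  for (s in seq_len(nrow(model$bounds))) {
    idx <- model$bounds[s, 1]:min(model$bounds[s, 2], d[3])
    lam <- model$lambda[[s]]
    for (f in idx) out[, , f] <- pmax(0, out[, , f] - lam)
  }
  frame_stack(out, pixel_nm = stack$pixel_nm, gain = stack$gain,
              offset = stack$offset, unit = "photons")
}
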