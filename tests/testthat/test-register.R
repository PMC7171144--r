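beads3 <- cbind(c(1000, 5000, 3000), c(1000, 2000, 5000))

test_that("drift estimation recovers null, linear and gappy trajectories", {
  # zero drift: trajectory stays within the noise bound 3 * sd / sqrt(k)
  tab0 <- bead_table(beads3, 100, c(0, 0), precision_nm = 5, seed = 1)
  tr0 <- estimate_drift(tab0, beads3)
  bound <- 3 * 5 / sqrt(3) + 3 * 5 / sqrt(3)  # anchor + frame noise, unsmoothed worst case
  expect_lt(max(abs(c(tr0$dx_nm, tr0$dy_nm))), bound)
  expect_equal(c(tr0$dx_nm[1], tr0$dy_nm[1]), c(0, 0))

  # linear drift 2 nm/frame over 100 frames: endpoint within 5 nm RMS
  # across replicates
  ep <- vapply(1:6, function(s) {
    tab <- bead_table(beads3, 100, c(2, 0), precision_nm = 5, seed = s)
    tr <- estimate_drift(tab, beads3)
    (tr$dx_nm[100] - 198)^2 + tr$dy_nm[100]^2
  }, 0)
  expect_lt(sqrt(mean(ep)), 5)

  # missing frames 40..60: interpolation keeps the trajectory defined
  tabg <- bead_table(beads3, 100, c(2, 0), precision_nm = 2,
                     drop_frames = 40:60, seed = 3)
  trg <- estimate_drift(tabg, beads3)
  expect_equal(nrow(trg), 100)
  expect_true(all(is.finite(trg$dx_nm)))
  expect_lt(max(abs(diff(trg$dx_nm))), 10)   # no jumps across the gap

  # beads localized in only 10% of frames: no track long enough
  lost <- tab0
  lost$x_nm[lost$frame >= 10] <- lost$x_nm[lost$frame >= 10] + 1e5
  expect_error(estimate_drift(lost, beads3), "fiducial")
})

test_that("drift application is exact and invertible", {
  tab <- bead_table(beads3, 50, c(2, 1), precision_nm = 0, seed = 2)
  tr <- estimate_drift(tab, beads3, smooth_window = 1L)
  zero <- tr; zero$dx_nm[] <- 0; zero$dy_nm[] <- 0
  expect_equal(apply_drift(tab, zero), tab)
  # apply then un-apply restores the table
  round_trip <- apply_drift(apply_drift(tab, tr), tr, invert = TRUE)
  expect_equal(round_trip$x_nm, tab$x_nm)
  # corrected noiseless beads collapse onto their first-frame positions
  corr <- apply_drift(tab, tr)
  for (k in 1:3) {
    xk <- corr$x_nm[seq(k, nrow(corr), by = 3)]
    expect_lt(max(abs(xk - xk[1])), 1e-9)
  }
  # drift correction reduces per-fiducial positional variance
  tabn <- bead_table(beads3, 100, c(2, 0), precision_nm = 5, seed = 4)
  trn <- estimate_drift(tabn, beads3)
  corrn <- apply_drift(tabn, trn)
  v_before <- var(tabn$x_nm[seq(1, nrow(tabn), by = 3)])
  v_after <- var(corrn$x_nm[seq(1, nrow(corrn), by = 3)])
  expect_lt(v_after, v_before)
  # frames outside coverage rejected
  bad <- tabn; bad$frame[1] <- 500L
  expect_error(apply_drift(bad, trn), "outside")
})

test_that("chromatic transforms recover identity, shift and affine maps", {
  set.seed(5)
  A <- cbind(runif(20, 0, 40000), runif(20, 0, 40000))

  # identity: zero residual, identity mapping
  tf_id <- fit_chromatic(A, A, degree = 1)
  expect_lt(tf_id$residual_rms, 1e-6)
  expect_equal(predict_chromatic(tf_id, A), A, tolerance = 1e-6)

  # too few beads
  expect_error(fit_chromatic(A[1:2, ], A[1:2, ], degree = 1), ">= 3")

  # known affine with jitter: recovered within ~2 nm RMS over the field
  # (the least-squares floor at 20 beads and 3 nm noise)
  B <- A * 1.002 + 40 + matrix(rnorm(40, 0, 3), 20, 2)
  tf <- fit_chromatic(A, B, degree = 1)
  grid <- as.matrix(expand.grid(seq(2000, 38000, 4000),
                                seq(2000, 38000, 4000)))
  rec <- predict_chromatic(tf, grid * 1.002 + 40)
  expect_lt(sqrt(mean(rowSums((rec - grid)^2))), 3)

  # leave-one-out residual within 2x in-sample residual
  loo <- vapply(1:20, function(i) {
    tfi <- fit_chromatic(A[-i, ], B[-i, ], degree = 1)
    sqrt(sum((predict_chromatic(tfi, B[i, , drop = FALSE]) - A[i, ])^2))
  }, 0)
  expect_lt(sqrt(mean(loo^2)), 2 * max(tf$residual_rms, 3))
})

test_that("chromatic application targets one channel and inverts numerically", {
  set.seed(6)
  A <- cbind(runif(12, 0, 20000), runif(12, 0, 20000))
  B <- A; B[, 1] <- B[, 1] + 40        # pure 40 nm x-shift
  tf <- fit_chromatic(A, B, degree = 1)
  tab <- loc_table(frame = rep(0L, 4), x_nm = c(100, 200, 300, 400),
                   y_nm = rep(1000, 4), photons = rep(1000, 4),
                   sigma_nm = rep(130, 4), bg_photons = rep(0, 4),
                   channel = c(0L, 1L, 1L, 0L), keep = rep(TRUE, 4))
  out <- suppressWarnings(apply_chromatic(tab, tf, channel = 1L))
  expect_equal(out$x_nm[c(2, 3)], c(160, 260), tolerance = 1e-6)
  expect_equal(out$x_nm[c(1, 4)], c(100, 400))   # reference channel untouched

  # numerical inverse: fitting the reverse map and composing is < 0.5 nm
  tf_inv <- fit_chromatic(B, A, degree = 1)
  round_trip <- predict_chromatic(tf_inv, predict_chromatic(tf, B))
  expect_lt(max(sqrt(rowSums((round_trip - B)^2))), 0.5)
})
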