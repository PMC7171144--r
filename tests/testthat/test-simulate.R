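test_that("ground truth generation honours counts, spread and determinism", {
  # no-cluster limit: pure uniform background points inside the polygon
  gt0 <- make_ground_truth(0, background_points = 100, seed = 3)
  expect_equal(nrow(gt0$emitters), 100)
  expect_true(all(nanostorm:::points_in_polygon(
    gt0$emitters[, 1], gt0$emitters[, 2], gt0$nucleus)))

  # clustered pattern: emitter count and per-axis spread
  gt <- make_ground_truth(10, cluster_sigma = 30, points_per_cluster = 50,
                          background_points = 0, seed = 1)
  expect_equal(nrow(gt$emitters), 500)
  dev <- gt$emitters - gt$cluster_centers[gt$cluster_id, ]
  expect_equal(sd(c(dev)), 30, tolerance = 0.1)

  # determinism: identical seeds give identical point lists
  gt2 <- make_ground_truth(10, cluster_sigma = 30, points_per_cluster = 50,
                           background_points = 0, seed = 1)
  expect_identical(gt$emitters, gt2$emitters)
  expect_false(identical(
    gt$emitters,
    make_ground_truth(10, 30, 50, background_points = 0, seed = 2)$emitters))

  # degenerate polygon rejected
  expect_error(make_ground_truth(1, nucleus = cbind(c(0, 1, 2), c(0, 1, 2))),
               "degenerate")
})

test_that("localization-level simulation obeys its closed-form statistics", {
  gt <- make_ground_truth(5, 40, 200, background_points = 0, seed = 5)

  # noiseless identity
  t0 <- simulate_localizations(gt, precision_nm = 0, detection_rate = 1,
                               seed = 2)
  expect_equal(nrow(t0), 1000)
  expect_equal(sort(t0$x_nm), sort(gt$emitters[, 1]))

  # Rayleigh mean displacement: sigma * sqrt(pi / 2)
  t1 <- simulate_localizations(gt, precision_nm = 10, detection_rate = 1,
                               seed = 3)
  disp <- sqrt((t1$x_nm - gt$emitters[t1$emitter_id, 1])^2 +
               (t1$y_nm - gt$emitters[t1$emitter_id, 2])^2)
  expect_equal(mean(disp), 10 * sqrt(pi / 2), tolerance = 0.05)

  # binomial detection thinning: ~500 of 1000 within a generous CI
  t2 <- simulate_localizations(gt, precision_nm = 0, detection_rate = 0.5,
                               seed = 4)
  expect_lt(abs(nrow(t2) - 500), 4 * sqrt(1000 * 0.25))

  # empty truth is an empty table, not an error
  gte <- make_ground_truth(0, background_points = 0, seed = 1)
  expect_equal(nrow(simulate_localizations(gte, 10, 1, seed = 1)), 0)
})

test_that("frame-stack simulation reproduces expected photon images", {
  nucleus <- circle_polygon(c(1600, 1600), 1200)

  # background-only: per-pixel temporal mean approaches the background
  gt0 <- make_ground_truth(0, background_points = 0, nucleus = nucleus,
                           seed = 1)
  acq <- acquisition_model(n_frames = 200L, fov_px = c(16L, 16L),
                           background_field = 7, gain = 1, offset = 0,
                           seed = 2)
  ss <- simulate_stack(gt0, acq)
  tm <- apply(ss$stack$data, c(1, 2), mean)
  expect_equal(mean(tm), 7, tolerance = 0.02)
  # Poisson dispersion: variance/mean within [0.9, 1.1] over >= 1e4 samples
  vm <- var(c(ss$stack$data)) / mean(ss$stack$data)
  expect_gt(vm, 0.9); expect_lt(vm, 1.1)

  # noise-disabled single always-on emitter matches the direct PSF
  # integral and conserves photons to 0.1%
  gt1 <- make_ground_truth(0, background_points = 0, nucleus = nucleus,
                           seed = 1)
  gt1$emitters <- matrix(c(1553, 1621), 1, 2)
  acq1 <- acquisition_model(n_frames = 1L, fov_px = c(32L, 32L),
                            background_field = 0, gain = 1, offset = 0,
                            on_probability = 1, photons_per_blink = 1000,
                            psf_sigma = 130, camera_pixel = 100,
                            noise = FALSE, seed = 3)
  ss1 <- simulate_stack(gt1, acq1)
  direct <- psf_image(32, 32, 1553 / 100, 1621 / 100, 1.3, 1000)
  # identical inside the rendered window; < 1e-3 photons absolute beyond
  # its 4 sigma truncation
  expect_lt(max(abs(ss1$stack$data[, , 1] - direct)), 1e-3)
  expect_equal(sum(ss1$stack$data), 1000, tolerance = 1e-3)

  # linear drift moves the true fiducial position by rate * (frames - 1)
  acq2 <- acquisition_model(n_frames = 100L, fov_px = c(32L, 32L),
                            background_field = 0, drift_rate = c(2, 0),
                            fiducial_positions = matrix(c(1600, 1600), 1),
                            noise = FALSE, seed = 4)
  ss2 <- simulate_stack(gt0, acq2)
  fid <- ss2$truth_frames[ss2$truth_frames$emitter_id < 0, ]
  expect_equal(fid$x_nm[fid$frame == 99] - fid$x_nm[fid$frame == 0], 198)

  # identical seeds give bit-identical stacks
  ss3 <- simulate_stack(gt0, acq)
  expect_identical(ss$stack$data, ss3$stack$data)
})

test_that("compaction presets fragment at fixed total localization count", {
  tot <- vapply(c("normal", "early", "tumor"), function(p) {
    nrow(chromatin_preset(p, seed = 1)$emitters)
  }, 0)
  expect_true(length(unique(tot)) == 1L)
  ncl <- vapply(c("normal", "early", "tumor"), function(p) {
    nrow(chromatin_preset(p, seed = 1)$cluster_centers)
  }, 0)
  expect_true(all(diff(ncl) > 0))
  sig <- vapply(c("normal", "early", "tumor"), function(p) {
    chromatin_preset(p, seed = 1)$cluster_sigma[1]
  }, 0)
  expect_true(all(diff(sig) < 0))
})
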