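test_that("3D background removal flattens constants and smooth gradients", {
  v <- volume3d(array(7, c(20, 20, 10)), c(250, 250, 250))
  vc <- remove_background_3d(v, 2000)
  expect_true(all(vc$data == 0))
  expect_equal(vc$background_level, 7)
  expect_error(remove_background_3d(v, 100), "smaller than one voxel")

  # bright compact object on a smooth gradient: gradient removed, object
  # contrast preserved
  d <- c(32, 32, 12)
  grad <- array(rep(seq(10, 30, length.out = d[2]), each = d[1]), d)
  obj <- array(0, d); obj[14:18, 14:18, 5:8] <- 100
  v2 <- volume3d(grad + obj, c(250, 250, 250))
  vc2 <- remove_background_3d(v2, 2500)
  outside <- obj == 0
  expect_lt(mean(vc2$data[outside]), 0.05 * mean(grad))
  expect_equal(mean(vc2$data[obj > 0]), 100, tolerance = 0.1)
})

test_that("radial-gradient segmentation recovers phantom geometry", {
  # solid ellipsoid: border within 1 voxel of truth on >= 95% of rays
  d <- c(40L, 40L, 24L)
  ctr <- (d + 1) / 2
  semi <- c(14, 10, 8)                   # (rows, cols, z)
  ii <- slice.index(array(0, d), 1); jj <- slice.index(array(0, d), 2)
  kk <- slice.index(array(0, d), 3)
  inside <- ((ii - ctr[1]) / semi[1])^2 + ((jj - ctr[2]) / semi[2])^2 +
    ((kk - ctr[3]) / semi[3])^2 <= 1
  vol <- volume3d(array(100 * inside, d), c(250, 250, 250))
  nuc <- segment_nucleus_3d(vol, seed = c(ctr[2], ctr[1]), n_rays = 120)
  expect_equal(nuc$z_peak, ctr[3], tolerance = 1)
  b <- nuc$borders[[round(ctr[3])]]
  th <- atan2(b[, 2] - ctr[1], b[, 1] - ctr[2])
  r_est <- sqrt((b[, 1] - ctr[2])^2 + (b[, 2] - ctr[1])^2)
  r_true <- 1 / sqrt((cos(th) / semi[2])^2 + (sin(th) / semi[1])^2)
  expect_gte(mean(abs(r_est - r_true) <= 1), 0.95)

  # sphere: segmented volume within 5% of (4/3) pi r^3
  ph <- sphere_phantom(radius_nm = 3000, dim_vox = c(40L, 40L, 40L))
  nuc2 <- segment_nucleus_3d(ph, seed = c(20, 20), n_rays = 180)
  truth <- attr(ph, "truth")
  expect_equal(nuc2$volume_nm3, truth$volume_nm3, tolerance = 0.05)

  # scaling invariance: borders do not move under global intensity
  # scaling (up to float ties between equal gradient samples)
  ph2 <- ph; ph2$data <- ph2$data * 7
  nuc3 <- segment_nucleus_3d(ph2, seed = c(20, 20), n_rays = 180)
  expect_equal(nuc3$volume_nm3, nuc2$volume_nm3, tolerance = 0.005)

  # seed on empty background errors
  empty <- volume3d(array(0, c(16, 16, 8)), c(250, 250, 250))
  expect_error(segment_nucleus_3d(empty, seed = c(4, 4)), "signal|gradient")
  expect_error(segment_nucleus_3d(ph, seed = c(500, 4)), "outside")
})

test_that("occupancy thresholds at three root-background and is monotone", {
  vol <- volume3d(array(0, c(20, 20, 10)), c(250, 250, 250))
  vol$background_level <- 4
  mask <- array(TRUE, c(20, 20, 10))
  expect_equal(dna_occupancy(vol, mask), 0)          # all below threshold
  vol$data[, 1:10, ] <- 100                          # exactly half above
  expect_equal(dna_occupancy(vol, mask), 0.5)
  # threshold is 3 sqrt(bg): intensity 6 is not above, 6 + eps is
  vol2 <- volume3d(array(6, c(4, 4, 4)), c(1, 1, 1))
  vol2$background_level <- 4
  expect_equal(dna_occupancy(vol2, array(TRUE, c(4, 4, 4))), 0)
  vol2$data[] <- 6 + 1e-9
  expect_equal(dna_occupancy(vol2, array(TRUE, c(4, 4, 4))), 1)
  # monotone non-increasing in the threshold multiplier
  set.seed(13)
  vol3 <- volume3d(array(rexp(4000, 1 / 10), c(20, 20, 10)), c(1, 1, 1))
  vol3$background_level <- 4
  occ <- vapply(c(1, 2, 3, 4), function(k)
    dna_occupancy(vol3, mask, k = k), 0)
  expect_true(all(diff(occ) <= 0))
  # zero background with signal present is an error
  vol$background_level <- 0
  expect_error(dna_occupancy(vol, mask), "background")
})

test_that("foci intensities are recovered and ordered", {
  d <- c(24, 24, 12)
  data <- array(0, d)
  data[4:8, 4:8, 4:8] <- 50              # 125 voxels at intensity 50
  data[14:18, 14:18, 4:8] <- 120
  vol <- volume3d(data, c(250, 250, 250))
  vol$background_level <- 1
  mask <- array(TRUE, d)
  fi <- foci_intensity(vol, mask, condensed_quantile = 0, min_vox = 50)
  expect_equal(length(fi), 2L)
  expect_equal(fi, c(50, 120))           # sorted, means exact
  # no foci above threshold: empty result
  expect_equal(length(foci_intensity(volume3d(array(0, d), c(1, 1, 1)),
                                     mask)), 0L)
})

test_that("decompaction raises occupancy and dims focus intensity", {
  res <- lapply(c("normal", "decompact"), function(p) {
    ph <- nucleus_phantom_3d(p, seed = 2)
    tr <- attr(ph, "truth")
    pc <- remove_background_3d(ph, 4000)
    occ <- dna_occupancy(pc, tr$inside, background = tr$background)
    fi <- foci_intensity(pc, tr$inside, background = tr$background,
                         min_vox = 20)
    list(occ = occ, fi = mean(fi))
  })
  expect_gt(res[[2]]$occ, res[[1]]$occ)
  expect_lt(res[[2]]$fi, res[[1]]$fi)
})
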