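test_that("candidate detection matches a brute-force local-maxima scan", {
  cfg <- fit_config()
  # blank frame: nothing
  expect_equal(nrow(detect_candidates(matrix(0, 16, 16), 10, cfg)), 0L)

  # one bright spot on lambda = 10: exactly one candidate, correct pixel
  frame <- psf_image(16, 16, 8.5, 6.5, 1.3, 1000)
  cand <- detect_candidates(frame, 10, cfg)
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$row, cand$col), c(7L, 9L))

  # two spots 10 px apart: brute-force oracle over all pixels agrees
  frame2 <- psf_image(24, 24, 6.5, 11.5, 1.3, 1000) +
    psf_image(24, 24, 16.5, 11.5, 1.3, 800)
  cand2 <- detect_candidates(frame2, 10, cfg)
  brute <- 0L
  for (i in 2:23) for (j in 2:23) {
    v <- frame2[i, j]
    nb <- frame2[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v == max(nb) && sum(nb == v) == 1L && v > 3 * sqrt(10)) {
      brute <- brute + 1L
    }
  }
  expect_equal(nrow(cand2), brute)
  expect_equal(nrow(cand2), 2L)
  # sorted by amplitude descending
  expect_true(all(diff(cand2$amp) <= 0))
})

test_that("gradient fit matches truth and the least-squares oracle", {
  sigma <- 1.3
  # exactly centred spot: symmetric, sub-1e-6 px
  roi <- psf_image(7, 7, 3.5, 3.5, sigma, 1000)
  ctr <- nanostorm:::radial_center(roi)
  expect_lt(max(abs(ctr)), 1e-6)

  # offset spot: within 0.02 px of truth and of the iterative LS oracle
  roi2 <- psf_image(9, 9, 4.5 + 0.30, 4.5 - 0.20, sigma, 1000)
  ctr2 <- nanostorm:::radial_center(roi2) + 4.5
  expect_lt(abs(ctr2[1] - 4.80), 0.02)
  expect_lt(abs(ctr2[2] - 4.30), 0.02)
  ls <- ls_fit_gaussian(roi2, sigma)
  expect_lt(max(abs(ctr2 - ls)), 0.02)
})

test_that("deflation restores overlapping emitters", {
  sigma <- 1.3
  cfg <- fit_config()
  x1 <- 5.3; x2 <- 9.3; y0 <- 7.6
  frame <- psf_image(15, 15, x1, y0, sigma, 1000) +
    psf_image(15, 15, x2, y0, sigma, 1000)
  cand <- detect_candidates(frame, 0, cfg)
  expect_equal(nrow(cand), 2L)
  fit <- deflate_and_fit(frame, cand, sigma, cfg, pixel_nm = 1)
  xs <- sort(fit$x_nm)
  expect_lt(abs(xs[1] - x1), 0.1)
  expect_lt(abs(xs[2] - x2), 0.1)
  expect_lt(max(abs(sort(fit$y_nm) - y0)), 0.1)
  # the two-emitter joint LS oracle agrees with the deflated fits
  ls <- ls_fit_two_gaussians(frame, sigma)
  expect_lt(max(abs(xs - ls[, 1])), 0.1)

  # without deflation the single-emitter fit is pulled by the neighbour
  fit0 <- deflate_and_fit(frame, cand, sigma,
                          fit_config(neighbor_radius = 0), pixel_nm = 1)
  expect_gt(min(abs(sort(fit0$x_nm) - c(x1, x2))), 0.3)
})

test_that("filtering applies photon and width bounds and edge flags", {
  cfg <- fit_config(min_photons = 500, sigma_range = c(0.5, 2))
  tab <- loc_table(frame = rep(0L, 4),
                   x_nm = c(100, 200, 300, 400), y_nm = rep(100, 4),
                   photons = c(499, 500, 2000, 1000),
                   sigma_nm = c(130, 130, 390, 130),   # third is 3x prior
                   bg_photons = rep(0, 4), channel = rep(0L, 4),
                   keep = c(TRUE, TRUE, TRUE, FALSE))  # fourth edge-flagged
  out <- filter_localizations(tab, cfg, psf_sigma_nm = 130)
  expect_identical(out$keep, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("rendering bins by the half-open 13 nm convention", {
  tab <- loc_table(frame = 0L, x_nm = 26.0, y_nm = 13.0, photons = 1000,
                   sigma_nm = 130, bg_photons = 0, channel = 0L, keep = TRUE)
  img <- render_localizations(tab, 13, extent = c(0, 52, 0, 52))
  expect_equal(sum(img$counts), 1)
  expect_equal(img$counts[2, 3], 1)      # 0-based (row 1, col 2)

  # conservation and translation equivariance
  set.seed(8)
  n <- 200
  tab2 <- loc_table(frame = integer(n), x_nm = runif(n, 13, 400),
                    y_nm = runif(n, 13, 400), photons = numeric(n),
                    sigma_nm = numeric(n), bg_photons = numeric(n),
                    channel = integer(n), keep = rep(TRUE, n))
  img2 <- render_localizations(tab2, 13, extent = c(0, 416, 0, 416))
  expect_equal(sum(img2$counts), n)
  tab3 <- tab2
  tab3$x_nm <- tab3$x_nm + 13
  img3 <- render_localizations(tab3, 13, extent = c(0, 429, 0, 416))
  expect_equal(img3$counts[, 2:32], img2$counts[, 1:31])
  expect_error(render_localizations(tab2, 13, extent = c(0, 0, 0, 0)),
               "empty extent")
})
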