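test_that("GMM clustering recovers simulated nanocluster structure", {
  set.seed(3)
  p1 <- cbind(rnorm(500, 2000, 30), rnorm(500, 2000, 30))
  p2 <- cbind(rnorm(500, 12000, 30), rnorm(500, 12000, 30))
  cs <- gmm_clusters(rbind(p1, p2), G = 1:5)
  expect_equal(length(cs$sizes), 2L)
  expect_equal(cs$mean_size, 60, tolerance = 0.1)        # 2 sigma
  expect_true(all(abs(cs$n_loc - 500) <= 3 * sqrt(500)))
  expect_equal(sort(unique(cs$assignment)), 1:2)

  # degenerate input: regularisation floor, not a crash
  same <- matrix(rep(c(100, 100), each = 50), 50, 2)
  cs2 <- gmm_clusters(same, G = 1:3)
  expect_equal(cs2$mean_size, 2 * sqrt(sqrt(1)))          # floor 1 nm^2

  # too few points
  expect_error(gmm_clusters(matrix(1:4, 2, 2), G = 2:3), "at least")

  # compact vs decompact presets: mean size strictly smaller when
  # fragmented (spherical family + noise component as in the trend
  # harness; diffuse localizations otherwise swamp the size statistic)
  sizes <- vapply(c("compact", "decompact"), function(p) {
    gt <- chromatin_preset(p, seed = 7)
    lt <- simulate_localizations(gt, precision_nm = 10, seed = 8)
    cs <- gmm_clusters(cbind(lt$x_nm, lt$y_nm), G = seq(10, 35, by = 5),
                       model_names = "VII", noise = TRUE, prior = 100)
    mean(cs$sizes[cs$n_loc >= 10])
  }, 0)
  expect_gt(sizes["compact"], sizes["decompact"])
})

test_that("nearest-neighbour distances match geometry and the Poisson law", {
  # square grid of spacing a: all nnd equal a
  g <- as.matrix(expand.grid(seq(0, 900, 100), seq(0, 900, 100)))
  nn <- nearest_neighbor_distances(g)
  expect_true(all(abs(nn$nnd - 100) < 1e-9))
  # two centres at distance d
  nn2 <- nearest_neighbor_distances(rbind(c(0, 0), c(30, 40)))
  expect_equal(nn2$nnd, c(50, 50))
  expect_error(nearest_neighbor_distances(rbind(c(0, 0))), ">= 2")
  # 2D Poisson process: mean nnd = 1 / (2 sqrt(rho))
  set.seed(4)
  n <- 3000; W <- 20000
  pts <- cbind(runif(n, 0, W), runif(n, 0, W))
  rho <- n / W^2
  expect_equal(nearest_neighbor_distances(pts)$mean, 1 / (2 * sqrt(rho)),
               tolerance = 0.03)
})

test_that("pair correlation is flat for CSR and spiked for two points", {
  set.seed(9)
  n <- 4000; W <- 4000
  pts <- cbind(runif(n, 0, W), runif(n, 0, W))
  mask <- matrix(TRUE, ceiling(W / 13), ceiling(W / 13))
  curve <- rdf(pts, mask, dr = 20, r_max = 500)
  sel <- curve$r >= 50
  expect_lt(max(abs(curve$g[sel] - 1)), 0.08)
  expect_true(all(curve$g >= 0))
  # no clustering signal: no correlation length
  expect_true(is.na(attr(curve, "correlation_length")) ||
                attr(curve, "correlation_length") < 100)

  # exactly two points distance d apart: single nonzero bin containing d
  two <- rbind(c(1000, 1000), c(1000, 1123))
  c2 <- rdf(two, mask, dr = 20, r_max = 300)
  nz <- which(c2$g > 0)
  expect_equal(length(nz), 1L)
  expect_true(c2$r[nz] - 10 <= 123 && 123 < c2$r[nz] + 10)

  expect_error(rdf(two, matrix(FALSE, 10, 10)), "empty mask")
})

test_that("pair correlation agrees with an independent estimator", {
  skip_if_not_installed("spatstat.explore")
  set.seed(10)
  pts <- sim_thomas(rho_p = 3e-6, sigma = 60, mu = 40, W = 5000, seed = 10)
  mask <- matrix(TRUE, ceiling(5000 / 13), ceiling(5000 / 13))
  ours <- rdf(pts, mask, dr = 10, r_max = 400)
  pp <- spatstat.geom::ppp(pts[, 1], pts[, 2],
                           window = spatstat.geom::owin(c(0, 5000), c(0, 5000)))
  ref <- spatstat.explore::pcf(pp, r = seq(0, 400, 5), correction = "Ripley")
  ref_g <- approx(ref$r, ref$iso, xout = ours$r)$y
  sel <- ours$r >= 30 & ours$r <= 350
  expect_lt(median(abs(ours$g[sel] - ref_g[sel]) / ref_g[sel]), 0.1)
})

test_that("Voronoi density reproduces lattice geometry and local density", {
  a <- 130
  g <- expand.grid(x = seq(200, 4800, by = a), y = seq(200, 4800, by = a))
  mask <- matrix(TRUE, 385, 385)
  vd <- voronoi_density(cbind(g$x, g$y), mask)
  interior <- !vd$border
  expect_true(any(interior))
  expect_equal(unique(round(vd$areas[interior], 6)), a^2)
  expect_equal(unique(round(vd$density[interior], 12)), round(1 / a^2, 12))

  # bounded polygon areas conserve the window area when points cover it
  set.seed(11)
  pts <- cbind(runif(3000, 0, 5000), runif(3000, 0, 5000))
  vd2 <- voronoi_density(pts, mask)
  expect_lte(sum(vd2$areas), 5005^2 * 1.001)
  expect_equal(sum(vd2$areas), 5005^2, tolerance = 0.01)

  # doubling density in a subregion doubles the median local density
  # (the base rate puts 500 of 2000 points in the 2500 nm quadrant)
  set.seed(12)
  base <- cbind(runif(2000, 0, 5000), runif(2000, 0, 5000))
  extra <- cbind(runif(500, 0, 2500), runif(500, 0, 2500))
  vd3 <- voronoi_density(rbind(base, extra), mask)
  inA <- vd3$points[, 1] < 2300 & vd3$points[, 2] < 2300 & !vd3$border
  inB <- vd3$points[, 1] > 2700 & vd3$points[, 2] > 2700 & !vd3$border
  ratio <- median(vd3$density[inA]) / median(vd3$density[inB])
  expect_equal(ratio, 2, tolerance = 0.15)

  expect_error(voronoi_density(cbind(1:5, 2 * (1:5)), mask), "collinear")
})

test_that("watershed follows the regional-maxima recipe", {
  # two well-separated blobs: exactly two domains covering the support
  xs <- row(matrix(0, 120, 120)); ys <- col(matrix(0, 120, 120))
  m <- exp(-((xs - 35)^2 + (ys - 35)^2) / 72) +
    exp(-((xs - 85)^2 + (ys - 85)^2) / 72)
  m[m < 0.01] <- 0
  ws <- watershed_domains(m)
  expect_equal(ws$count, 2L)
  # connected-components oracle on the thresholded truth agrees
  cc <- EBImage::bwlabel(m > 0.01)
  expect_equal(max(cc), 2L)
  # domains partition only the support
  expect_true(all(ws$labels[m == 0] == 0L))
  expect_lte(sum(ws$areas_px), sum(m > 0))
  # equivalent diameter definition
  expect_equal(ws$diameters_nm, 2 * sqrt(ws$areas_px * 13^2 / pi))

  # segments under 20 px are rejected
  m2 <- matrix(0, 40, 40); m2[20:21, 18:22] <- 1
  expect_equal(watershed_domains(m2)$count, 0L)
  # an all-zero map yields an empty segmentation, not an error
  expect_equal(watershed_domains(matrix(0, 30, 30))$count, 0L)
})

test_that("coverage fraction thresholds the smoothed render", {
  mask <- matrix(TRUE, 41, 41)
  expect_equal(coverage_fraction(matrix(0, 41, 41), mask), 0)
  expect_equal(coverage_fraction(matrix(1, 41, 41), mask), 1)
  # an isolated single-count pixel contributes no covered pixels: the
  # sigma = 1 smoothed unit impulse peaks at ~0.159 < 0.5
  img <- matrix(0, 41, 41); img[21, 21] <- 1
  expect_equal(max(gaussian_smooth(img, 1)), 1 / (2 * pi), tolerance = 0.01)
  expect_equal(coverage_fraction(img, mask), 0)
  expect_error(coverage_fraction(img, matrix(FALSE, 41, 41)), "empty mask")
})

test_that("colocalization fractions are directional and bounded", {
  A <- matrix(FALSE, 10, 10); B <- matrix(FALSE, 10, 10)
  A[3:4, 3:4] <- TRUE; B[1:6, 1:6] <- TRUE
  co <- colocalize(A, B)
  expect_equal(co$a_over_b, 1.0)           # A subset of B
  expect_equal(co$b_over_a, 4 / 36)
  # disjoint maps
  B2 <- matrix(FALSE, 10, 10); B2[8:9, 8:9] <- TRUE
  co2 <- colocalize(A, B2)
  expect_equal(c(co2$a_over_b, co2$b_over_a), c(0, 0))
  # left half vs top half of a square: both fractions 0.5
  L <- matrix(FALSE, 10, 10); L[, 1:5] <- TRUE
  T_ <- matrix(FALSE, 10, 10); T_[1:5, ] <- TRUE
  co3 <- colocalize(L, T_)
  expect_equal(c(co3$a_over_b, co3$b_over_a), c(0.5, 0.5))
  # empty map flags that direction instead of crashing
  co4 <- colocalize(matrix(FALSE, 10, 10), B)
  expect_true(is.na(co4$a_over_b))
  expect_true(co4$undefined["a"])
})

test_that("group comparison is the exact two-tailed Mann-Whitney test", {
  # full-enumeration oracle: all C(4,2) = 6 rank splits of {1,2,3,4}
  splits <- combn(4, 2)
  u_all <- apply(splits, 2, function(ix) {
    g1 <- c(1, 2, 3, 4)[ix]; g2 <- c(1, 2, 3, 4)[-ix]
    sum(outer(g1, g2, ">"))
  })
  p_oracle <- mean(u_all <= 0) * 2        # two-tailed, U = 0 observed
  gc <- group_compare(c(1, 2), c(3, 4))
  expect_equal(gc$U, 0)
  expect_equal(gc$p, p_oracle)
  expect_equal(gc$p, 1 / 3)
  # label symmetry
  expect_equal(group_compare(c(3, 4), c(1, 2))$p, gc$p)
  # identical groups: p = 1 under tie handling
  expect_equal(group_compare(c(1, 2, 3), c(1, 2, 3))$p, 1, tolerance = 1e-6)
  expect_error(group_compare(numeric(0), 1:3), "empty")
})
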