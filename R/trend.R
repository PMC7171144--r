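# In-silico compaction-trend evaluation: the package's own end-to-end
# benchmark of the quantification suite on the simulator presets.

#' Quantify simulated nuclei along the compaction axis
#'
#' For each requested preset, simulates `n_per_group` nuclei and measures
#' the per-nucleus quantities the quantification suite reports on real
#' data: GMM mean nanocluster size, pair-correlation length, watershed
#' nanodomain diameter and coverage fraction.  Two acquisition regimes of
#' the same ground truth are simulated: cluster metrics (GMM, pair
#' correlation) use single-blink localizations at high precision
#' (`cluster_precision_nm`), as after photon filtering; density-map
#' metrics (Voronoi/watershed, coverage) use the full multi-blink stream
#' at tissue-typical precision (`density_precision_nm`).  Mixture fits use
#' the spherical family with a uniform noise component (the presets'
#' diffuse pool), and the size summary averages components holding at
#' least 10 localizations; watershed domains enter the size statistics
#' when they hold at least three emitters' worth of localizations.
#'
#' @param n_per_group Nuclei per preset.
#' @param seed Base seed; nucleus k of preset j uses derived seeds.
#' @param presets Character vector of [chromatin_preset()] names.
#' @param cluster_precision_nm Localization precision of the cluster-
#'   metric acquisition.
#' @param density_precision_nm Localization precision of the density-map
#'   acquisition.
#' @param mean_blinks Mean blinks per emitter for the density-map path.
#' @param gmm_G BIC grid for the mixture fits (the presets carry 20-30
#'   clusters per nucleus).
#' @return Data frame with one row per nucleus: `preset`, `replicate`,
#'   `mean_cluster_size_nm`, `correlation_length_nm`,
#'   `median_domain_diameter_nm`, `domain_count`, `coverage_fraction`.
#' @export
preset_trend <- function(n_per_group = 20L, seed = 1L,
                         presets = c("normal", "early", "tumor"),
                         cluster_precision_nm = 10,
                         density_precision_nm = 20, mean_blinks = 15,
                         gmm_G = seq(10L, 35L, by = 5L)) {
  nucleus <- circle_polygon(c(2600, 2600), 2000)
  px <- 13
  lab <- rasterize_polygon(circle_polygon(c(2600, 2600), 2100), px,
                           c(400L, 400L))
  rows <- list()
  for (j in seq_along(presets)) {
    for (k in seq_len(n_per_group)) {
      s <- stage_seed(seed, j * 1000L + k)
      gt <- chromatin_preset(presets[j], seed = s, nucleus = nucleus)
      l1 <- simulate_localizations(gt, cluster_precision_nm, seed = s + 1L)
      pts1 <- cbind(l1$x_nm, l1$y_nm)
      cs <- gmm_clusters(pts1, G = gmm_G, model_names = "VII",
                         noise = TRUE, prior = 100, robust_size = TRUE,
                         seed = s + 2L)
      occupied <- cs$n_loc >= 10L
      curve <- rdf(pts1, lab, dr = 10, r_max = 400, pixel_nm = px)
      ld <- simulate_localizations(gt, density_precision_nm,
                                   mean_blinks = mean_blinks, seed = s + 3L)
      pts <- cbind(ld$x_nm, ld$y_nm)
      vd <- voronoi_density(pts, lab, pixel_nm = px)
      ws <- watershed_domains(vd, mask = lab)
      dom_d <- domain_diameters_filtered(ws, pts, min_locs = 3 * mean_blinks)
      img <- render_localizations(ld, px, extent = c(0, 5200, 0, 5200))
      rows[[length(rows) + 1L]] <- data.frame(
        preset = presets[j], replicate = k,
        mean_cluster_size_nm = mean(cs$sizes[occupied]),
        correlation_length_nm = attr(curve, "correlation_length"),
        median_domain_diameter_nm = if (length(dom_d) > 0)
          median(dom_d) else NA_real_,
        domain_count = ws$count,
        coverage_fraction = coverage_fraction(img, lab))
    }
  }
  do.call(rbind, rows)
}

# Diameters of watershed domains holding at least min_locs localizations.
domain_diameters_filtered <- function(ws, pts, min_locs) {
  if (ws$count == 0L) return(numeric(0))
  px <- ws$pixel_nm
  j <- clamp(floor(pts[, 1] / px) + 1L, 1L, ncol(ws$labels))
  i <- clamp(floor(pts[, 2] / px) + 1L, 1L, nrow(ws$labels))
  ids <- ws$labels[cbind(i, j)]
  cnt <- tabulate(ids[ids > 0L], nbins = ws$count)
  ws$diameters_nm[cnt >= min_locs]
}
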