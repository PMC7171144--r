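# Pipeline orchestration: reconstruction (stack -> localizations ->
# rendered image) and quantification (localizations + masks -> per-nucleus
# summary), with a single nested configuration and reproducible seeding.

default_config <- function() {
  list(
    seed = 1L,
    background = list(substack = 100L),
    fit = list(roi_radius = 3L, threshold_k = 3, min_photons = 300,
               sigma_range = c(0.5, 2.0), psf_sigma_nm = 130),
    register = list(gate_nm = 500, smooth_window = 10L, degree = 2L),
    render = list(pixel_nm = 13),
    nanostruct = list(gmm_G = c(2L, 30L), gmm_model = "VVV",
                      gmm_noise = TRUE, rdf_dr = 10, rdf_rmax = 500,
                      voronoi_smooth = 2, min_domain_px = 20L,
                      min_points = 50L),
    sim3d = list(median_radius_nm = 5000, n_rays = 360L, stop_frac = 0.2)
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ", paste0(path, nm))
    }
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Build a resolved pipeline configuration
#'
#' Unknown keys are rejected; every pipeline run writes the resolved
#' configuration beside its outputs.
#'
#' @param ... Named overrides of the defaults, nested as in the default
#'   list (e.g. `background = list(substack = 50)`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(default_config(), user)
  class(cfg) <- "pipeline_config"
  cfg
}

write_resolved_config <- function(cfg, out_dir) {
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Reconstruct a localization table and rendered image from a raw stack
#'
#' Runs the full path: counts to photons, temporal-minimum background
#' estimation and subtraction, per-frame detection, deflation and
#' gradient fitting, quality filtering, optional fiducial drift
#' correction, and rendering at the configured pixel size.
#'
#' @param stack A `frame_stack` (counts or photons) or a path readable by
#'   [read_stack()].
#' @param config A [pipeline_config()].
#' @param fiducial_seeds Optional k x 2 matrix of approximate bead
#'   positions (nm) enabling drift correction.
#' @param out_dir Optional output directory; localizations, render,
#'   resolved config and a stage manifest are written there.
#' @return List with `locs` (a `loc_table`), `render` (a
#'   [rendered_image()]), `background` model, `drift` trajectory (or
#'   `NULL`) and a `manifest` of per-stage counts.
#' @export
reconstruct_pipeline <- function(stack, config = pipeline_config(),
                                 fiducial_seeds = NULL, out_dir = NULL) {
  if (is.character(stack)) stack <- read_stack(stack)
  manifest <- list(n_frames = n_frames(stack))
  extent <- c(0, ncol(stack$data) * stack$pixel_nm,
              0, nrow(stack$data) * stack$pixel_nm)
  if (n_frames(stack) == 0L || all(dim(stack$data)[1:2] == 0L)) {
    locs <- empty_loc_table()
    img <- render_localizations(locs, config$render$pixel_nm,
                                extent = c(0, stack$pixel_nm, 0, stack$pixel_nm))
    return(list(locs = locs, render = img, background = NULL, drift = NULL,
                manifest = manifest))
  }
  if (stack$unit == "counts") stack <- counts_to_photons(stack)
  model <- estimate_background(stack, config$background$substack)
  corrected <- subtract_background(stack, model)
  fc <- fit_config(roi_radius = config$fit$roi_radius,
                   threshold_k = config$fit$threshold_k,
                   min_photons = config$fit$min_photons,
                   sigma_range = config$fit$sigma_range,
                   render_pixel_nm = config$render$pixel_nm)
  locs <- localize_stack(corrected, model, config$fit$psf_sigma_nm, fc)
  manifest$n_fits <- nrow(locs)
  manifest$n_kept <- sum(locs$keep)
  drift <- NULL
  if (!is.null(fiducial_seeds) && nrow(locs) > 0L) {
    drift <- estimate_drift(locs, fiducial_seeds,
                            gate_nm = config$register$gate_nm,
                            smooth_window = config$register$smooth_window)
    locs <- apply_drift(locs, drift)
  }
  img <- render_localizations(locs, config$render$pixel_nm, extent = extent)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_locs(locs, file.path(out_dir, "localizations.csv"))
    write_render(img, file.path(out_dir, "render.tif"))
    write_resolved_config(config, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(drift)) {
      write.csv(as.data.frame(drift), file.path(out_dir, "drift.csv"),
                row.names = FALSE)
    }
  }
  list(locs = locs, render = img, background = model, drift = drift,
       manifest = manifest)
}

#' Quantify chromatin nanostructure per nucleus
#'
#' For every nucleus in the mask: GMM nanoclusters (size, localizations
#' per cluster, centre nearest-neighbour distance), edge-corrected pair
#' correlation with correlation length, Voronoi density map, watershed
#' nanodomains and coverage fraction.  Nuclei with fewer than
#' `min_points` kept localizations are flagged and skipped; the others
#' proceed.  When a second channel table and chromatic transform are
#' supplied, binary-map colocalization is appended.
#'
#' @param locs A `loc_table` or a CSV path.
#' @param mask A `nucleus_mask` (label image or polygons) or path to a
#'   label TIFF written by [write_mask()].
#' @param config A [pipeline_config()].
#' @param locs_b Optional second-channel `loc_table`.
#' @param chromatic Optional [fit_chromatic()] transform applied to
#'   `locs_b` before colocalization.
#' @param out_dir Optional output directory for the summary CSV and
#'   resolved config.
#' @return Data frame with one row per nucleus:
#'   `nucleus_id, n_locs, flagged, mean_cluster_size_nm, locs_per_cluster,
#'   nnd_nm, correlation_length_nm, domain_count,
#'   median_domain_diameter_nm, coverage_fraction` (plus colocalization
#'   columns when a second channel is given), with the per-nucleus result
#'   objects attached as attribute `details`.
#' @export
quantify_pipeline <- function(locs, mask, config = pipeline_config(),
                              locs_b = NULL, chromatic = NULL,
                              out_dir = NULL) {
  if (is.character(locs)) locs <- read_locs(locs)
  if (is.character(mask)) mask <- read_mask(mask)
  labels <- mask_labels(mask)
  px <- mask$pixel_nm
  origin <- mask$origin
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  pts_all <- locs[locs$keep %in% TRUE, , drop = FALSE]
  if (!is.null(locs_b) && !is.null(chromatic)) {
    locs_b <- apply_chromatic(locs_b, chromatic)
  }
  rows <- list()
  details <- list()
  for (id in ids) {
    msk <- labels == id
    mr <- list(raster = msk, pixel_nm = px, origin = origin)
    inb <- mask_lookup(mr, pts_all$x_nm, pts_all$y_nm)
    pts <- cbind(pts_all$x_nm[inb], pts_all$y_nm[inb])
    n <- nrow(pts)
    row <- data.frame(nucleus_id = id, n_locs = n, flagged = FALSE,
                      mean_cluster_size_nm = NA_real_,
                      locs_per_cluster = NA_real_, nnd_nm = NA_real_,
                      correlation_length_nm = NA_real_,
                      domain_count = NA_integer_,
                      median_domain_diameter_nm = NA_real_,
                      coverage_fraction = NA_real_)
    if (n < config$nanostruct$min_points) {
      row$flagged <- TRUE
      rows[[length(rows) + 1L]] <- row
      next
    }
    gg <- config$nanostruct$gmm_G
    G <- seq(gg[1], gg[2], by = max(2L, (gg[2] - gg[1]) %/% 6L))
    cs <- gmm_clusters(pts, G = G,
                       model_names = config$nanostruct$gmm_model,
                       noise = config$nanostruct$gmm_noise,
                       prior = if (config$nanostruct$gmm_noise) 100 else FALSE,
                       robust_size = config$nanostruct$gmm_noise,
                       seed = stage_seed(config$seed, id))
    curve <- rdf(pts, msk, dr = config$nanostruct$rdf_dr,
                 r_max = config$nanostruct$rdf_rmax, pixel_nm = px)
    vd <- voronoi_density(pts, msk, pixel_nm = px,
                          smooth_sigma = config$nanostruct$voronoi_smooth)
    ws <- watershed_domains(vd, mask = msk,
                            min_area_px = config$nanostruct$min_domain_px)
    tab <- loc_table(frame = integer(n), x_nm = pts[, 1], y_nm = pts[, 2],
                     photons = numeric(n), sigma_nm = numeric(n),
                     bg_photons = numeric(n), channel = integer(n),
                     keep = rep(TRUE, n))
    img <- render_localizations(tab, px,
                                extent = c(origin[1],
                                           origin[1] + ncol(labels) * px,
                                           origin[2],
                                           origin[2] + nrow(labels) * px))
    row$mean_cluster_size_nm <- cs$mean_size
    row$locs_per_cluster <- cs$mean_locs_per_cluster
    row$nnd_nm <- cs$mean_nnd
    row$correlation_length_nm <- attr(curve, "correlation_length")
    row$domain_count <- ws$count
    row$median_domain_diameter_nm <-
      if (ws$count > 0) median(ws$diameters_nm) else NA_real_
    row$coverage_fraction <- coverage_fraction(img, msk)
    if (!is.null(locs_b)) {
      ptsb <- locs_b[locs_b$keep %in% TRUE, , drop = FALSE]
      inbb <- mask_lookup(mr, ptsb$x_nm, ptsb$y_nm)
      tabb <- ptsb[inbb, , drop = FALSE]
      imgb <- render_localizations(tabb, px,
                                   extent = c(origin[1],
                                              origin[1] + ncol(labels) * px,
                                              origin[2],
                                              origin[2] + nrow(labels) * px))
      co <- colocalize(gaussian_smooth(img$counts, 1) > 0.5 & msk,
                       gaussian_smooth(imgb$counts, 1) > 0.5 & msk)
      row$coloc_a_over_b <- co$a_over_b
      row$coloc_b_over_a <- co$b_over_a
    }
    rows[[length(rows) + 1L]] <- row
    details[[as.character(id)]] <- list(clusters = cs, rdf = curve,
                                        voronoi = vd, watershed = ws)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(nucleus_id = integer(), n_locs = integer(),
               flagged = logical())
  attr(out, "details") <- details
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(out_dir, "summary.csv"), row.names = FALSE)
    write_resolved_config(config, out_dir)
  }
  out
}
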