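# File formats: multi-page TIFF stacks with JSON metadata sidecars,
# comma-delimited localization tables, label-image / polygon nucleus masks.
# All file coordinates are 0-based, units nm, y down.

#' Construct a frame stack
#'
#' @param data 3D numeric array `[row, col, frame]` of camera counts or
#'   photons.
#' @param pixel_nm Camera pixel size (nm/px, > 0).
#' @param gain Camera gain (counts/photon, > 0).
#' @param offset Camera offset (counts).
#' @param unit `"counts"` or `"photons"`.
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(data, pixel_nm, gain, offset, unit = c("counts", "photons")) {
  unit <- match.arg(unit)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, pixel_nm > 0, gain > 0)
  if (unit == "photons" && any(data < 0)) stop("photon data must be >= 0")
  structure(list(data = data, pixel_nm = pixel_nm, gain = gain,
                 offset = offset, unit = unit),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("frame_stack: %d frames of %dx%d px (%g nm/px), unit %s\n",
              d[3], d[1], d[2], x$pixel_nm, x$unit))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A `frame_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$data)[3]

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a frame stack as multi-page TIFF plus JSON sidecar
#'
#' Counts stacks are stored as 16-bit integer TIFF (values must be integers
#' in 0..65535); photon stacks are stored as 32-bit float with a power-of-two
#' scale recorded in the sidecar.  `read_stack(write_stack(s))` reproduces
#' data and metadata exactly for counts stacks.
#'
#' @param stack A `frame_stack`.
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns a
#'   `frame_stack`.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  meta <- list(pixel_nm = stack$pixel_nm, gain = stack$gain,
               offset = stack$offset, unit = stack$unit, n_frames = d[3])
  if (stack$unit == "counts") {
    v <- stack$data
    if (any(v != round(v)) || any(v < 0) || any(v > 65535)) {
      stop("counts stack must hold integers in 0..65535 for 16-bit storage")
    }
    pages <- lapply(seq_len(d[3]), function(f) stack$data[, , f] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else {
    scale <- 2^ceiling(log2(max(stack$data, 1)))
    meta$scale <- scale
    pages <- lapply(seq_len(d[3]), function(f) stack$data[, , f] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing metadata sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  required <- c("pixel_nm", "gain", "offset", "unit")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop("stack metadata missing required keys: ", paste(missing, collapse = ", "))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (meta$unit == "counts"))
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) stop("non-uniform frame shapes in TIFF")
  data <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (meta$unit == "photons") data <- data * meta$scale
  frame_stack(data, pixel_nm = meta$pixel_nm, gain = meta$gain,
              offset = meta$offset, unit = meta$unit)
}

loc_columns <- c("frame", "x_nm", "y_nm", "photons", "sigma_nm",
                 "bg_photons", "channel", "keep")

#' Construct a localization table
#'
#' The central exchange format of the pipeline: one row per fitted
#' molecule.
#'
#' @param frame 0-based frame index.
#' @param x_nm,y_nm Position in nm (x right, y down, origin top-left).
#' @param photons Fitted photon count.
#' @param sigma_nm Fitted PSF width.
#' @param bg_photons Local background estimate (photons/px).
#' @param channel Integer channel id.
#' @param keep Quality flag.
#' @return A `loc_table` data frame.
#' @export
loc_table <- function(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                      photons = numeric(), sigma_nm = numeric(),
                      bg_photons = numeric(), channel = integer(),
                      keep = logical()) {
  stopifnot(all(is.finite(x_nm)), all(is.finite(y_nm)))
  df <- data.frame(frame = as.integer(frame), x_nm = x_nm, y_nm = y_nm,
                   photons = photons, sigma_nm = sigma_nm,
                   bg_photons = bg_photons, channel = as.integer(channel),
                   keep = keep)
  class(df) <- c("loc_table", "data.frame")
  df
}

empty_loc_table <- function() loc_table()

as_loc_table <- function(df) {
  missing <- setdiff(c("frame", "x_nm", "y_nm"), names(df))
  if (length(missing) > 0L) {
    stop("localization table missing required columns: ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(df)
  defaults <- list(photons = NA_real_, sigma_nm = NA_real_, bg_photons = 0,
                   channel = 0L, keep = TRUE)
  for (cn in names(defaults)) {
    if (is.null(df[[cn]])) df[[cn]] <- rep(defaults[[cn]], n)
  }
  df$frame <- as.integer(df$frame)
  df$keep <- as.logical(df$keep)
  if (any(!is.finite(df$x_nm)) || any(!is.finite(df$y_nm))) {
    stop("localization coordinates must be finite")
  }
  class(df) <- c("loc_table", "data.frame")
  df[c(loc_columns, setdiff(names(df), loc_columns))]
}

#' Write / read localization tables as delimited text
#'
#' The native dialect is comma-delimited with header
#' `frame,x_nm,y_nm,photons,sigma_nm,bg_photons,channel,keep` (coordinates
#' in nm).  The `"pixels"` dialect reads tables with `x_px`/`y_px` columns
#' in camera-pixel units and converts through `pixel_nm`.  Unknown columns
#' are preserved as opaque extras; missing `frame`/`x`/`y` columns are an
#' error.
#'
#' @param table A `loc_table`.
#' @param path CSV path.
#' @param dialect `"native"` or `"pixels"`.
#' @param pixel_nm Camera pixel size, required for the `"pixels"` dialect.
#' @return `write_locs` returns `path` invisibly; `read_locs` returns a
#'   `loc_table`.
#' @export
write_locs <- function(table, path) {
  df <- as.data.frame(table)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_locs
#' @export
read_locs <- function(path, dialect = c("native", "pixels"), pixel_nm = NULL) {
  dialect <- match.arg(dialect)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "pixels") {
    if (is.null(pixel_nm)) stop("pixel dialect requires pixel_nm")
    missing <- setdiff(c("frame", "x_px", "y_px"), names(df))
    if (length(missing) > 0L) {
      stop("localization table missing required columns: ",
           paste(missing, collapse = ", "))
    }
    df$x_nm <- df$x_px * pixel_nm
    df$y_nm <- df$y_px * pixel_nm
    if (!is.null(df$sigma_px) && is.null(df$sigma_nm)) {
      df$sigma_nm <- df$sigma_px * pixel_nm
    }
    df$x_px <- NULL; df$y_px <- NULL; df$sigma_px <- NULL
  }
  as_loc_table(df)
}

#' Construct a nucleus mask
#'
#' Either a label image at render resolution (`labels`: integer matrix,
#' 0 = outside, k = nucleus k) or a list of closed polygons in nm
#' (`polygons`).  Both representations are accepted wherever a mask is
#' needed; [mask_labels()] rasterizes polygons on demand.
#'
#' @param labels Integer label matrix, or `NULL`.
#' @param polygons List of two-column vertex matrices (nm), or `NULL`.
#' @param pixel_nm Raster pixel size of `labels` (default 13 nm).
#' @param origin Raster origin in nm.
#' @return A `nucleus_mask`.
#' @export
nucleus_mask <- function(labels = NULL, polygons = NULL, pixel_nm = 13,
                         origin = c(0, 0)) {
  if (is.null(labels) && is.null(polygons)) {
    stop("provide labels or polygons")
  }
  structure(list(labels = labels, polygons = polygons, pixel_nm = pixel_nm,
                 origin = origin),
            class = "nucleus_mask")
}

#' Rasterize a nucleus mask to a label matrix
#' @param mask A `nucleus_mask`.
#' @param dim_px Raster size (rows, cols); required when rasterizing
#'   polygons without an existing label image.
#' @return Integer label matrix.
#' @export
mask_labels <- function(mask, dim_px = NULL) {
  if (!is.null(mask$labels)) return(mask$labels)
  if (is.null(dim_px)) {
    xmax <- max(vapply(mask$polygons, function(p) max(p[, 1]), 0))
    ymax <- max(vapply(mask$polygons, function(p) max(p[, 2]), 0))
    dim_px <- c(ceiling(ymax / mask$pixel_nm) + 1L,
                ceiling(xmax / mask$pixel_nm) + 1L)
  }
  lab <- matrix(0L, dim_px[1], dim_px[2])
  for (k in seq_along(mask$polygons)) {
    inside <- rasterize_polygon(mask$polygons[[k]], mask$pixel_nm, dim_px,
                                mask$origin)
    if (any(lab[inside] != 0L)) stop("nucleus regions overlap")
    lab[inside] <- k
  }
  lab
}

#' Write / read a label mask as 16-bit TIFF with sidecar
#' @param mask A `nucleus_mask` with labels (polygons are rasterized).
#' @param path TIFF path.
#' @return `read_mask` returns a `nucleus_mask`.
#' @export
write_mask <- function(mask, path) {
  lab <- mask_labels(mask)
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(pixel_nm = mask$pixel_nm, origin = mask$origin),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  lab <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(lab) <- "integer"
  nucleus_mask(labels = lab, pixel_nm = meta$pixel_nm, origin = meta$origin)
}

#' Write / read nucleus polygons as JSON
#' @param polygons List of two-column vertex matrices (nm).
#' @param path JSON path.
#' @return `read_polygons` returns the list of matrices.
#' @export
write_polygons <- function(polygons, path) {
  jsonlite::write_json(lapply(polygons, unname), path, digits = NA)
  invisible(path)
}

#' @rdname write_polygons
#' @export
read_polygons <- function(path) {
  lapply(jsonlite::read_json(path), function(p) {
    do.call(rbind, lapply(p, function(v) unlist(v)))
  })
}

#' Construct a rendered localization image
#'
#' A 2D histogram of accumulated molecule counts at the render pixel size
#' (13 nm by default).
#'
#' @param counts Count matrix.
#' @param pixel_nm Render pixel size.
#' @param origin Field origin offset in nm.
#' @return A `rendered_image`.
#' @export
rendered_image <- function(counts, pixel_nm = 13, origin = c(0, 0)) {
  structure(list(counts = counts, pixel_nm = pixel_nm, origin = origin),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("rendered_image: %dx%d px at %g nm, %g molecules\n",
              nrow(x$counts), ncol(x$counts), x$pixel_nm, sum(x$counts)))
  invisible(x)
}

#' Write a rendered image (16-bit TIFF + sidecar)
#' @param img A `rendered_image`.
#' @param path TIFF path.
#' @export
write_render <- function(img, path) {
  v <- pmin(img$counts, 65535)
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(pixel_nm = img$pixel_nm, origin = img$origin),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
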