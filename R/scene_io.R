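# Scene bundles on disk: reflectance as a 5-channel float TIFF in [0, 1],
# truth mask as a binary TIFF, and thermal/DSM/DEM as TIFFs linearly
# rescaled to [0, 1] with per-layer scale/offset recorded in scene.json
# (the sidecar also carries the geotransform and CRS note). Plot polygons go
# to a GeoJSON FeatureCollection with plot_id and lai_measured properties.

write_scaled_tiff <- function(m, path) {
  lo <- min(m)
  hi <- max(m)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((m - lo) / scale, path, bits.per.sample = 16L,
                  compression = "deflate")
  list(offset = lo, scale = scale)
}

read_scaled_tiff <- function(path, meta) {
  m <- tiff::readTIFF(path)
  m * meta$scale + meta$offset
}

#' Write a scene bundle to a directory
#'
#' Writes `reflectance.tif` (5-channel, band order blue/green/red/rededge/
#' nir), `thermal.tif`, `dsm.tif`, `dem.tif`, `truth_mask.tif` (if present),
#' `plots.geojson` and a `scene.json` sidecar with the geotransform
#' (north-up), CRS note and per-layer scale/offset. [read_scene()] accepts
#' the same layout for externally produced data (truth mask optional).
#'
#' @param scene A `uav_scene`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  band_order <- c("blue", "green", "red", "rededge", "nir")
  # one TIFF page per band, in the declared band order
  tiff::writeTIFF(lapply(band_order, function(b) scene$bands[[b]]),
                  file.path(dir, "reflectance.tif"),
                  bits.per.sample = 16L, compression = "deflate")
  layers <- list(
    thermal = write_scaled_tiff(scene$thermal, file.path(dir, "thermal.tif")),
    dsm = write_scaled_tiff(scene$dsm, file.path(dir, "dsm.tif")),
    dem = write_scaled_tiff(scene$dem, file.path(dir, "dem.tif"))
  )
  if (!is.null(scene$truth_mask))
    tiff::writeTIFF(matrix(as.numeric(scene$truth_mask), scene$geom$nrow),
                    file.path(dir, "truth_mask.tif"), bits.per.sample = 8L,
                    compression = "deflate")
  write_plots_geojson(scene$plots, file.path(dir, "plots.geojson"))
  sidecar <- list(
    geom = scene$geom,
    crs_note = scene$crs_note,
    band_order = band_order,
    layer_scaling = layers,
    has_truth_mask = !is.null(scene$truth_mask)
  )
  jsonlite::write_json(sidecar, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

write_plots_geojson <- function(plots, path) {
  features <- lapply(seq_len(nrow(plots)), function(i) {
    p <- plots[i, ]
    ring <- list(c(p$xmin, p$ymin), c(p$xmax, p$ymin), c(p$xmax, p$ymax),
                 c(p$xmin, p$ymax), c(p$xmin, p$ymin))
    list(type = "Feature",
         properties = list(plot_id = p$plot_id,
                           lai_measured = p$lai_measured),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
}

read_plots_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(pt) as.numeric(pt[[1]]), numeric(1))
    ys <- vapply(ring, function(pt) as.numeric(pt[[2]]), numeric(1))
    data.frame(plot_id = f$properties$plot_id,
               xmin = min(xs), ymin = min(ys),
               xmax = max(xs), ymax = max(ys),
               lai_measured = as.numeric(f$properties$lai_measured %||% NA),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a scene bundle from a directory
#'
#' Inverse of [write_scene()]; the truth mask is optional (real scenes have
#' none).
#'
#' @param dir Directory containing a scene bundle.
#' @return A `uav_scene`.
#' @export
read_scene <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "scene.json"),
                                 simplifyVector = TRUE)
  bands <- tiff::readTIFF(file.path(dir, "reflectance.tif"), all = TRUE)
  names(bands) <- sidecar$band_order
  truth_path <- file.path(dir, "truth_mask.tif")
  truth <- if (file.exists(truth_path)) {
    m <- tiff::readTIFF(truth_path)
    matrix(as.integer(round(m)), nrow(m))
  } else NULL
  geom <- sidecar$geom
  geom$nrow <- as.integer(geom$nrow)
  geom$ncol <- as.integer(geom$ncol)
  structure(list(
    bands = bands,
    thermal = read_scaled_tiff(file.path(dir, "thermal.tif"),
                               sidecar$layer_scaling$thermal),
    dsm = read_scaled_tiff(file.path(dir, "dsm.tif"),
                           sidecar$layer_scaling$dsm),
    dem = read_scaled_tiff(file.path(dir, "dem.tif"),
                           sidecar$layer_scaling$dem),
    truth_mask = truth,
    plots = read_plots_geojson(file.path(dir, "plots.geojson")),
    geom = geom,
    crs_note = sidecar$crs_note,
    config = NULL
  ), class = "uav_scene")
}

#' Write a feature raster as TIFF with a nodata sidecar
#'
#' Undefined cells are written as the nodata value recorded in the `.json`
#' sidecar next to the TIFF (together with scale/offset).
#'
#' @param raster Feature matrix (NA = undefined).
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_feature_raster <- function(raster, path) {
  filled <- raster
  nodata <- if (all(is.na(raster))) 0 else min(raster, na.rm = TRUE) - 1
  filled[is.na(filled)] <- nodata
  meta <- write_scaled_tiff(filled, path)
  meta$nodata <- nodata
  meta$feature <- attr(raster, "feature")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
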