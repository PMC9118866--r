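#' Plot-level zonal mean of a feature raster
#'
#' For each plot polygon, averages the raster over the pixels whose centers
#' fall inside the polygon (pixel-center-in-polygon membership), ignoring
#' undefined cells. A plot whose member pixels are all undefined yields `NA`
#' with a warning.
#'
#' @param raster Feature matrix (NA = undefined).
#' @param plots Plot layout data.frame (see [generate_plot_layout()]).
#' @param geom Grid geometry, e.g. `scene$geom`.
#' @return Data.frame with `plot_id`, `mean` and `n_defined` (count of
#'   defined member pixels).
#' @export
#' @examples
#' sc <- generate_scene(scene_config(n_plot_rows = 1, n_plot_cols = 2,
#'                                   pixel_size_m = 0.05))
#' zonal_mean(sc$bands$nir, sc$plots, sc$geom)
zonal_mean <- function(raster, plots, geom) {
  stopifnot(is.matrix(raster))
  if (nrow(raster) != geom$nrow || ncol(raster) != geom$ncol)
    stop("raster shape does not match geometry", call. = FALSE)
  out <- data.frame(plot_id = plots$plot_id,
                    mean = NA_real_, n_defined = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(plots))) {
    if (plots$xmin[i] < geom$xmin || plots$xmax[i] > geom$xmax ||
        plots$ymin[i] < geom$ymin || plots$ymax[i] > geom$ymax)
      stop(sprintf("plot %s lies outside the raster extent", plots$plot_id[i]),
           call. = FALSE)
    cell <- pixel_indices_in_rect(geom, plots$xmin[i], plots$ymin[i],
                                  plots$xmax[i], plots$ymax[i])
    vals <- raster[cell$rows, cell$cols]
    n_def <- sum(!is.na(vals))
    out$n_defined[i] <- n_def
    if (n_def == 0L) {
      warning(sprintf("plot %s has no defined pixels; zonal mean is NA",
                      plots$plot_id[i]), call. = FALSE)
    } else {
      out$mean[i] <- mean(vals, na.rm = TRUE)
    }
  }
  out
}

#' Build the plot-by-feature modeling table
#'
#' Computes all 22 feature rasters of a scene (5 bands, 15 vegetation
#' indices, CHM, NRCT), optionally removes the soil background with a mask,
#' aggregates each feature to plot level by zonal mean, and joins the
#' measured LAI. Plots with fewer than `min_pixels` defined pixels (or any
#' undefined feature mean) are dropped with a message.
#'
#' @param scene A `uav_scene`.
#' @param mask Optional `vegetation_mask` (or 0/1 matrix); when given, soil
#'   pixels are excluded from every feature before aggregation.
#' @param nrct_extent NRCT baseline extent, `"whole_field"` (default) or
#'   `"masked_canopy"`.
#' @param min_pixels Minimum defined pixels for a plot to be retained
#'   (default 10).
#' @return A data.frame of class `lai_feature_table`: `plot_id`, 22 feature
#'   columns, `lai_measured`; attributes `masked`, `min_pixels`,
#'   `n_defined` (per retained plot).
#' @export
build_feature_table <- function(scene, mask = NULL,
                                nrct_extent = c("whole_field", "masked_canopy"),
                                min_pixels = 10L) {
  nrct_extent <- match.arg(nrct_extent)
  m <- if (inherits(mask, "vegetation_mask")) mask$mask else mask
  if (!is.null(m))
    stop_if_not_matrix_pair(scene$bands$nir, m, "scene grids", "mask")
  feats <- all_feature_names()
  tab <- data.frame(plot_id = scene$plots$plot_id, stringsAsFactors = FALSE)
  n_defined <- NULL
  for (f in feats) {
    r <- compute_feature(scene, f, nrct_extent = nrct_extent, mask = m)
    if (!is.null(m)) r <- apply_mask(r, m)
    zm <- withCallingHandlers(
      zonal_mean(r, scene$plots, scene$geom),
      warning = function(w) invokeRestart("muffleWarning"))
    tab[[f]] <- zm$mean
    if (f == "NIR") n_defined <- zm$n_defined
  }
  tab$lai_measured <- scene$plots$lai_measured
  keep <- n_defined >= min_pixels & stats::complete.cases(tab)
  if (!all(keep))
    message(sprintf("dropping %d plot(s) below %d defined pixels or with undefined features",
                    sum(!keep), min_pixels))
  if (!any(keep))
    stop("all plots dropped; mask removed every plot", call. = FALSE)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "masked") <- !is.null(m)
  attr(out, "min_pixels") <- as.integer(min_pixels)
  attr(out, "n_defined") <- n_defined[keep]
  class(out) <- c("lai_feature_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
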