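#' Lay out the trial's square plots
#'
#' Builds the plot polygons of the field trial: a regular
#' `n_plot_rows x n_plot_cols` grid of axis-aligned square plots of side
#' `plot_size_m`, separated by bare-soil alleys of width `alley_m` and
#' surrounded by a margin. Map coordinates are meters, x increasing east and
#' y increasing north, origin at the field's south-west corner.
#'
#' @param config A [scene_config()].
#' @return A data.frame with one row per plot: `plot_id`, grid `row`/`col`
#'   (row 1 is the northernmost), corner coordinates `xmin`, `ymin`, `xmax`,
#'   `ymax` (meters), and `lai_measured` (NA until LAI is sampled).
#' @export
#' @examples
#' layout <- generate_plot_layout(scene_config(pixel_size_m = 0.05))
#' nrow(layout)  # 80 plots
generate_plot_layout <- function(config) {
  validate_scene_config(config)
  nr <- config$n_plot_rows
  nc <- config$n_plot_cols
  step <- config$plot_size_m + config$alley_m
  field_h <- 2 * config$margin_m + nr * config$plot_size_m + (nr - 1) * config$alley_m
  idx <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  xmin <- config$margin_m + (idx$col - 1) * step
  # row 1 at the top (north): y decreases with row index
  ymax <- field_h - (config$margin_m + (idx$row - 1) * step)
  out <- data.frame(
    plot_id = sprintf("P%03d", seq_len(nr * nc)),
    row = idx$row,
    col = idx$col,
    xmin = xmin,
    ymin = ymax - config$plot_size_m,
    xmax = xmin + config$plot_size_m,
    ymax = ymax,
    lai_measured = NA_real_,
    stringsAsFactors = FALSE
  )
  out
}

# Default histogram table for the fig2_histogram LAI mode. The trial's LAI
# distribution concentrated in 1-2, 2-3 and 6-7 (20, 13 and 12 of 80 plots)
# with only two plots in 7-8; the remaining mass is spread uniformly over the
# unreported mid-range bins.
default_lai_bins <- function() {
  data.frame(
    lower = 1:7,
    upper = 2:8,
    count = c(20, 13, 11, 11, 11, 12, 2)
  )
}

#' Sample per-plot leaf area index values
#'
#' Draws plot-level LAI (m2 leaf per m2 ground) either uniformly on a range or
#' from a piecewise-constant density over unit-width bins mimicking the skewed
#' field distribution of a heading-stage wheat trial (mass concentrated in
#' 1--3 with a secondary mode at 6--7).
#'
#' @param n Number of plots.
#' @param mode `"uniform"` or `"fig2_histogram"`.
#' @param range Length-2 (min, max) for uniform mode.
#' @param seed Integer seed.
#' @param bins Optional data.frame (`lower`, `upper`, `count`) replacing the
#'   default histogram table.
#' @return Numeric vector of `n` positive LAI values.
#' @export
#' @examples
#' lai <- sample_plot_lai(80, "fig2_histogram", seed = 1)
#' range(lai)
sample_plot_lai <- function(n, mode = c("fig2_histogram", "uniform"),
                            range = c(0.5, 8), seed = 1L, bins = NULL) {
  mode <- match.arg(mode)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  if (mode == "uniform") {
    if (length(range) != 2L || range[2] < range[1])
      stop("range must be (min, max) with min <= max", call. = FALSE)
    return(stats::runif(n, range[1], range[2]))
  }
  if (is.null(bins)) bins <- default_lai_bins()
  if (!all(c("lower", "upper", "count") %in% names(bins)) || nrow(bins) == 0L)
    stop("bins must have columns lower, upper, count", call. = FALSE)
  if (any(bins$upper <= bins$lower) || any(bins$count < 0) || sum(bins$count) <= 0)
    stop("invalid histogram bin table", call. = FALSE)
  which_bin <- sample.int(nrow(bins), n, replace = TRUE, prob = bins$count)
  stats::runif(n, bins$lower[which_bin], bins$upper[which_bin])
}

#' Generate a synthetic co-registered multi-sensor UAV scene
#'
#' Simulates the full sensor stack over the plot layout of `config`: five
#' multispectral reflectance bands, a thermal band (deg C), DSM and DEM
#' (meters), a ground-truth canopy/soil mask, and per-plot measured LAI.
#'
#' Within each plot of LAI `L`, the canopy covers fraction
#' `f = 1 - exp(-k * L)` of pixels, perturbed per plot on the logit scale by
#' `cover_logit_sd` (stand-density variation; realized cover is therefore an
#' imperfect LAI proxy). Canopy pixels are spatially clumped:
#' a smoothed Gaussian noise field is thresholded at the plot-specific
#' quantile `1 - f`, so cover is calibrated while patches stay coherent.
#' Canopy reflectance per band is `base + slope * L` plus a per-plot
#' deviation and per-pixel noise; soil pixels take `soil_reflectance` times a
#' per-plot brightness factor. Canopy height is
#' `height_intercept + height_slope * L` (DSM = DEM + height on canopy, DSM =
#' DEM on soil); canopy temperature is `temp_soil + temp_slope * L` plus
#' noise. Alleys and margins are bare soil. Reflectance outside \[0, 1\] is
#' clipped (a warning reports the count). Fully reproducible from
#' `config$seed`.
#'
#' @param config A [scene_config()].
#' @return An object of class `uav_scene`: a list with `bands` (named list of
#'   5 matrices), `thermal`, `dsm`, `dem`, `truth_mask` (integer matrix,
#'   1 = canopy, 0 = soil), `plots` (the layout with `lai_measured` filled),
#'   `geom` (pixel size, grid shape, origin), `crs_note` and `config`.
#'   Matrix row 1 is the northern edge.
#' @export
#' @examples
#' sc <- generate_scene(scene_config(n_plot_rows = 2, n_plot_cols = 2,
#'                                   pixel_size_m = 0.05))
#' sc
generate_scene <- function(config) {
  validate_scene_config(config)
  plots <- generate_plot_layout(config)
  n_plots <- nrow(plots)

  set.seed(subseed(config$seed, "lai"))
  plots$lai_measured <- sample_plot_lai(
    n_plots, mode = config$lai_mode, range = config$lai_range,
    seed = subseed(config$seed, "lai-values"), bins = config$lai_bins)

  px <- config$pixel_size_m
  field_w <- 2 * config$margin_m + config$n_plot_cols * config$plot_size_m +
    (config$n_plot_cols - 1) * config$alley_m
  field_h <- 2 * config$margin_m + config$n_plot_rows * config$plot_size_m +
    (config$n_plot_rows - 1) * config$alley_m
  ncol_px <- max(1L, ceiling(field_w / px))
  nrow_px <- max(1L, ceiling(field_h / px))
  geom <- list(nrow = nrow_px, ncol = ncol_px, pixel_size_m = px,
               xmin = 0, ymin = 0,
               xmax = ncol_px * px, ymax = nrow_px * px)

  set.seed(subseed(config$seed, "scene"))

  # spatially clumped canopy pattern: one smoothed noise field for the grid
  clump <- box_blur(matrix(stats::rnorm(nrow_px * ncol_px), nrow_px, ncol_px),
                    config$clump_scale_px)

  truth <- matrix(0L, nrow_px, ncol_px)
  plot_zone <- matrix(0L, nrow_px, ncol_px)  # 0 = alley/margin, else plot index

  cells <- lapply(seq_len(n_plots), function(i) {
    pixel_indices_in_rect(geom, plots$xmin[i], plots$ymin[i],
                          plots$xmax[i], plots$ymax[i])
  })
  # per-plot cover deviation (logit scale): stand density / emergence-rate
  # variation makes realized cover an imperfect proxy of LAI
  cover_eps <- stats::rnorm(n_plots, 0, config$cover_logit_sd)
  for (i in seq_len(n_plots)) {
    cell <- cells[[i]]
    if (length(cell$rows) == 0L || length(cell$cols) == 0L) next
    plot_zone[cell$rows, cell$cols] <- i
    f <- 1 - exp(-config$extinction_k * plots$lai_measured[i])
    if (config$cover_logit_sd > 0 && f > 0 && f < 1)
      f <- stats::plogis(stats::qlogis(f) + cover_eps[i])
    block <- clump[cell$rows, cell$cols, drop = FALSE]
    # exact-count assignment: the round(f * n) pixels with the highest
    # smoothed-noise values become canopy (spatially clumped patches)
    k <- round(f * length(block))
    canopy <- matrix(FALSE, nrow(block), ncol(block))
    if (k > 0L) canopy[order(block, decreasing = TRUE)[seq_len(k)]] <- TRUE
    truth[cell$rows, cell$cols] <- as.integer(canopy)
  }

  # per-plot heterogeneity: soil brightness, canopy reflectance deviation,
  # height and temperature offsets
  soil_factor_plot <- 1 + stats::rnorm(n_plots, 0, config$soil_brightness_sd)
  soil_factor_plot <- pmax(soil_factor_plot, 0.2)
  band_names <- c("blue", "green", "red", "rededge", "nir")
  refl_dev_plot <- matrix(stats::rnorm(n_plots * 5L, 0, config$plot_reflectance_sd),
                          n_plots, 5L, dimnames = list(NULL, band_names))
  height_dev_plot <- stats::rnorm(n_plots, 0, config$height_plot_sd_m)
  temp_dev_plot <- stats::rnorm(n_plots, 0, config$temp_plot_sd_c)
  temp_soil_dev_plot <- stats::rnorm(n_plots, 0, config$temp_soil_plot_sd_c)

  in_plot <- plot_zone > 0L
  zone_idx <- plot_zone[in_plot]
  lai_px <- numeric(length(zone_idx))
  lai_px <- plots$lai_measured[zone_idx]
  canopy_vec <- truth == 1L

  soil_factor_px <- matrix(1, nrow_px, ncol_px)
  soil_factor_px[in_plot] <- soil_factor_plot[zone_idx]

  n_clipped <- 0L
  bands <- vector("list", 5L)
  names(bands) <- band_names
  for (b in band_names) {
    soil_val <- config$soil_reflectance[[b]] * soil_factor_px
    val <- soil_val
    canopy_base <- matrix(0, nrow_px, ncol_px)
    canopy_base[in_plot] <- config$canopy_reflectance_base[[b]] +
      config$canopy_reflectance_slope[[b]] * lai_px +
      refl_dev_plot[zone_idx, b]
    val[canopy_vec] <- canopy_base[canopy_vec]
    if (config$noise_sd > 0)
      val <- val + matrix(stats::rnorm(nrow_px * ncol_px, 0, config$noise_sd),
                          nrow_px, ncol_px)
    out_of_range <- val < 0 | val > 1
    n_clipped <- n_clipped + sum(out_of_range)
    val[val < 0] <- 0
    val[val > 1] <- 1
    bands[[b]] <- val
  }
  if (n_clipped > 0L)
    warning(sprintf("%d reflectance value(s) clipped to [0, 1]", n_clipped),
            call. = FALSE)

  dem <- matrix(config$dem_base_m, nrow_px, ncol_px)
  height <- matrix(0, nrow_px, ncol_px)
  h_canopy <- matrix(0, nrow_px, ncol_px)
  h_canopy[in_plot] <- config$height_intercept_m +
    config$height_slope_m_per_lai * lai_px + height_dev_plot[zone_idx]
  height[canopy_vec] <- h_canopy[canopy_vec]
  if (config$height_noise_m > 0) {
    hn <- matrix(stats::rnorm(nrow_px * ncol_px, 0, config$height_noise_m),
                 nrow_px, ncol_px)
    height[canopy_vec] <- height[canopy_vec] + hn[canopy_vec]
  }
  height[height < 0] <- 0
  dsm <- dem + height

  thermal <- matrix(config$temp_soil_c, nrow_px, ncol_px)
  tsoil <- matrix(0, nrow_px, ncol_px)
  tsoil[in_plot] <- temp_soil_dev_plot[zone_idx]
  soil_vec <- in_plot & !canopy_vec
  thermal[soil_vec] <- thermal[soil_vec] + tsoil[soil_vec]
  tcan <- matrix(0, nrow_px, ncol_px)
  tcan[in_plot] <- config$temp_slope_c_per_lai * lai_px + temp_dev_plot[zone_idx]
  thermal[canopy_vec] <- thermal[canopy_vec] + tcan[canopy_vec]
  if (config$temp_noise_c > 0)
    thermal <- thermal + matrix(stats::rnorm(nrow_px * ncol_px, 0, config$temp_noise_c),
                                nrow_px, ncol_px)

  structure(list(
    bands = bands,
    thermal = thermal,
    dsm = dsm,
    dem = dem,
    truth_mask = truth,
    plots = plots,
    geom = geom,
    crs_note = "local metric grid, north-up; origin at field SW corner",
    config = config
  ), class = "uav_scene")
}

# Matrix row/column index ranges whose pixel centers fall inside the
# axis-aligned rectangle [xmin, xmax) x [ymin, ymax).
pixel_indices_in_rect <- function(geom, xmin, ymin, xmax, ymax) {
  px <- geom$pixel_size_m
  xc <- (seq_len(geom$ncol) - 0.5) * px
  yc <- geom$ymax - (seq_len(geom$nrow) - 0.5) * px  # row 1 = north
  list(rows = which(yc >= ymin & yc < ymax),
       cols = which(xc >= xmin & xc < xmax))
}

#' @export
print.uav_scene <- function(x, ...) {
  cat("Synthetic multi-sensor UAV scene\n")
  cat(sprintf("  grid: %d x %d px at %.4g m/px (%.1f x %.1f m)\n",
              x$geom$nrow, x$geom$ncol, x$geom$pixel_size_m,
              x$geom$ymax, x$geom$xmax))
  cat(sprintf("  layers: 5 reflectance bands, thermal (degC), DSM, DEM%s\n",
              if (!is.null(x$truth_mask)) ", truth mask" else ""))
  cat(sprintf("  plots: %d, measured LAI %.2f-%.2f\n",
              nrow(x$plots), min(x$plots$lai_measured),
              max(x$plots$lai_measured)))
  if (!is.null(x$truth_mask))
    cat(sprintf("  canopy cover: %.1f%% of pixels\n",
                100 * mean(x$truth_mask == 1L)))
  invisible(x)
}
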