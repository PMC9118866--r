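#' Configuration for a synthetic multi-sensor UAV scene
#'
#' Describes a rectangular grid of square field plots imaged by a UAV carrying
#' a five-band multispectral sensor, a long-wave thermal sensor, and a
#' photogrammetric height product (digital surface model, DSM, plus digital
#' elevation model, DEM). Every generative link is driven by the plot's leaf
#' area index (LAI): canopy cover follows a Beer-Lambert law
#' `f = 1 - exp(-k * LAI)`, canopy height and canopy temperature are linear
#' in LAI, and canopy reflectance ramps linearly in LAI per band (NIR
#' increasing, red decreasing).
#'
#' Between-plot heterogeneity terms (`soil_brightness_sd`,
#' `plot_reflectance_sd`, `height_plot_sd_m`, `temp_plot_sd_c`) model field
#' variability that does not average out within a plot: soil colour/moisture
#' patches and per-plot canopy condition. They are what makes soil-background
#' removal genuinely matter at plot level.
#'
#' @param n_plot_rows,n_plot_cols Number of plot rows/columns in the trial grid.
#' @param plot_size_m Side of each square plot in meters (default 2 m).
#' @param alley_m Width of the bare-soil alley separating plots, meters.
#' @param margin_m Bare-soil margin around the trial, meters.
#' @param pixel_size_m Ground sampling distance in meters per pixel
#'   (default 0.0149, i.e. 1.49 cm/pixel).
#' @param lai_range Numeric length-2, the (min, max) LAI used by
#'   `lai_mode = "uniform"`; min must be positive.
#' @param lai_mode `"fig2_histogram"` draws plot LAI from a piecewise-constant
#'   density over unit bins on 1--8 (see [sample_plot_lai()]), `"uniform"`
#'   draws i.i.d. uniform on `lai_range`.
#' @param lai_bins Optional data.frame with columns `lower`, `upper`, `count`
#'   overriding the default histogram table.
#' @param extinction_k Beer-Lambert extinction coefficient linking LAI to
#'   canopy cover fraction (default 0.5).
#' @param cover_logit_sd SD of the per-plot cover deviation on the logit
#'   scale (default 0.6). Field stands differ in emergence rate and density,
#'   so realized ground cover varies between plots of equal LAI; this is
#'   what makes exposed soil contamination rather than signal. Set to 0 for
#'   exactly Beer-law-calibrated cover.
#' @param canopy_reflectance_base,canopy_reflectance_slope Named 5-vectors
#'   (blue, green, red, rededge, nir): canopy reflectance at LAI = 0 and its
#'   change per unit LAI. All reflectances are unitless surface reflectance
#'   in \[0, 1\].
#' @param soil_reflectance Named 5-vector of bright-soil reflectance.
#' @param noise_sd Per-pixel reflectance noise standard deviation.
#' @param soil_brightness_sd SD of the per-plot multiplicative soil brightness
#'   factor (1 = nominal).
#' @param plot_reflectance_sd SD of the per-plot additive canopy reflectance
#'   deviation, applied independently per band.
#' @param temp_soil_c Soil surface temperature in deg C (default 32).
#' @param temp_slope_c_per_lai Change in canopy temperature per unit LAI,
#'   deg C (default -0.8: denser canopies transpire more and run cooler).
#' @param temp_noise_c Per-pixel thermal noise SD, deg C.
#' @param temp_plot_sd_c SD of the per-plot canopy temperature offset, deg C.
#' @param temp_soil_plot_sd_c SD of the per-plot soil temperature offset,
#'   deg C (default 1.5; soil surface temperature varies strongly with
#'   moisture patches).
#' @param height_intercept_m,height_slope_m_per_lai Canopy height model:
#'   height = intercept + slope * LAI, meters.
#' @param height_noise_m Per-pixel canopy height noise SD, meters.
#' @param height_plot_sd_m SD of the per-plot height deviation, meters.
#' @param dem_base_m Terrain elevation (flat), meters.
#' @param clump_scale_px Box-blur window (pixels) for the spatial noise field
#'   that clumps canopy pixels; larger values give coarser canopy patches.
#' @param seed Master integer seed; all stage seeds derive from it.
#'
#' @return An object of class `scene_config` (a validated list).
#' @seealso [generate_scene()], [generate_plot_layout()], [sample_plot_lai()]
#' @export
#' @examples
#' cfg <- scene_config(n_plot_rows = 2, n_plot_cols = 2, pixel_size_m = 0.05)
#' cfg$extinction_k
scene_config <- function(n_plot_rows = 8L,
                         n_plot_cols = 10L,
                         plot_size_m = 2.0,
                         alley_m = 0.5,
                         margin_m = 0.5,
                         pixel_size_m = 0.0149,
                         lai_range = c(0.5, 8.0),
                         lai_mode = c("fig2_histogram", "uniform"),
                         lai_bins = NULL,
                         extinction_k = 0.5,
                         cover_logit_sd = 0.6,
                         canopy_reflectance_base = c(blue = 0.040, green = 0.080,
                                                     red = 0.055, rededge = 0.220,
                                                     nir = 0.320),
                         canopy_reflectance_slope = c(blue = -0.0025, green = -0.0020,
                                                      red = -0.0040, rededge = 0.0080,
                                                      nir = 0.0350),
                         soil_reflectance = c(blue = 0.16, green = 0.20,
                                              red = 0.24, rededge = 0.27,
                                              nir = 0.30),
                         noise_sd = 0.01,
                         soil_brightness_sd = 0.15,
                         plot_reflectance_sd = 0.015,
                         temp_soil_c = 32.0,
                         temp_slope_c_per_lai = -0.8,
                         temp_noise_c = 0.3,
                         temp_plot_sd_c = 0.5,
                         temp_soil_plot_sd_c = 1.5,
                         height_intercept_m = 0.55,
                         height_slope_m_per_lai = 0.035,
                         height_noise_m = 0.02,
                         height_plot_sd_m = 0.03,
                         dem_base_m = 100.0,
                         clump_scale_px = 15L,
                         seed = 1L) {
  lai_mode <- match.arg(lai_mode)
  cfg <- list(
    n_plot_rows = as.integer(n_plot_rows),
    n_plot_cols = as.integer(n_plot_cols),
    plot_size_m = plot_size_m,
    alley_m = alley_m,
    margin_m = margin_m,
    pixel_size_m = pixel_size_m,
    lai_range = as.numeric(lai_range),
    lai_mode = lai_mode,
    lai_bins = lai_bins,
    extinction_k = extinction_k,
    cover_logit_sd = cover_logit_sd,
    canopy_reflectance_base = canopy_reflectance_base,
    canopy_reflectance_slope = canopy_reflectance_slope,
    soil_reflectance = soil_reflectance,
    noise_sd = noise_sd,
    soil_brightness_sd = soil_brightness_sd,
    plot_reflectance_sd = plot_reflectance_sd,
    temp_soil_c = temp_soil_c,
    temp_slope_c_per_lai = temp_slope_c_per_lai,
    temp_noise_c = temp_noise_c,
    temp_plot_sd_c = temp_plot_sd_c,
    temp_soil_plot_sd_c = temp_soil_plot_sd_c,
    height_intercept_m = height_intercept_m,
    height_slope_m_per_lai = height_slope_m_per_lai,
    height_noise_m = height_noise_m,
    height_plot_sd_m = height_plot_sd_m,
    dem_base_m = dem_base_m,
    clump_scale_px = as.integer(clump_scale_px),
    seed = as.integer(seed)
  )
  validate_scene_config(cfg)
  class(cfg) <- "scene_config"
  cfg
}

validate_scene_config <- function(cfg) {
  if (cfg$n_plot_rows < 1L || cfg$n_plot_cols < 1L)
    stop("n_plot_rows and n_plot_cols must be positive", call. = FALSE)
  if (cfg$plot_size_m <= 0 || cfg$pixel_size_m <= 0)
    stop("plot_size_m and pixel_size_m must be positive", call. = FALSE)
  if (cfg$plot_size_m / cfg$pixel_size_m < 10)
    stop("plots must span at least 10 pixels per side ",
         "(plot_size_m / pixel_size_m >= 10)", call. = FALSE)
  if (cfg$alley_m < 0 || cfg$margin_m < 0)
    stop("alley_m and margin_m must be non-negative", call. = FALSE)
  if (length(cfg$lai_range) != 2L || cfg$lai_range[1] <= 0 ||
      cfg$lai_range[2] < cfg$lai_range[1])
    stop("lai_range must be (min, max) with 0 < min <= max", call. = FALSE)
  band_names <- c("blue", "green", "red", "rededge", "nir")
  for (nm in c("canopy_reflectance_base", "soil_reflectance")) {
    v <- cfg[[nm]]
    if (length(v) != 5L || !all(band_names %in% names(v)))
      stop(nm, " must be a named 5-vector (blue, green, red, rededge, nir)",
           call. = FALSE)
    if (any(v < 0) || any(v > 1))
      stop(nm, " must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$extinction_k <= 0) stop("extinction_k must be positive", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  invisible(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  cat("Synthetic UAV scene configuration\n")
  cat(sprintf("  plots: %d x %d of %.2g m, alley %.2g m, margin %.2g m\n",
              x$n_plot_rows, x$n_plot_cols, x$plot_size_m, x$alley_m, x$margin_m))
  cat(sprintf("  pixel size: %.4g m  (plot spans %.0f px per side)\n",
              x$pixel_size_m, x$plot_size_m / x$pixel_size_m))
  cat(sprintf("  LAI: mode '%s', range [%.2g, %.2g], extinction k = %.2g\n",
              x$lai_mode, x$lai_range[1], x$lai_range[2], x$extinction_k))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
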