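# Feature rasters are plain numeric matrices; NA marks an undefined cell
# (zero denominator, masked soil, or propagated from an undefined parent).
# Zero denominators never produce Inf/NaN sentinels: they would silently
# corrupt zonal means downstream.

#' Registry of the fifteen vegetation-index formulas
#'
#' Named list mapping each vegetation index (VI) to its band-arithmetic
#' formula over blue (B), green (G), red (R), red-edge (RE) and
#' near-infrared (NIR) reflectance. Constants: the soil-adjustment term
#' L = 0.16 in OSAVI and the weighting a = 0.12 in WDRVI.
#'
#' Indices: RVI, GCI, RECI, NDVI, GNDVI, GRVI, NDRE, NDREI, SCCCI, OSAVI,
#' MCARI, TCARI, MCARI_OSAVI, TCARI_OSAVI, WDRVI.
#'
#' @return Named list of functions `f(B, G, R, RE, NIR)` operating
#'   element-wise; cells with a zero denominator (or an undefined parent
#'   index, e.g. SCCCI where NDVI = 0) evaluate to `NA`.
#' @export
#' @examples
#' reg <- vi_registry()
#' reg$NDVI(B = 0, G = 0, R = 0.1, RE = 0, NIR = 0.5)  # 0.4/0.6
vi_registry <- function() {
  list(
    RVI   = function(B, G, R, RE, NIR) safe_div(NIR, R),
    GCI   = function(B, G, R, RE, NIR) safe_div(NIR, G) - 1,
    RECI  = function(B, G, R, RE, NIR) safe_div(NIR, RE) - 1,
    NDVI  = function(B, G, R, RE, NIR) safe_div(NIR - R, NIR + R),
    GNDVI = function(B, G, R, RE, NIR) safe_div(NIR - G, NIR + G),
    GRVI  = function(B, G, R, RE, NIR) safe_div(G - R, G + R),
    NDRE  = function(B, G, R, RE, NIR) safe_div(NIR - RE, NIR + RE),
    NDREI = function(B, G, R, RE, NIR) safe_div(RE - G, RE + G),
    SCCCI = function(B, G, R, RE, NIR) {
      ndre <- safe_div(NIR - RE, NIR + RE)
      ndvi <- safe_div(NIR - R, NIR + R)
      safe_div(ndre, ndvi)
    },
    OSAVI = function(B, G, R, RE, NIR) safe_div(NIR - R, NIR + R + 0.16),
    MCARI = function(B, G, R, RE, NIR) ((RE - R) - 0.2 * (RE - G)) * safe_div(RE, R),
    TCARI = function(B, G, R, RE, NIR) 3 * ((RE - R) - 0.2 * (RE - G) * safe_div(RE, R)),
    MCARI_OSAVI = function(B, G, R, RE, NIR) {
      mcari <- ((RE - R) - 0.2 * (RE - G)) * safe_div(RE, R)
      osavi <- safe_div(NIR - R, NIR + R + 0.16)
      safe_div(mcari, osavi)
    },
    TCARI_OSAVI = function(B, G, R, RE, NIR) {
      tcari <- 3 * ((RE - R) - 0.2 * (RE - G) * safe_div(RE, R))
      osavi <- safe_div(NIR - R, NIR + R + 0.16)
      safe_div(tcari, osavi)
    },
    WDRVI = function(B, G, R, RE, NIR) safe_div(0.12 * NIR - R, 0.12 * NIR + R)
  )
}

# canonical feature names
vi_names <- function() names(vi_registry())
band_feature_names <- function() c("B", "G", "R", "RE", "NIR")
all_feature_names <- function() c(band_feature_names(), vi_names(), "CHM", "NRCT")

# map canonical band feature names to scene band list names
band_key <- c(B = "blue", G = "green", R = "red", RE = "rededge", NIR = "nir")

#' Compute a vegetation-index raster
#'
#' Evaluates the registry formula for `name` element-wise over a 5-band
#' reflectance stack. Cells with a zero denominator, or whose parent index is
#' undefined, are flagged `NA`.
#'
#' @param bands Named list of 5 reflectance matrices (`blue`, `green`, `red`,
#'   `rededge`, `nir`), or a `uav_scene`.
#' @param name One of the registry names, see [vi_registry()].
#' @return Numeric matrix with attribute `feature` set to `name`.
#' @export
#' @examples
#' b <- lapply(c(blue = .04, green = .08, red = .1, rededge = .2, nir = .5),
#'             function(v) matrix(v, 2, 2))
#' compute_vi(b, "NDVI")[1, 1]
compute_vi <- function(bands, name) {
  if (inherits(bands, "uav_scene")) bands <- bands$bands
  reg <- vi_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown vegetation index '%s'; valid names: %s",
                 name, paste(names(reg), collapse = ", ")), call. = FALSE)
  dims <- lapply(bands, dim)
  if (length(unique(dims)) != 1L)
    stop("bands must share the same shape", call. = FALSE)
  out <- reg[[name]](B = bands$blue, G = bands$green, R = bands$red,
                     RE = bands$rededge, NIR = bands$nir)
  attr(out, "feature") <- name
  out
}

#' Canopy height model from surface and terrain models
#'
#' CHM = DSM - DEM per cell, in meters. Negative cells (photogrammetric
#' noise putting the surface below the terrain) are clamped to 0; the clamp
#' count is recorded in attribute `n_clamped` and reported via a message.
#'
#' @param dsm,dem Matrices of identical shape (meters).
#' @return CHM matrix (meters) with attributes `feature = "CHM"` and
#'   `n_clamped`.
#' @export
compute_chm <- function(dsm, dem) {
  stop_if_not_matrix_pair(dsm, dem, "dsm", "dem")
  chm <- dsm - dem
  n_clamped <- sum(chm < 0, na.rm = TRUE)
  if (n_clamped > 0L) {
    message(sprintf("compute_chm: clamped %d negative cell(s) to 0", n_clamped))
    chm[!is.na(chm) & chm < 0] <- 0
  }
  attr(chm, "feature") <- "CHM"
  attr(chm, "n_clamped") <- n_clamped
  chm
}

#' Normalized relative canopy temperature (NRCT)
#'
#' `NRCT_i = (T_i - T_min) / (T_max - T_min)` where the baselines `T_min` and
#' `T_max` are the coolest and warmest temperatures over the chosen baseline
#' extent: the whole field (default) or the masked canopy only. Values lie in
#' \[0, 1\] over the baseline extent by construction (0 = coolest,
#' 1 = warmest).
#'
#' @param thermal Temperature matrix (deg C).
#' @param baseline_extent `"whole_field"` or `"masked_canopy"`.
#' @param mask `vegetation_mask` (or 0/1 matrix); required for
#'   `"masked_canopy"`.
#' @return NRCT matrix with attributes `feature = "NRCT"`, `t_min`, `t_max`.
#'   All-`NA` with a warning when the baseline extent has constant
#'   temperature (the index is then undefined).
#' @export
compute_nrct <- function(thermal,
                         baseline_extent = c("whole_field", "masked_canopy"),
                         mask = NULL) {
  baseline_extent <- match.arg(baseline_extent)
  base_vals <- if (baseline_extent == "whole_field") {
    thermal
  } else {
    if (is.null(mask))
      stop("baseline_extent = 'masked_canopy' requires a mask", call. = FALSE)
    m <- if (inherits(mask, "vegetation_mask")) mask$mask else mask
    stop_if_not_matrix_pair(thermal, m, "thermal", "mask")
    thermal[m == 1L]
  }
  t_min <- min(base_vals, na.rm = TRUE)
  t_max <- max(base_vals, na.rm = TRUE)
  if (!is.finite(t_min) || !is.finite(t_max) || t_max <= t_min) {
    warning("NRCT undefined: constant temperature over the baseline extent",
            call. = FALSE)
    out <- thermal
    out[] <- NA_real_
  } else {
    out <- (thermal - t_min) / (t_max - t_min)
  }
  attr(out, "feature") <- "NRCT"
  attr(out, "t_min") <- t_min
  attr(out, "t_max") <- t_max
  out
}

#' Mask soil pixels out of a feature raster
#'
#' Soil cells become undefined (`NA`); canopy cells are unchanged.
#'
#' @param raster Feature matrix.
#' @param mask A `vegetation_mask` or 0/1 matrix (1 = canopy).
#' @return Matrix of the same shape and attributes.
#' @export
apply_mask <- function(raster, mask) {
  m <- if (inherits(mask, "vegetation_mask")) mask$mask else mask
  stop_if_not_matrix_pair(raster, m, "raster", "mask")
  at <- attributes(raster)
  raster[m != 1L] <- NA_real_
  attributes(raster) <- at
  raster
}

#' Resample a raster by block means
#'
#' Aggregates the raster by `factor` in each dimension: each output cell is
#' the mean of the defined cells in its `factor x factor` block (trailing
#' partial blocks average over the available cells). Blocks with no defined
#' cell are undefined. Used to emulate coarser ground sampling distances
#' (e.g. degrading 1.49 cm/pixel imagery to 5 cm/pixel).
#'
#' @param raster Feature matrix.
#' @param factor Integer >= 2 aggregation factor.
#' @return Matrix of shape `ceiling(dim(raster) / factor)`.
#' @export
resample_block_mean <- function(raster, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2L)
    stop("factor must be an integer >= 2", call. = FALSE)
  rg <- ceiling(seq_len(nrow(raster)) / factor)
  cg <- ceiling(seq_len(ncol(raster)) / factor)
  ok <- !is.na(raster)
  vals <- raster
  vals[!ok] <- 0
  s <- rowsum(vals, rg, reorder = TRUE)
  s <- t(rowsum(t(s), cg, reorder = TRUE))
  n <- rowsum(ok + 0, rg, reorder = TRUE)
  n <- t(rowsum(t(n), cg, reorder = TRUE))
  out <- s / n
  out[n == 0] <- NA_real_
  dimnames(out) <- NULL
  attr(out, "feature") <- attr(raster, "feature")
  out
}

#' Compute any single feature raster of a scene
#'
#' Dispatcher over the 22 canonical features: the five raw bands (B, G, R,
#' RE, NIR), the fifteen vegetation indices, CHM, and NRCT.
#'
#' @param scene A `uav_scene`.
#' @param name Canonical feature name, see [all_features()].
#' @param nrct_extent Baseline extent passed to [compute_nrct()].
#' @param mask Optional mask, used only for the NRCT `"masked_canopy"`
#'   baseline (soil masking of the returned raster is the caller's job, via
#'   [apply_mask()]).
#' @return Feature matrix.
#' @export
compute_feature <- function(scene, name, nrct_extent = "whole_field",
                            mask = NULL) {
  if (name %in% band_feature_names()) {
    out <- scene$bands[[band_key[[name]]]]
    attr(out, "feature") <- name
    return(out)
  }
  if (name %in% vi_names()) return(compute_vi(scene$bands, name))
  if (name == "CHM") return(compute_chm(scene$dsm, scene$dem))
  if (name == "NRCT") return(compute_nrct(scene$thermal, nrct_extent, mask))
  stop(sprintf("unknown feature '%s'; valid names: %s",
               name, paste(all_feature_names(), collapse = ", ")),
       call. = FALSE)
}

#' Canonical feature names
#'
#' @return Character vector of the 22 feature names: 5 bands, 15 vegetation
#'   indices, CHM, NRCT.
#' @export
all_features <- function() all_feature_names()
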