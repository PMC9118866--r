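# Independent scalar oracle for the vegetation-index formulas: each index is
# transcribed directly from its printed band-arithmetic definition and
# evaluated one pixel at a time with explicit division guards. Kept separate
# from the package's vectorised registry so the two can be compared.

oracle_vi <- function(name, B, G, R, RE, NIR) {
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  switch(name,
    RVI = div(NIR, R),
    GCI = if (G == 0) NA_real_ else NIR / G - 1,
    RECI = if (RE == 0) NA_real_ else NIR / RE - 1,
    NDVI = div(NIR - R, NIR + R),
    GNDVI = div(NIR - G, NIR + G),
    GRVI = div(G - R, G + R),
    NDRE = div(NIR - RE, NIR + RE),
    NDREI = div(RE - G, RE + G),
    SCCCI = {
      ndre <- div(NIR - RE, NIR + RE)
      ndvi <- div(NIR - R, NIR + R)
      if (is.na(ndre) || is.na(ndvi) || ndvi == 0) NA_real_ else ndre / ndvi
    },
    OSAVI = div(NIR - R, NIR + R + 0.16),
    MCARI = if (R == 0) NA_real_ else ((RE - R) - 0.2 * (RE - G)) * (RE / R),
    TCARI = if (R == 0) NA_real_ else 3 * ((RE - R) - 0.2 * (RE - G) * (RE / R)),
    MCARI_OSAVI = {
      m <- if (R == 0) NA_real_ else ((RE - R) - 0.2 * (RE - G)) * (RE / R)
      o <- div(NIR - R, NIR + R + 0.16)
      if (is.na(m) || is.na(o) || o == 0) NA_real_ else m / o
    },
    TCARI_OSAVI = {
      tc <- if (R == 0) NA_real_ else 3 * ((RE - R) - 0.2 * (RE - G) * (RE / R))
      o <- div(NIR - R, NIR + R + 0.16)
      if (is.na(tc) || is.na(o) || o == 0) NA_real_ else tc / o
    },
    WDRVI = div(0.12 * NIR - R, 0.12 * NIR + R),
    stop("oracle has no index ", name)
  )
}

# A scene configuration with every stochastic term switched off; generative
# links (cover, reflectance ramps, height, temperature) become exact.
noiseless_config <- function(...) {
  scene_config(noise_sd = 0, soil_brightness_sd = 0, plot_reflectance_sd = 0,
               cover_logit_sd = 0, temp_noise_c = 0, temp_plot_sd_c = 0,
               temp_soil_plot_sd_c = 0, height_noise_m = 0,
               height_plot_sd_m = 0, ...)
}

# Small default-noise test scene (5 cm pixels keeps tests fast).
small_config <- function(n_plot_rows = 2, n_plot_cols = 3,
                         pixel_size_m = 0.05, ...) {
  scene_config(n_plot_rows = n_plot_rows, n_plot_cols = n_plot_cols,
               pixel_size_m = pixel_size_m, ...)
}

# Hand-built scene wrapper around explicit layer matrices, for toy cases
# where the generator would get in the way.
toy_scene <- function(bands, thermal = NULL, dsm = NULL, dem = NULL,
                      truth_mask = NULL, plots = NULL, pixel_size_m = 1) {
  nr <- nrow(bands[[1]]); nc <- ncol(bands[[1]])
  zero <- matrix(0, nr, nc)
  structure(list(
    bands = bands,
    thermal = if (is.null(thermal)) zero + 25 else thermal,
    dsm = if (is.null(dsm)) zero + 100 else dsm,
    dem = if (is.null(dem)) zero + 100 else dem,
    truth_mask = truth_mask,
    plots = plots,
    geom = list(nrow = nr, ncol = nc, pixel_size_m = pixel_size_m,
                xmin = 0, ymin = 0,
                xmax = nc * pixel_size_m, ymax = nr * pixel_size_m),
    crs_note = "toy", config = NULL
  ), class = "uav_scene")
}

# Random feature table where LAI is a known linear function of chosen
# columns plus Gaussian noise; remaining canonical features are pure noise.
synthetic_table <- function(n, beta = c(CHM = 2), intercept = 1, sigma = 0,
                            seed = 1, x_sd = 1) {
  set.seed(seed)
  feats <- all_features()
  tab <- as.data.frame(setNames(
    lapply(feats, function(f) stats::rnorm(n, 0, x_sd)), feats))
  y <- rep(intercept, n)
  for (v in names(beta)) y <- y + beta[[v]] * tab[[v]]
  tab$lai_measured <- y + stats::rnorm(n, 0, sigma)
  tab$plot_id <- sprintf("P%03d", seq_len(n))
  tab
}
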