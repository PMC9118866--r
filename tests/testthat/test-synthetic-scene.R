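test_that("plot layout produces the designed grid of disjoint square plots", {
  cfg <- scene_config(n_plot_rows = 8, n_plot_cols = 10, pixel_size_m = 0.05)
  layout <- generate_plot_layout(cfg)
  expect_equal(nrow(layout), 80)
  expect_true(all((layout$xmax - layout$xmin) == 2))
  expect_true(all((layout$ymax - layout$ymin) == 2))

  single <- generate_plot_layout(scene_config(n_plot_rows = 1, n_plot_cols = 1,
                                              pixel_size_m = 0.05))
  expect_equal(nrow(single), 1)
  expect_equal((single$xmax - single$xmin) * (single$ymax - single$ymin), 4)

  # brute-force pairwise rectangle intersection areas
  four <- generate_plot_layout(scene_config(n_plot_rows = 2, n_plot_cols = 2,
                                            alley_m = 0.5, pixel_size_m = 0.05))
  expect_equal(nrow(four), 4)
  overlap <- function(a, b) {
    w <- max(0, min(a$xmax, b$xmax) - max(a$xmin, b$xmin))
    h <- max(0, min(a$ymax, b$ymax) - max(a$ymin, b$ymin))
    w * h
  }
  for (i in 1:3) for (j in (i + 1):4)
    expect_identical(overlap(four[i, ], four[j, ]), 0)

  expect_error(scene_config(n_plot_rows = 0, pixel_size_m = 0.05), "positive")
})

test_that("LAI sampling matches its target distribution and is reproducible", {
  x <- sample_plot_lai(4000, "fig2_histogram", seed = 3)
  expect_true(all(x > 0 & x <= 8))
  # bin 1-2 holds 20/80 of the mass; binomial 3-sigma band around 0.25
  p12 <- mean(x >= 1 & x < 2)
  expect_lt(abs(p12 - 20 / 80), 3 * sqrt(0.25 * 0.75 / 4000))

  expect_equal(sample_plot_lai(5, "uniform", range = c(3, 3), seed = 1),
               rep(3, 5))

  u <- sample_plot_lai(10000, "uniform", range = c(0.5, 8), seed = 2)
  expect_lt(abs(mean(u) - 4.25), 0.1)

  expect_identical(sample_plot_lai(80, "fig2_histogram", seed = 9),
                   sample_plot_lai(80, "fig2_histogram", seed = 9))
  expect_error(sample_plot_lai(0, "uniform"), ">= 1")
})

test_that("scene generation is bit-identical under a fixed seed", {
  cfg <- small_config(seed = 5)
  a <- suppressWarnings(generate_scene(cfg))
  b <- suppressWarnings(generate_scene(cfg))
  expect_identical(a$bands, b$bands)
  expect_identical(a$thermal, b$thermal)
  expect_identical(a$dsm, b$dsm)
  expect_identical(a$truth_mask, b$truth_mask)
  expect_identical(a$plots, b$plots)
})

test_that("near-zero LAI yields an all-soil plot with DSM = DEM", {
  cfg <- noiseless_config(n_plot_rows = 1, n_plot_cols = 1,
                          pixel_size_m = 0.05, lai_mode = "uniform",
                          lai_range = c(1e-9, 1e-9), seed = 2)
  sc <- generate_scene(cfg)
  expect_equal(sum(sc$truth_mask), 0)
  expect_equal(sc$dsm, sc$dem)
})

test_that("realized canopy cover is Beer-law calibrated when cover noise is off", {
  # 2 m plots at 1.49 cm/px give ~1.8e4 pixels per plot
  cfg <- noiseless_config(n_plot_rows = 1, n_plot_cols = 3,
                          pixel_size_m = 0.0149, lai_mode = "uniform",
                          lai_range = c(4, 4), extinction_k = 0.5, seed = 4)
  sc <- generate_scene(cfg)
  for (i in seq_len(nrow(sc$plots))) {
    cell <- uavlai:::pixel_indices_in_rect(sc$geom, sc$plots$xmin[i],
                                           sc$plots$ymin[i], sc$plots$xmax[i],
                                           sc$plots$ymax[i])
    block <- sc$truth_mask[cell$rows, cell$cols]
    expect_gt(length(block), 1e4)
    expect_lt(abs(mean(block) - (1 - exp(-2))), 0.02)
  }
})

test_that("noiseless generative links are exact and monotone in LAI", {
  cfg <- noiseless_config(n_plot_rows = 2, n_plot_cols = 4,
                          pixel_size_m = 0.05, lai_mode = "uniform",
                          lai_range = c(1, 7), seed = 8)
  sc <- generate_scene(cfg)
  soil <- sc$truth_mask == 0L
  expect_true(all(sc$dsm[soil] == sc$dem[soil]))

  per_plot <- function(layer) {
    vapply(seq_len(nrow(sc$plots)), function(i) {
      cell <- uavlai:::pixel_indices_in_rect(sc$geom, sc$plots$xmin[i],
                                             sc$plots$ymin[i], sc$plots$xmax[i],
                                             sc$plots$ymax[i])
      vals <- layer[cell$rows, cell$cols]
      canopy <- sc$truth_mask[cell$rows, cell$cols] == 1L
      mean(vals[canopy])
    }, numeric(1))
  }
  ord <- order(sc$plots$lai_measured)
  expect_true(all(diff(per_plot(sc$bands$nir)[ord]) > 0))
  expect_true(all(diff(per_plot(sc$thermal)[ord]) < 0))
  # canopy height equals the linear height model exactly
  h <- per_plot(sc$dsm - sc$dem)
  expect_equal(h, cfg$height_intercept_m +
                 cfg$height_slope_m_per_lai * sc$plots$lai_measured,
               tolerance = 1e-12)
})

test_that("alleys and margins are bare soil", {
  sc <- suppressWarnings(generate_scene(small_config(seed = 3)))
  in_plot <- matrix(FALSE, sc$geom$nrow, sc$geom$ncol)
  for (i in seq_len(nrow(sc$plots))) {
    cell <- uavlai:::pixel_indices_in_rect(sc$geom, sc$plots$xmin[i],
                                           sc$plots$ymin[i], sc$plots$xmax[i],
                                           sc$plots$ymax[i])
    in_plot[cell$rows, cell$cols] <- TRUE
  }
  expect_true(all(sc$truth_mask[!in_plot] == 0L))
})
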