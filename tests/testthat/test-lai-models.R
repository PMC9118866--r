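test_that("train/test splitting is sized, disjoint, exhaustive and reproducible", {
  tab <- synthetic_table(80)
  spl <- split_train_test(tab, 0.7, seed = 1)
  expect_equal(nrow(spl$train), 56)
  expect_equal(nrow(spl$test), 24)

  tab10 <- synthetic_table(10)
  s <- split_train_test(tab10, 0.5, seed = 2)
  expect_equal(nrow(s$train), 5)
  expect_setequal(c(s$train$plot_id, s$test$plot_id), tab10$plot_id)
  expect_length(intersect(s$train$plot_id, s$test$plot_id), 0)

  expect_identical(split_train_test(tab, 0.7, seed = 3)$train$plot_id,
                   split_train_test(tab, 0.7, seed = 3)$train$plot_id)
  expect_error(split_train_test(tab[1:4, ], 0.7), "at least 5")
})

test_that("R2 and RMSE reproduce their defining formulas on hand cases", {
  m <- c(1, 2, 3)
  expect_equal(r_squared(m, m), 1)
  expect_equal(rmse(m, m), 0)
  expect_equal(r_squared(m, rep(mean(m), 3)), 0)
  expect_equal(rmse(m, c(1, 2, 4)), sqrt(1 / 3))
  expect_equal(r_squared(m, c(1, 2, 4)), 0.5)
  # worse than the mean predictor -> negative R2
  expect_lt(r_squared(m, c(3, 2, 1)), 0)
  expect_warning(r2 <- r_squared(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r2))
})

test_that("R2 is affine-invariant and RMSE scales linearly", {
  set.seed(5)
  m <- runif(30, 1, 8)
  p <- m + rnorm(30, 0, 0.5)
  expect_equal(r_squared(2 * m + 3, 2 * p + 3), r_squared(m, p))
  expect_equal(rmse(2 * m + 3, 2 * p + 3), 2 * rmse(m, p))
})

test_that("MLR recovers an exact linear relationship and RFR approximates it", {
  tab <- synthetic_table(40, beta = c(CHM = 2), intercept = 1, sigma = 0,
                         seed = 3, x_sd = 1)
  spl <- split_train_test(tab, 0.7, seed = 1)
  res <- fit_predict("mlr", spl$train, spl$test, features = "CHM")
  expect_equal(unname(coef(res$fit)["(Intercept)"]), 1, tolerance = 1e-8)
  expect_equal(unname(coef(res$fit)["CHM"]), 2, tolerance = 1e-8)
  expect_equal(res$r2, 1, tolerance = 1e-10)

  res_rf <- fit_predict("rfr", spl$train, spl$test, features = "CHM", seed = 4)
  expect_gte(res_rf$r2, 0.9)
})

test_that("label permutation destroys predictive skill", {
  r2s <- vapply(1:20, function(s) {
    tab <- synthetic_table(50, beta = c(CHM = 2), sigma = 0.2, seed = s)
    set.seed(s + 500)
    tab$lai_measured <- sample(tab$lai_measured)
    spl <- split_train_test(tab, 0.7, seed = s)
    fit_predict("rfr", spl$train, spl$test, seed = s)$r2
  }, numeric(1))
  expect_lte(mean(r2s), 0.2)
})

test_that("MLR coefficients converge to generative truth at large n", {
  n <- 1000; sigma <- 0.5
  beta <- c(CHM = 1.5, NRCT = -0.8, NDVI = 0.6)
  tab <- synthetic_table(n, beta = beta, intercept = 2, sigma = sigma,
                         seed = 11, x_sd = 2)
  fit <- lai_fit(tab, "mlr", features = names(beta))
  est <- coef(fit)
  bound <- 2 * sigma / sqrt(n)
  expect_lt(abs(est[["(Intercept)"]] - 2), bound)
  for (v in names(beta)) expect_lt(abs(est[[v]] - beta[[v]]), bound)
})

test_that("rank-deficient MLR designs fall back to a smallest-norm solution", {
  tab <- synthetic_table(20, beta = c(CHM = 2), seed = 8)
  tab$NRCT <- tab$CHM  # perfectly collinear
  expect_warning(fit <- lai_fit(tab, "mlr", features = c("CHM", "NRCT")),
                 "rank-deficient")
  expect_false(anyNA(coef(fit)))
  expect_equal(unname(predict(fit, tab)), tab$lai_measured, tolerance = 1e-6)
})

test_that("importance ranks the driving feature first and normalizes to one", {
  tab <- synthetic_table(60, beta = c(CHM = 3), sigma = 0.1, seed = 21)
  for (method in c("rfr", "svr")) {
    fit <- lai_fit(tab, method, seed = 5)
    imp <- importance(fit)
    expect_equal(sum(imp), 1, tolerance = 1e-9)
    expect_true(all(imp >= 0))
    expect_equal(names(imp)[1], "CHM", label = method)
  }
  expect_error(importance(lai_fit(tab, "mlr")), "not defined")
})

test_that("all-noise features yield near-uniform importance", {
  max_scores <- vapply(1:8, function(s) {
    tab <- synthetic_table(40, beta = c(CHM = 0), sigma = 1, seed = s)
    feats <- all_features()[1:20]
    max(importance(lai_fit(tab, "rfr", features = feats, seed = s)))
  }, numeric(1))
  expect_lte(mean(max_scores), 0.2)
})

test_that("common_top_k intersects rankings and orders by mean rank", {
  feats <- all_features()
  ra <- setNames(rev(seq_along(feats)) / sum(seq_along(feats)), feats)
  expect_equal(common_top_k(ra, ra, k = 10), names(ra)[1:10])

  rb <- setNames(seq_along(feats) / sum(seq_along(feats)), feats)
  expect_length(common_top_k(ra, rb, k = 5), 0)

  # rankings built to mimic the two models' published top-10 lists:
  # intersection is exactly {CHM, B, NRCT, NDRE} (B = blue band)
  rfr_top <- c("CHM", "NDREI", "NIR", "B", "NRCT", "NDRE", "GNDVI", "OSAVI",
               "RVI", "GRVI")
  svr_top <- c("CHM", "NRCT", "RECI", "GCI", "NDRE", "B", "WDRVI", "MCARI",
               "TCARI", "SCCCI")
  rank_of <- function(top) c(top, setdiff(feats, top))
  common <- common_top_k(rank_of(rfr_top), rank_of(svr_top), k = 10)
  expect_setequal(common, c("CHM", "B", "NRCT", "NDRE"))
  expect_equal(common[1], "CHM")  # rank 1 in both

  expect_warning(common_top_k(ra, rb, k = 99), "clipping")
})

test_that("the published four-variable model evaluates as printed", {
  m <- published_lai_model()
  at <- function(B = 0, NDRE = 0, NRCT = 0, CHM = 0)
    predict(m, data.frame(B = B, NDRE = NDRE, NRCT = NRCT, CHM = CHM))
  expect_equal(at(), 12.92)
  expect_equal(at(CHM = 1), 22.41)
  expect_equal(at(B = 0.01), 9.0135)
  # vectorized evaluation
  expect_equal(at(B = c(0, 0.01)), c(12.92, 9.0135))
})

test_that("prediction maps agree with the model and respect the soil mask", {
  b <- lapply(c(blue = 0.03, green = 0.08, red = 0.05, rededge = 0.25,
                nir = 0.45), function(v) matrix(v, 4, 4))
  sc <- toy_scene(b, thermal = matrix(seq(20, 30, length.out = 16), 4, 4),
                  dsm = matrix(100.6, 4, 4), dem = matrix(100, 4, 4))
  map <- prediction_map(sc, mask = NULL)
  ndre <- (0.45 - 0.25) / (0.45 + 0.25)
  nrct <- (sc$thermal - 20) / 10
  want <- 12.92 - 390.65 * 0.03 - 12.14 * ndre - 3.2 * nrct + 9.49 * 0.6
  expect_equal(unclass(map), unclass(want), tolerance = 1e-12,
               ignore_attr = TRUE)

  all_soil <- matrix(0L, 4, 4)
  expect_true(all(is.na(prediction_map(sc, mask = all_soil))))
})

test_that("per-pixel linear predictions commute with plot-mean features", {
  sc <- suppressWarnings(generate_scene(small_config(seed = 14)))
  tab <- build_feature_table(sc)
  model <- published_lai_model()
  map <- prediction_map(sc, mask = NULL)
  map_means <- zonal_mean(map, sc$plots, sc$geom)
  plot_preds <- predict(model, tab)
  expect_equal(map_means$mean[match(tab$plot_id, map_means$plot_id)],
               plot_preds, tolerance = 1e-9)
})

test_that("the combination experiment fills its 16-cell design under one split", {
  sc <- suppressWarnings(generate_scene(small_config(n_plot_rows = 3,
                                                     n_plot_cols = 3,
                                                     seed = 17)))
  px <- sample_training_pixels(sc, 300, seed = 2)
  mask <- train_and_classify(sc, px$train)
  tm <- suppressMessages(build_feature_table(sc, mask = mask))
  tu <- suppressMessages(build_feature_table(sc))
  ex <- run_combination_experiment(tm, tu, seed = 6)
  expect_equal(nrow(ex), 16)
  expect_equal(sort(unique(ex$soil_background)), c("removed", "retained"))
  expect_equal(sort(unique(ex$feature_set)),
               sort(c("Sp", "Sp+Th", "Sp+St", "Sp+St+Th")))
  expect_true(all(ex$rmse >= 0))
  # one shared split across cells
  expect_length(attr(ex, "test_ids"), round(0.3 * nrow(tm)))
})
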