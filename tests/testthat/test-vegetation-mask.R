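test_that("training pixel sampling honours counts, determinism and errors", {
  sc <- suppressWarnings(generate_scene(small_config(seed = 1)))
  px <- sample_training_pixels(sc, 500, seed = 7)
  expect_equal(nrow(px$train), 1000)
  expect_equal(as.vector(table(px$train$class)), c(500, 500))
  expect_length(intersect(px$train$index, px$test$index), 0)

  px2 <- sample_training_pixels(sc, 500, seed = 7)
  expect_identical(px$train$index, px2$train$index)

  all_soil <- sc
  all_soil$truth_mask[] <- 0L
  expect_error(sample_training_pixels(all_soil, 10), "canopy has 0 pixels")
})

test_that("a separable noiseless scene is classified exactly", {
  sc <- generate_scene(noiseless_config(n_plot_rows = 2, n_plot_cols = 2,
                                        pixel_size_m = 0.05, seed = 2))
  px <- sample_training_pixels(sc, 200, seed = 1)
  mask <- train_and_classify(sc, px$train)
  expect_identical(mask$mask, sc$truth_mask)
})

test_that("default-noise masking reaches high held-out accuracy and transfers across scenes", {
  cfg_a <- scene_config(n_plot_rows = 2, n_plot_cols = 3,
                        pixel_size_m = 0.05, seed = 11)
  cfg_b <- cfg_a; cfg_b$seed <- 12L
  sc_a <- suppressWarnings(generate_scene(cfg_a))
  sc_b <- suppressWarnings(generate_scene(cfg_b))
  px_a <- sample_training_pixels(sc_a, 500, seed = 3)
  mask_a <- train_and_classify(sc_a, px_a$train)
  oa_within <- overall_accuracy(confusion_matrix(mask_a, sc_a$truth_mask, px_a$test))
  expect_gte(oa_within, 0.95)

  # same classifier applied to an independently drawn scene with the same
  # generative parameters
  px_b <- sample_training_pixels(sc_b, 500, seed = 4)
  pred_b <- stats::predict(mask_a$model,
                           uavlai:::pixel_features(sc_b, px_b$test$index))
  oa_cross <- mean((pred_b == "canopy") == (sc_b$truth_mask[px_b$test$index] == 1L))
  expect_lt(abs(oa_cross - oa_within), 0.02)
})

test_that("degenerate training still returns a classifier, with a warning", {
  # blue varies by row (rows 1 and 3 identical), the other bands by column,
  # so pixels (1,1) and (3,1) share a feature vector but carry both labels
  row_pat <- c(0.1, 0.2, 0.1, 0.2)
  col_pat <- seq(0.1, 0.4, length.out = 4)
  b <- list(blue = matrix(row_pat, 4, 4),
            green = matrix(col_pat, 4, 4, byrow = TRUE),
            red = matrix(col_pat + 0.1, 4, 4, byrow = TRUE),
            rededge = matrix(col_pat + 0.2, 4, 4, byrow = TRUE),
            nir = matrix(col_pat + 0.3, 4, 4, byrow = TRUE))
  sc <- toy_scene(b)
  training <- data.frame(index = c(1L, 6L, 3L, 8L),
                         class = factor(c("canopy", "canopy", "soil", "soil"),
                                        levels = c("soil", "canopy")))
  expect_warning(m <- train_and_classify(sc, training), "degenerate")
  expect_s3_class(m, "vegetation_mask")
})

test_that("confusion matrix counts evaluated pixels as specified", {
  truth <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 1L, 0L), 2, 5)
  perfect <- truth
  ev <- data.frame(index = 1:10)
  cm <- confusion_matrix(perfect, truth, ev)
  expect_equal(cm[1, 2] + cm[2, 1], 0)
  expect_equal(sum(cm), 10)

  inverted <- 1L - truth
  cmi <- confusion_matrix(inverted, truth, ev)
  expect_equal(cmi[1, 1] + cmi[2, 2], 0)

  one_err <- truth
  one_err[1] <- 1L - one_err[1]
  cm1 <- confusion_matrix(one_err, truth, ev)
  expect_equal(cm1[1, 2] + cm1[2, 1], 1)

  expect_error(confusion_matrix(perfect, truth, ev[0, , drop = FALSE]),
               "empty")
})

test_that("overall accuracy and kappa reproduce hand-computed cases", {
  as_cm <- function(m) {
    dimnames(m) <- list(truth = c("soil", "canopy"),
                        predicted = c("soil", "canopy"))
    structure(as.table(m), class = c("confusion_matrix", "table"))
  }
  perfect <- as_cm(matrix(c(50, 0, 0, 50), 2, byrow = TRUE))
  expect_equal(overall_accuracy(perfect), 1)
  expect_equal(kappa_coefficient(perfect), 1)

  chance <- as_cm(matrix(c(25, 25, 25, 25), 2, byrow = TRUE))
  expect_equal(overall_accuracy(chance), 0.5)
  expect_equal(kappa_coefficient(chance), 0)

  # p_o = 0.85, p_e = 0.5 -> kappa = 0.70
  hand <- as_cm(matrix(c(45, 5, 10, 40), 2, byrow = TRUE))
  expect_equal(overall_accuracy(hand), 0.85)
  expect_equal(kappa_coefficient(hand), 0.70)

  degenerate <- as_cm(matrix(c(100, 0, 0, 0), 2, byrow = TRUE))
  expect_warning(k <- kappa_coefficient(degenerate), "undefined")
  expect_true(is.na(k))
})

test_that("accuracy statistics are invariant to a consistent label swap", {
  truth <- matrix(rbinom(400, 1, 0.4), 20, 20)
  mask <- truth
  flip <- sample(400, 60)
  mask[flip] <- 1L - mask[flip]
  ev <- data.frame(index = 1:400)
  cm <- confusion_matrix(mask, truth, ev)
  cm_swapped <- confusion_matrix(1L - mask, 1L - truth, ev)
  expect_equal(overall_accuracy(cm), overall_accuracy(cm_swapped))
  expect_equal(kappa_coefficient(cm), kappa_coefficient(cm_swapped))
  # masking conservation
  expect_equal(sum(mask == 1L), length(mask) - sum(mask == 0L))
})
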