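#' Model-comparison experiment over feature sets and soil-mask conditions
#'
#' Runs the full factorial comparison behind the pipeline's results table:
#' soil background removed vs retained (masked vs unmasked feature tables),
#' times regression method, times feature-set combination (spectral only,
#' spectral+thermal, spectral+structural, all three). One shared train/test
#' split (by plot id) is applied to every cell so that feature-set and mask
#' effects are not confounded with split noise.
#'
#' @param table_masked,table_unmasked Feature tables from
#'   [build_feature_table()] with and without the soil mask; they must share
#'   plot ids (plots dropped from the masked table are excluded everywhere).
#' @param methods Regression methods, default `c("rfr", "svr")`.
#' @param sets List of feature-set group vectors, default
#'   `list("Sp", c("Sp","Th"), c("Sp","St"), c("Sp","St","Th"))`.
#' @param train_fraction,seed Split specification (70/30 by default).
#' @return Data.frame of class `lai_experiment` with one row per cell:
#'   `soil_background` ("removed"/"retained"), `method`, `feature_set`,
#'   `r2`, `rmse`; the full `lai_model_result` objects are in attribute
#'   `results`.
#' @export
run_combination_experiment <- function(table_masked, table_unmasked,
                                       methods = c("rfr", "svr"),
                                       sets = list("Sp", c("Sp", "Th"),
                                                   c("Sp", "St"),
                                                   c("Sp", "St", "Th")),
                                       train_fraction = 0.7, seed = 1L) {
  common_ids <- intersect(table_masked$plot_id, table_unmasked$plot_id)
  if (length(common_ids) < 5L)
    stop("masked and unmasked tables share fewer than 5 plots", call. = FALSE)
  tm <- table_masked[match(common_ids, table_masked$plot_id), , drop = FALSE]
  tu <- table_unmasked[match(common_ids, table_unmasked$plot_id), , drop = FALSE]

  split <- split_train_test(data.frame(plot_id = common_ids), train_fraction,
                            seed = subseed(seed, "split"))
  train_ids <- split$train$plot_id
  test_ids <- split$test$plot_id

  rows <- list()
  results <- list()
  for (mask_cond in c("removed", "retained")) {
    tab <- if (mask_cond == "removed") tm else tu
    train <- tab[match(train_ids, tab$plot_id), , drop = FALSE]
    test <- tab[match(test_ids, tab$plot_id), , drop = FALSE]
    for (method in methods) {
      for (groups in sets) {
        label <- paste(groups, collapse = "+")
        res <- fit_predict(method, train, test,
                           features = feature_set(groups),
                           seed = subseed(seed, paste(mask_cond, method, label)))
        key <- paste(mask_cond, method, label, sep = "|")
        results[[key]] <- res
        rows[[key]] <- data.frame(soil_background = mask_cond,
                                  method = toupper(method),
                                  feature_set = label,
                                  r2 = res$r2, rmse = res$rmse,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  attr(out, "train_ids") <- train_ids
  attr(out, "test_ids") <- test_ids
  class(out) <- c("lai_experiment", "data.frame")
  out
}

#' Common features in the top k of two importance rankings
#'
#' Intersects the top-`k` features of two importance rankings (e.g. from the
#' random-forest and support-vector models) and orders the intersection by
#' mean rank across the two. This is the feature-selection step that reduces
#' the 22-feature fusion model to a handful of variables for a simple linear
#' model.
#'
#' @param rank_a,rank_b Named numeric importance vectors (sorted or not) or
#'   character vectors already in rank order. Must cover the same feature
#'   universe.
#' @param k Depth of each ranking to intersect (default 10). Clipped with a
#'   warning if larger than the number of features.
#' @return Character vector of common features, ordered by mean rank.
#' @export
common_top_k <- function(rank_a, rank_b, k = 10L) {
  as_ranked <- function(r) {
    if (is.character(r)) return(r)
    names(r)[order(-r, names(r))]
  }
  a <- as_ranked(rank_a)
  b <- as_ranked(rank_b)
  if (!setequal(a, b))
    stop("rankings must cover the same feature universe", call. = FALSE)
  if (k > length(a)) {
    warning(sprintf("k = %d exceeds the %d features; clipping", k, length(a)),
            call. = FALSE)
    k <- length(a)
  }
  common <- intersect(a[seq_len(k)], b[seq_len(k)])
  mean_rank <- (match(common, a) + match(common, b)) / 2
  common[order(mean_rank, common)]
}

#' The published four-variable linear LAI model
#'
#' The fixed multiple linear regression over the four variables common to the
#' top-10 importance rankings of both machine-learning models (blue-band
#' reflectance B, NDRE, NRCT, CHM):
#'
#' `LAI = -390.65 * B - 12.14 * NDRE - 3.2 * NRCT + 9.49 * CHM + 12.92`
#'
#' Coefficients are hard-coded as published; `B` is blue-band surface
#' reflectance in \[0, 1\], `CHM` in meters, `NDRE` and `NRCT` dimensionless.
#'
#' @return Object of class `lai_mlr` with elements `intercept` and named
#'   `coefficients`; supports `predict()` on a data.frame (or named list)
#'   with columns `B`, `NDRE`, `NRCT`, `CHM`, and [prediction_map()].
#' @export
#' @examples
#' m <- published_lai_model()
#' predict(m, data.frame(B = 0, NDRE = 0, NRCT = 0, CHM = 0))  # intercept
published_lai_model <- function() {
  structure(list(
    intercept = 12.92,
    coefficients = c(B = -390.65, NDRE = -12.14, NRCT = -3.2, CHM = 9.49)
  ), class = "lai_mlr")
}

#' Construct a linear LAI model from explicit coefficients
#'
#' @param intercept Intercept in LAI units.
#' @param coefficients Named numeric vector; names must be canonical feature
#'   names (see [all_features()]).
#' @return Object of class `lai_mlr`.
#' @export
lai_mlr_model <- function(intercept, coefficients) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("coefficients must be named", call. = FALSE)
  bad <- setdiff(names(coefficients), all_feature_names())
  if (length(bad))
    stop("unknown feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients),
            class = "lai_mlr")
}

#' @export
predict.lai_mlr <- function(object, newdata, ...) {
  vars <- names(object$coefficients)
  missing_vars <- setdiff(vars, names(newdata))
  if (length(missing_vars))
    stop("newdata lacks: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  out <- rep(object$intercept, length(newdata[[vars[1L]]]))
  for (v in vars) out <- out + object$coefficients[[v]] * newdata[[v]]
  out
}

#' @export
print.lai_mlr <- function(x, ...) {
  terms <- sprintf("%+.4g*%s", x$coefficients, names(x$coefficients))
  cat("Linear LAI model:\n  LAI =", paste(terms, collapse = " "),
      sprintf("%+.4g\n", x$intercept))
  invisible(x)
}

#' @export
coef.lai_mlr <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Per-pixel LAI prediction map from a linear model
#'
#' Evaluates a linear LAI model (`lai_mlr`, e.g. [published_lai_model()] or a
#' refit from [as_lai_mlr()]) at every canopy pixel of a scene, using the
#' per-pixel feature rasters named by the model's coefficients. Soil pixels
#' (and pixels with any undefined feature) are nodata (`NA`).
#'
#' @param scene A `uav_scene`.
#' @param mask Optional `vegetation_mask` or 0/1 matrix; when `NULL` every
#'   pixel is evaluated.
#' @param model An `lai_mlr` object (default: the published four-variable
#'   model).
#' @param nrct_extent NRCT baseline extent (see [compute_nrct()]).
#' @return Matrix of predicted LAI with `NA` at soil/nodata pixels.
#' @export
prediction_map <- function(scene, mask = NULL, model = published_lai_model(),
                           nrct_extent = "whole_field") {
  vars <- names(model$coefficients)
  out <- matrix(model$intercept, scene$geom$nrow, scene$geom$ncol)
  for (v in vars) {
    r <- compute_feature(scene, v, nrct_extent = nrct_extent, mask = mask)
    out <- out + model$coefficients[[v]] * r
  }
  if (!is.null(mask)) out <- apply_mask(out, mask)
  attr(out, "feature") <- "LAI_pred"
  out
}

#' Convert a fitted MLR `lai_fit` into a portable linear model
#'
#' @param fit An MLR [lai_fit()] object.
#' @return An `lai_mlr` with the same intercept and coefficients.
#' @export
as_lai_mlr <- function(fit) {
  if (!inherits(fit, "lai_fit") || fit$method != "mlr")
    stop("fit must be an MLR lai_fit", call. = FALSE)
  beta <- fit$coefficients
  lai_mlr_model(beta[["(Intercept)"]], beta[setdiff(names(beta), "(Intercept)")])
}
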