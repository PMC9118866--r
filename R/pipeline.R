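#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: the scene generator settings,
#' masking and NRCT options, the train/test split, the regression methods
#' and feature-set combinations, and the master seed from which every stage
#' seed is derived.
#'
#' @param scene A [scene_config()].
#' @param n_train_pixels,n_test_pixels Per-class pixel counts for mask
#'   training/evaluation.
#' @param nrct_extent NRCT baseline extent (see [compute_nrct()]).
#' @param train_fraction Train fraction of the plot-level split.
#' @param methods Regression methods for the combination experiment.
#' @param sets List of feature-group combinations.
#' @param masking Run the soil-removal arm (default TRUE). With `FALSE` only
#'   the retained-background cells are produced.
#' @param min_pixels Plot retention threshold (defined pixels).
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(),
                            n_train_pixels = 500L,
                            n_test_pixels = 500L,
                            nrct_extent = c("whole_field", "masked_canopy"),
                            train_fraction = 0.7,
                            methods = c("rfr", "svr"),
                            sets = list("Sp", c("Sp", "Th"), c("Sp", "St"),
                                        c("Sp", "St", "Th")),
                            masking = TRUE,
                            min_pixels = 10L,
                            seed = 1L) {
  nrct_extent <- match.arg(nrct_extent)
  stopifnot(inherits(scene, "scene_config"))
  structure(list(scene = scene,
                 n_train_pixels = as.integer(n_train_pixels),
                 n_test_pixels = as.integer(n_test_pixels),
                 nrct_extent = nrct_extent,
                 train_fraction = train_fraction,
                 methods = methods,
                 sets = sets,
                 masking = isTRUE(masking),
                 min_pixels = as.integer(min_pixels),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected with an error naming them. Keys omitted from the
#' file keep their defaults. A round-trip through
#' [write_pipeline_config()] and back is identical.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  scene_args <- raw$scene %||% list()
  known_scene <- names(formals(scene_config))
  bad <- setdiff(names(scene_args), known_scene)
  if (length(bad))
    stop("unknown scene config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in c("canopy_reflectance_base", "canopy_reflectance_slope",
               "soil_reflectance"))
    if (!is.null(scene_args[[nm]])) scene_args[[nm]] <- unlist(scene_args[[nm]])
  top <- raw[setdiff(names(raw), "scene")]
  known_top <- setdiff(names(formals(pipeline_config)), "scene")
  bad <- setdiff(names(top), known_top)
  if (length(bad))
    stop("unknown pipeline config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(top$sets)) top$sets <- lapply(top$sets, unlist)
  do.call(pipeline_config, c(list(scene = do.call(scene_config, scene_args)), top))
}

#' Write a pipeline configuration to YAML or JSON
#'
#' @param config A `pipeline_config`.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$scene <- unclass(x$scene)
  x$scene$lai_bins <- NULL
  x$scene <- lapply(x$scene, function(v) if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Run the full LAI estimation pipeline
#'
#' Orchestrates simulate -> mask -> extract -> aggregate -> model and writes
#' every product to `out_dir`: the scene bundle (optional), the vegetation
#' mask and its accuracy report, masked and unmasked feature tables, the
#' model-comparison results table, importance rankings for the fused
#' feature set, the common top-10 variables with a refit four-variable
#' linear model, a per-pixel LAI prediction map, and a JSON run manifest.
#' Fully deterministic for a fixed master seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param write_scene_bundle Also write the raster scene bundle
#'   (default FALSE; tables and maps are always written).
#' @return Invisibly, a list with the scene, mask, accuracy, feature tables,
#'   experiment results, importance rankings, common variables, refit MLR
#'   and prediction map.
#' @export
run_pipeline <- function(config, out_dir, write_scene_bundle = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  seed <- config$seed
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  scn_cfg <- config$scene
  scn_cfg$seed <- subseed(seed, "scene")
  log_line("simulate: %d x %d plots at %.4g m/px, master seed %d",
           scn_cfg$n_plot_rows, scn_cfg$n_plot_cols, scn_cfg$pixel_size_m, seed)
  scene <- stage("simulate", suppressWarnings(generate_scene(scn_cfg)))
  if (write_scene_bundle)
    stage("write-scene", write_scene(scene, file.path(out_dir, "scene")))

  mask <- NULL
  accuracy <- NULL
  if (config$masking) {
    px <- stage("mask-sample", sample_training_pixels(
      scene, config$n_train_pixels, config$n_test_pixels,
      seed = subseed(seed, "mask-pixels")))
    mask <- stage("mask-train", train_and_classify(scene, px$train))
    cm <- stage("mask-eval", confusion_matrix(mask, scene$truth_mask, px$test))
    accuracy <- data.frame(oa = overall_accuracy(cm),
                           kappa = kappa_coefficient(cm),
                           n_soil_soil = cm[1, 1], n_soil_canopy = cm[1, 2],
                           n_canopy_soil = cm[2, 1], n_canopy_canopy = cm[2, 2])
    utils::write.csv(accuracy, file.path(out_dir, "mask_accuracy.csv"),
                     row.names = FALSE)
    log_line("mask: held-out OA %.4f, kappa %.4f", accuracy$oa, accuracy$kappa)
  }

  table_unmasked <- stage("features-unmasked", suppressMessages(
    build_feature_table(scene, mask = NULL, nrct_extent = config$nrct_extent,
                        min_pixels = config$min_pixels)))
  utils::write.csv(table_unmasked, file.path(out_dir, "features_unmasked.csv"),
                   row.names = FALSE)
  table_masked <- NULL
  if (config$masking) {
    table_masked <- stage("features-masked", suppressMessages(
      build_feature_table(scene, mask = mask, nrct_extent = config$nrct_extent,
                          min_pixels = config$min_pixels)))
    utils::write.csv(table_masked, file.path(out_dir, "features_masked.csv"),
                     row.names = FALSE)
  }

  experiment <- stage("models", {
    full <- run_combination_experiment(
      if (config$masking) table_masked else table_unmasked, table_unmasked,
      methods = config$methods, sets = config$sets,
      train_fraction = config$train_fraction,
      seed = subseed(seed, "experiment"))
    if (config$masking) full
    else full[full$soil_background == "retained", , drop = FALSE]
  })
  utils::write.csv(as.data.frame(experiment), file.path(out_dir, "model_results.csv"),
                   row.names = FALSE)
  log_line("models: %d result cells written", nrow(experiment))

  best_table <- if (config$masking) table_masked else table_unmasked
  split <- split_train_test(best_table, config$train_fraction,
                            seed = subseed(seed, "experiment-split-final"))
  fused <- feature_set(c("Sp", "St", "Th"))
  res_rfr <- stage("importance", fit_predict("rfr", split$train, split$test,
                                             features = fused,
                                             seed = subseed(seed, "rfr-final")))
  res_svr <- stage("importance", fit_predict("svr", split$train, split$test,
                                             features = fused))
  imp_df <- function(imp) data.frame(feature = names(imp), score = unname(imp))
  utils::write.csv(imp_df(res_rfr$importance),
                   file.path(out_dir, "importance_rfr.csv"), row.names = FALSE)
  utils::write.csv(imp_df(res_svr$importance),
                   file.path(out_dir, "importance_svr.csv"), row.names = FALSE)

  common <- common_top_k(res_rfr$importance, res_svr$importance, k = 10L)
  log_line("common top-10 variables: %s", paste(common, collapse = ", "))
  mlr_res <- stage("mlr", fit_predict("mlr", split$train, split$test,
                                      features = common))
  mlr_model <- as_lai_mlr(mlr_res$fit)
  mlr_summary <- data.frame(term = c("(Intercept)", names(mlr_model$coefficients)),
                            estimate = c(mlr_model$intercept,
                                         unname(mlr_model$coefficients)))
  utils::write.csv(mlr_summary, file.path(out_dir, "mlr_common_variables.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(metric = c("r2", "rmse"),
                              value = c(mlr_res$r2, mlr_res$rmse)),
                   file.path(out_dir, "mlr_validation.csv"), row.names = FALSE)

  map <- stage("map", prediction_map(scene, mask = mask, model = mlr_model,
                                     nrct_extent = config$nrct_extent))
  write_feature_raster(map, file.path(out_dir, "lai_prediction_map.tif"))

  manifest <- list(
    master_seed = seed,
    stage_seeds = list(scene = subseed(seed, "scene"),
                       mask_pixels = subseed(seed, "mask-pixels"),
                       experiment = subseed(seed, "experiment")),
    masking = config$masking,
    nrct_extent = config$nrct_extent,
    n_plots = nrow(scene$plots),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("uavlai"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(scene = scene, mask = mask, accuracy = accuracy,
                 table_masked = table_masked, table_unmasked = table_unmasked,
                 experiment = experiment, importance_rfr = res_rfr$importance,
                 importance_svr = res_svr$importance, common_variables = common,
                 mlr = mlr_model, mlr_validation = mlr_res,
                 prediction_map = map))
}
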