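#' Sample labeled training and test pixels from a scene's ground truth
#'
#' Draws, without replacement, `n_per_class` training pixels and
#' `n_test_per_class` held-out test pixels from each class (canopy, soil) of
#' the scene's truth mask. Train and test sets are disjoint.
#'
#' @param scene A `uav_scene` with a `truth_mask`.
#' @param n_per_class Training pixels per class (default 500).
#' @param n_test_per_class Test pixels per class (default: same as training).
#' @param seed Integer seed.
#' @return A list with data.frames `train` and `test`, each with columns
#'   `row`, `col`, `class` (factor soil/canopy) and linear `index`.
#' @export
sample_training_pixels <- function(scene, n_per_class = 500L,
                                   n_test_per_class = n_per_class,
                                   seed = 1L) {
  if (is.null(scene$truth_mask))
    stop("scene has no truth_mask; cannot sample labeled pixels", call. = FALSE)
  need <- as.integer(n_per_class + n_test_per_class)
  idx_canopy <- which(scene$truth_mask == 1L)
  idx_soil <- which(scene$truth_mask == 0L)
  for (cls in c("canopy", "soil")) {
    n_avail <- if (cls == "canopy") length(idx_canopy) else length(idx_soil)
    if (n_avail < need)
      stop(sprintf("%s has %d pixels; %d required", cls, n_avail, need),
           call. = FALSE)
  }
  set.seed(as.integer(seed))
  pick_canopy <- sample(idx_canopy, need)
  pick_soil <- sample(idx_soil, need)
  split_set <- function(ix, cls) {
    data.frame(index = ix,
               row = ((ix - 1L) %% nrow(scene$truth_mask)) + 1L,
               col = ((ix - 1L) %/% nrow(scene$truth_mask)) + 1L,
               class = factor(cls, levels = c("soil", "canopy")))
  }
  train <- rbind(split_set(pick_canopy[seq_len(n_per_class)], "canopy"),
                 split_set(pick_soil[seq_len(n_per_class)], "soil"))
  test <- rbind(split_set(pick_canopy[n_per_class + seq_len(n_test_per_class)], "canopy"),
                split_set(pick_soil[n_per_class + seq_len(n_test_per_class)], "soil"))
  list(train = train, test = test)
}

# 5-band feature matrix at given linear pixel indices
pixel_features <- function(scene, index, bands = names(scene$bands)) {
  X <- vapply(bands, function(b) scene$bands[[b]][index],
              numeric(length(index)))
  if (length(index) == 1L) X <- matrix(X, nrow = 1L, dimnames = list(NULL, bands))
  X
}

#' Classify every pixel as canopy or soil with a linear-kernel SVM
#'
#' Fits a linear-kernel support-vector classifier on per-pixel reflectance
#' vectors at the labeled training pixels and applies it to the whole grid,
#' producing the binary soil-background mask used to exclude soil pixels from
#' all downstream feature aggregation.
#'
#' @param scene A `uav_scene`.
#' @param training Data.frame of labeled pixels (`index`, `class`), e.g. the
#'   `$train` element of [sample_training_pixels()].
#' @param bands Character vector of band names to use as classifier features
#'   (default: all five).
#' @param cost SVM margin penalty C (default 1).
#' @return An object of class `vegetation_mask`: list with `mask` (integer
#'   matrix, 1 = canopy, 0 = soil), the fitted `model`,
#'   `training_size_per_class` and a `classifier_note`.
#' @export
train_and_classify <- function(scene, training, bands = names(scene$bands),
                               cost = 1.0) {
  if (length(unique(training$class)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  X <- pixel_features(scene, training$index, bands)
  y <- factor(training$class, levels = c("soil", "canopy"))
  key <- apply(X, 1L, paste, collapse = ",")
  if (any(vapply(split(as.character(y), key),
                 function(z) length(unique(z)) > 1L, logical(1))))
    warning("identical feature vectors appear in both classes; classifier may be degenerate",
            call. = FALSE)
  model <- e1071::svm(x = X, y = y, kernel = "linear", cost = cost,
                      scale = TRUE, type = "C-classification")
  n_px <- scene$geom$nrow * scene$geom$ncol
  X_all <- pixel_features(scene, seq_len(n_px), bands)
  pred <- stats::predict(model, X_all)
  mask <- matrix(as.integer(pred == "canopy"), scene$geom$nrow, scene$geom$ncol)
  structure(list(
    mask = mask,
    model = model,
    bands = bands,
    training_size_per_class = as.integer(table(y)),
    classifier_note = sprintf("linear-kernel SVM, C = %g, bands: %s",
                              cost, paste(bands, collapse = ", "))
  ), class = "vegetation_mask")
}

#' @export
print.vegetation_mask <- function(x, ...) {
  cat("Vegetation (canopy/soil) mask\n")
  cat(sprintf("  %d x %d px, canopy fraction %.3f\n",
              nrow(x$mask), ncol(x$mask), mean(x$mask == 1L)))
  cat(" ", x$classifier_note, "\n")
  invisible(x)
}

#' Confusion matrix of a mask against ground truth
#'
#' @param mask A `vegetation_mask` or an integer matrix (1 = canopy, 0 = soil).
#' @param truth Integer matrix of the same shape (1 = canopy, 0 = soil).
#' @param eval_pixels Data.frame with linear pixel `index` (e.g. the `$test`
#'   element of [sample_training_pixels()]); must be disjoint from training.
#' @return A 2x2 table of class `confusion_matrix`; rows are truth, columns
#'   predicted, in class order soil, canopy.
#' @export
confusion_matrix <- function(mask, truth, eval_pixels) {
  m <- if (inherits(mask, "vegetation_mask")) mask$mask else mask
  stop_if_not_matrix_pair(m, truth, "mask", "truth")
  if (is.null(eval_pixels) || nrow(eval_pixels) == 0L)
    stop("eval_pixels is empty", call. = FALSE)
  idx <- eval_pixels$index
  lv <- c("soil", "canopy")
  t_cls <- factor(lv[truth[idx] + 1L], levels = lv)
  p_cls <- factor(lv[m[idx] + 1L], levels = lv)
  cm <- table(truth = t_cls, predicted = p_cls)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Overall accuracy of a confusion matrix
#'
#' Proportion of evaluated pixels on the diagonal (correctly classified).
#'
#' @param cm A `confusion_matrix` (or any square count table).
#' @return Overall accuracy in \[0, 1\].
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has no counts", call. = FALSE)
  sum(diag(unclass(cm))) / total
}

#' Cohen's kappa coefficient of a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed agreement (overall accuracy) and `p_e` the agreement expected from
#' the row/column marginals. When `p_e = 1` (both raters constant) kappa is
#' undefined and `NA` is returned with a warning.
#'
#' @param cm A `confusion_matrix`.
#' @return Kappa (dimensionless), or `NA` when undefined.
#' @export
kappa_coefficient <- function(cm) {
  m <- unclass(cm)
  total <- sum(m)
  if (total <= 0) stop("confusion matrix has no counts", call. = FALSE)
  p_o <- sum(diag(m)) / total
  p_e <- sum(rowSums(m) * colSums(m)) / total^2
  if (abs(1 - p_e) < .Machine$double.eps * 4) {
    warning("kappa undefined: expected agreement p_e = 1", call. = FALSE)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}
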