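#' Coefficient of determination (R squared)
#'
#' `R2 = 1 - SSE/SST` with `SSE = sum((y - yhat)^2)` and
#' `SST = sum((y - mean(y))^2)`. May be negative for models worse than the
#' mean predictor. Undefined (NA with a warning) when the measured values
#' have zero variance.
#'
#' @param measured,predicted Numeric vectors of equal length >= 2.
#' @return R squared (dimensionless).
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
r_squared <- function(measured, predicted) {
  check_metric_inputs(measured, predicted)
  sst <- sum((measured - mean(measured))^2)
  if (sst == 0) {
    warning("R squared undefined: measured values have zero variance",
            call. = FALSE)
    return(NA_real_)
  }
  1 - sum((measured - predicted)^2) / sst
}

#' Root mean square error
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`, in the units of the response (LAI).
#'
#' @inheritParams r_squared
#' @return RMSE >= 0.
#' @export
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 4))  # sqrt(1/3)
rmse <- function(measured, predicted) {
  check_metric_inputs(measured, predicted)
  sqrt(mean((measured - predicted)^2))
}

check_metric_inputs <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("measured and predicted must have equal length", call. = FALSE)
  if (length(measured) < 2L)
    stop("need at least 2 observations", call. = FALSE)
  if (anyNA(measured) || anyNA(predicted))
    stop("NA values in measured or predicted", call. = FALSE)
  invisible(TRUE)
}

#' Random train/test split of a feature table
#'
#' Draws `round(train_fraction * n)` rows for training; the rest are the
#' held-out test set. Disjoint and exhaustive, reproducible by seed.
#'
#' @param table Data.frame (e.g. a [build_feature_table()] result).
#' @param train_fraction Proportion in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @return List with data.frames `train` and `test`.
#' @export
split_train_test <- function(table, train_fraction = 0.7, seed = 1L) {
  n <- nrow(table)
  if (n < 5L) stop("need at least 5 rows to split", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  n_train <- round(train_fraction * n)
  idx <- sample.int(n, n_train)
  list(train = table[idx, , drop = FALSE],
       test = table[-idx, , drop = FALSE])
}

#' Feature-group column sets
#'
#' Expands the spectral/structural/thermal grouping into canonical feature
#' columns: `Sp` = 5 raw bands + 15 vegetation indices, `St` = CHM,
#' `Th` = NRCT.
#'
#' @param groups Character subset of `c("Sp", "St", "Th")`.
#' @return Character vector of feature column names.
#' @export
#' @examples
#' feature_set(c("Sp", "St"))
feature_set <- function(groups) {
  groups <- unique(groups)
  bad <- setdiff(groups, c("Sp", "St", "Th"))
  if (length(bad) || length(groups) == 0L)
    stop("groups must be a non-empty subset of {Sp, St, Th}", call. = FALSE)
  out <- character(0)
  if ("Sp" %in% groups) out <- c(out, band_feature_names(), vi_names())
  if ("St" %in% groups) out <- c(out, "CHM")
  if ("Th" %in% groups) out <- c(out, "NRCT")
  out
}

#' Fit a plot-level LAI regression model
#'
#' The fitting front-end of the package: regresses measured LAI on plot-level
#' features with one of three methods. `"rfr"` is random-forest regression
#' with 100 trees (the count at which forest accuracy plateaus for this kind
#' of table); `"svr"` is support-vector regression with a linear kernel,
#' predictors standardized to zero mean / unit variance using training
#' statistics only; `"mlr"` is ordinary least squares. A rank-deficient MLR
#' design falls back to the smallest-norm solution (SVD pseudoinverse) with a
#' warning.
#'
#' @param data Training data.frame containing the response and features.
#' @param method `"rfr"`, `"svr"` or `"mlr"`.
#' @param features Character vector of predictor columns (default: every
#'   canonical feature present in `data`).
#' @param response Response column name (default `"lai_measured"`).
#' @param ntree Number of trees for `"rfr"` (default 100).
#' @param cost,epsilon SVR margin penalty and insensitivity tube
#'   (defaults 1 and 0.1).
#' @param seed Integer seed for the forest's bootstrap/column sampling.
#' @return Object of class `lai_fit` with `print`, `summary`, `predict`,
#'   `coef`, `residuals`, `fitted`, `plot` and [importance()] methods.
#' @export
#' @examples
#' d <- data.frame(CHM = runif(30), lai_measured = NA)
#' d$lai_measured <- 1 + 2 * d$CHM
#' fit <- lai_fit(d, "mlr", features = "CHM")
#' coef(fit)
lai_fit <- function(data, method = c("rfr", "svr", "mlr"),
                    features = NULL, response = "lai_measured",
                    ntree = 100L, cost = 1.0, epsilon = 0.1, seed = 1L) {
  method <- match.arg(method)
  if (is.null(features))
    features <- intersect(all_feature_names(), names(data))
  missing_cols <- setdiff(c(features, response), names(data))
  if (length(missing_cols))
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(data[, features, drop = FALSE])
  y <- data[[response]]
  if (anyNA(X) || anyNA(y)) stop("NA values in model inputs", call. = FALSE)

  obj <- list(method = method, features = features, response = response,
              n_train = nrow(X))
  if (method == "rfr") {
    set.seed(as.integer(seed))
    rf <- randomForest::randomForest(x = X, y = y, ntree = as.integer(ntree))
    imp_mat <- randomForest::importance(rf)  # mean decrease in node impurity
    imp <- stats::setNames(imp_mat[, 1L], rownames(imp_mat))
    obj$model <- rf
    obj$importance_raw <- imp
  } else if (method == "svr") {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0] <- 1
    Xs <- scale(X, center = ctr, scale = scl)
    sv <- e1071::svm(x = Xs, y = y, kernel = "linear", cost = cost,
                     epsilon = epsilon, scale = FALSE, type = "eps-regression")
    w <- drop(t(sv$coefs) %*% sv$SV)
    names(w) <- features
    obj$model <- sv
    obj$center <- ctr
    obj$scale <- scl
    obj$weights <- w
    # |coefficient on standardized predictor| == |raw coefficient| * sd
    obj$importance_raw <- abs(w)
  } else {
    design <- cbind(`(Intercept)` = 1, X)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      warning("rank-deficient design; using smallest-norm least-squares solution",
              call. = FALSE)
      sv <- svd(design)
      pos <- sv$d > max(sv$d) * 1e-12
      beta <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
      beta <- drop(beta)
    } else {
      beta <- drop(qr.coef(qrd, y))
    }
    names(beta) <- colnames(design)
    obj$coefficients <- beta
  }
  obj$fitted <- NULL
  class(obj) <- "lai_fit"
  obj$fitted <- predict(obj, data)
  obj$residuals <- y - obj$fitted
  obj$train_r2 <- if (stats::sd(y) > 0) r_squared(y, obj$fitted) else NA_real_
  obj$train_response <- y
  obj
}

#' @export
predict.lai_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  switch(object$method,
    rfr = unname(stats::predict(object$model, X)),
    svr = {
      Xs <- scale(X, center = object$center, scale = object$scale)
      unname(stats::predict(object$model, Xs))
    },
    mlr = unname(drop(cbind(1, X) %*% object$coefficients))
  )
}

#' @export
coef.lai_fit <- function(object, ...) {
  switch(object$method,
    mlr = object$coefficients,
    svr = object$weights,  # weights on standardized predictors
    rfr = NULL
  )
}

#' @export
residuals.lai_fit <- function(object, ...) object$residuals

#' @export
fitted.lai_fit <- function(object, ...) object$fitted

#' @export
print.lai_fit <- function(x, ...) {
  label <- c(rfr = "random-forest regression (100-tree class)",
             svr = "linear-kernel support-vector regression",
             mlr = "multiple linear regression")[[x$method]]
  cat(sprintf("LAI model: %s\n", label))
  cat(sprintf("  %d training plots, %d features\n", x$n_train,
              length(x$features)))
  cat(sprintf("  training R2 = %.3f\n", x$train_r2))
  invisible(x)
}

#' @export
summary.lai_fit <- function(object, ...) {
  print(object)
  if (object$method == "mlr") {
    cat("  coefficients:\n")
    print(round(object$coefficients, 4))
  } else {
    imp <- importance(object)
    cat("  top features by importance:\n")
    print(round(utils::head(imp, 5), 4))
  }
  invisible(object)
}

#' @export
plot.lai_fit <- function(x, newdata = NULL, ...) {
  if (is.null(newdata)) {
    measured <- x$train_response
    predicted <- x$fitted
    main <- "Training fit"
  } else {
    measured <- newdata[[x$response]]
    predicted <- predict(x, newdata)
    main <- "Validation"
  }
  lim <- range(c(measured, predicted))
  graphics::plot(measured, predicted, xlim = lim, ylim = lim,
                 xlab = "Measured LAI", ylab = "Predicted LAI",
                 main = main, pch = 19, col = "#00000080", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Ranked feature importance of a fitted LAI model
#'
#' For random-forest fits, normalized mean impurity-decrease scores; for
#' linear-kernel SVR, the absolute coefficient on each standardized predictor
#' (equivalently |raw coefficient| times the training standard deviation),
#' normalized. Scores are non-negative and sum to 1; ties are broken by
#' feature name order. Not defined for MLR fits.
#'
#' @param fit A `lai_fit` object.
#' @param ... Unused.
#' @return Named numeric vector sorted by decreasing importance.
#' @export
importance <- function(fit, ...) UseMethod("importance")

#' @export
importance.lai_fit <- function(fit, ...) {
  if (fit$method == "mlr")
    stop("importance is not defined for MLR fits", call. = FALSE)
  raw <- fit$importance_raw
  raw[raw < 0] <- 0
  tot <- sum(raw)
  scores <- if (tot > 0) raw / tot else rep(1 / length(raw), length(raw))
  names(scores) <- names(raw)
  scores[order(-scores, names(scores))]
}

#' Fit on a training table and evaluate on a held-out test table
#'
#' Convenience wrapper: fits [lai_fit()] on `train`, predicts `test`, and
#' reports R squared and RMSE on the held-out plots together with the
#' feature-importance ranking (where defined).
#'
#' @param method `"rfr"`, `"svr"` or `"mlr"`.
#' @param train,test Data.frames sharing the feature and response columns.
#' @param features Predictor columns (default: canonical features present).
#' @param seed Seed forwarded to the forest.
#' @param ... Further arguments to [lai_fit()].
#' @return Object of class `lai_model_result`: list with `method`,
#'   `features`, `r2`, `rmse`, `importance` (or NULL for MLR),
#'   `predictions`, `measured` and the underlying `fit`.
#' @export
fit_predict <- function(method, train, test, features = NULL, seed = 1L, ...) {
  fit <- lai_fit(train, method = method, features = features, seed = seed, ...)
  pred <- predict(fit, test)
  measured <- test[[fit$response]]
  structure(list(
    method = method,
    features = fit$features,
    r2 = r_squared(measured, pred),
    rmse = rmse(measured, pred),
    importance = if (method == "mlr") NULL else importance(fit),
    predictions = pred,
    measured = measured,
    fit = fit
  ), class = "lai_model_result")
}

#' @export
print.lai_model_result <- function(x, ...) {
  cat(sprintf("%s: test R2 = %.3f, RMSE = %.3f (n_test = %d)\n",
              toupper(x$method), x$r2, x$rmse, length(x$predictions)))
  invisible(x)
}
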