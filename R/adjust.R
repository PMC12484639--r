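#' Fit per-feature confounder regressions
#'
#' For every ECG feature, fits an ordinary-least-squares regression of the
#' feature on LV mass index, age and sex. The fitted models are used to
#' residualize the training data (see [apply_adjustment()]); at inference
#' time predictions use raw feature values and the adjustment is a no-op.
#'
#' Rows with missing covariates are dropped (and counted). A rank-deficient
#' design (e.g. a constant covariate) is fit by pseudoinverse with a
#' warning.
#'
#' @param features Numeric matrix (ECGs x features) with column names.
#' @param covariates data.frame with columns `lvmi`, `age`, `sex`
#'   (sex coded 0/1), one row per feature row.
#' @return An object of class `adjustment_model` with per-feature
#'   coefficients (intercept, beta_lvmi, beta_age, beta_sex), training
#'   means, and per-feature R-squared.
#' @export
fit_adjusters <- function(features, covariates) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(covariates))
  need <- c("lvmi", "age", "sex")
  if (!all(need %in% names(covariates))) {
    stopf("covariates must contain columns: %s", paste(need, collapse = ", "))
  }
  C <- as.matrix(covariates[, need])
  keep <- stats::complete.cases(C)
  n_dropped <- sum(!keep)
  if (sum(keep) < 10L) stopf("need at least 10 rows with complete covariates")
  Y <- features[keep, , drop = FALSE]
  X <- cbind(intercept = 1, C[keep, , drop = FALSE])

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warnf("rank-deficient covariate design (rank %d of %d); using pseudoinverse",
          qx$rank, ncol(X))
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    beta <- pinv %*% Y
  } else {
    beta <- qr.coef(qx, Y)
  }
  rownames(beta) <- c("intercept", paste0("beta_", need))

  fitted <- X %*% beta
  res <- Y - fitted
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2 <- ifelse(sst > 0, 1 - colSums(res^2) / sst, 0)

  model <- list(
    coefficients = t(beta),       # one row per feature
    feature_means = colMeans(Y),
    r_squared = r2,
    n_used = sum(keep),
    n_dropped = n_dropped
  )
  class(model) <- "adjustment_model"
  model
}

#' Apply (or bypass) the confounder adjustment
#'
#' In `train` mode each feature becomes
#' `raw - predicted(confounders) + training mean`, i.e. the OLS residual
#' re-centred on the feature's training mean so adjusted values stay on the
#' physical scale. In `inference` mode the input is returned unchanged:
#' deployed predictions rely exclusively on raw ECG feature values.
#'
#' @param model An `adjustment_model`.
#' @param features Numeric matrix with the same feature columns the model
#'   was fitted on.
#' @param covariates data.frame with `lvmi`, `age`, `sex` (ignored in
#'   inference mode).
#' @param mode `"train"` or `"inference"`.
#' @return Adjusted feature matrix of the same shape.
#' @export
apply_adjustment <- function(model, features, covariates = NULL,
                             mode = c("train", "inference")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "adjustment_model"))
  features <- as.matrix(features)
  if (mode == "inference") return(features)
  if (!identical(colnames(features), rownames(model$coefficients))) {
    stopf("feature columns do not match the fitted adjustment model")
  }
  if (is.null(covariates)) stopf("train-mode adjustment requires covariates")
  X <- cbind(1, as.matrix(covariates[, c("lvmi", "age", "sex")]))
  pred <- X %*% t(model$coefficients)
  out <- features - pred
  sweep(out, 2, model$feature_means, `+`)
}

#' Persist an adjustment model as a coefficient CSV
#' @param model An `adjustment_model`.
#' @param path CSV path.
#' @export
write_adjustment_csv <- function(model, path) {
  df <- data.frame(feature = rownames(model$coefficients),
                   model$coefficients,
                   mean = model$feature_means,
                   r_squared = model$r_squared,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjustment_csv
#' @export
read_adjustment_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  coef <- as.matrix(df[, c("intercept", "beta_lvmi", "beta_age", "beta_sex")])
  rownames(coef) <- df$feature
  model <- list(coefficients = coef,
                feature_means = stats::setNames(df$mean, df$feature),
                r_squared = stats::setNames(df$r_squared, df$feature),
                n_used = NA_integer_, n_dropped = NA_integer_)
  class(model) <- "adjustment_model"
  model
}
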