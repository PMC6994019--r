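# L2-regularized logistic regression for recurrence classification.
#
# The penalized objective is stated explicitly so results do not depend on a
# library's private parameterization:
#
#   J(b0, b) = (1/n) * sum_i [ log(1 + exp(eta_i)) - y_i * eta_i ]
#              + (lambda / 2) * ||b||_2^2 ,   eta_i = b0 + x_i' b
#
# i.e. mean binomial negative log-likelihood plus a ridge penalty on the
# slopes; the intercept is unpenalized and features enter unstandardized
# (counts are left on their natural scale; age is standardized upstream).
# This is exactly glmnet's objective with alpha = 0 and standardize = FALSE,
# so glmnet is used as the optimizer; tests check the fit against a direct
# numerical minimizer of J.

#' Fitting configuration for the recurrence classifier
#'
#' @param n_folds Cross-validation folds (default 10).
#' @param lambda_grid Optional descending positive penalty sequence; by
#'   default the optimizer derives a 100-point data-driven path.
#' @param cutoff_grid Candidate probability cutoffs (default 0.01..0.99).
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `mbc_fit_config`.
#' @export
fit_config <- function(n_folds = 10L, lambda_grid = NULL,
                       cutoff_grid = seq(0.01, 0.99, by = 0.01),
                       seed = 1L) {
  stopifnot(n_folds >= 2L, all(cutoff_grid > 0 & cutoff_grid < 1))
  if (!is.null(lambda_grid)) {
    stopifnot(all(lambda_grid > 0), all(diff(lambda_grid) < 0))
  }
  structure(list(n_folds = as.integer(n_folds), lambda_grid = lambda_grid,
                 cv_loss = "binomial_deviance", cutoff_grid = cutoff_grid,
                 seed = as.integer(seed)),
            class = "mbc_fit_config")
}

# Stratified, seeded fold assignment: each class is shuffled then dealt
# round-robin, so fold class balance is as even as possible. The caller's
# RNG stream is left untouched.
stratified_folds <- function(y, n_folds, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  foldid <- integer(length(y))
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  foldid
}

#' Fit the L2-regularized recurrence classifier
#'
#' Minimizes mean binomial negative log-likelihood plus `(lambda/2)||b||^2`
#' over a descending lambda path; 10-fold cross-validation (stratified,
#' seeded folds; binomial-deviance loss) selects `lambda.1se`, the largest
#' penalty whose mean CV loss is within one standard error of the minimum.
#' The model is then refit on all data at `lambda.1se`, the probability
#' cutoff is chosen to maximize F1 over the out-of-fold predictions (see
#' [select_cutoff()]), and age (`ccr.age_at_dx`) is standardized using
#' training mean/SD stored with the model.
#'
#' @param X Numeric design matrix with column names (see
#'   [assemble_design_matrix()]).
#' @param y 0/1 response; both classes must be present.
#' @param config An [fit_config()].
#' @return An object of class `mbc_model`: coefficients, intercept,
#'   lambda_min, lambda_1se, cutoff, cv_curve, achieved CV F1, feature
#'   names, config.
#' @export
fit_recurrence_model <- function(X, y, config = fit_config()) {
  stopifnot(inherits(config, "mbc_fit_config"), nrow(X) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  bad <- colnames(X)[!apply(X, 2, function(c) all(is.finite(c)))]
  if (length(bad)) {
    stop("non-finite values in feature column(s): ",
         paste(bad, collapse = ", "))
  }
  std <- list(center = 0, scale = 1)
  if ("ccr.age_at_dx" %in% colnames(X)) {
    mu <- mean(X[, "ccr.age_at_dx"])
    sd_ <- stats::sd(X[, "ccr.age_at_dx"])
    if (!is.finite(sd_) || sd_ == 0) sd_ <- 1
    std <- list(center = mu, scale = sd_)
    X[, "ccr.age_at_dx"] <- (X[, "ccr.age_at_dx"] - mu) / sd_
  }
  foldid <- stratified_folds(y, config$n_folds, config$seed)
  # glmnet's ridge objective matches J with lambda_glmnet = lambda.
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = config$lambda_grid, foldid = foldid,
                          type.measure = "deviance", keep = TRUE,
                          standardize = FALSE, thresh = 1e-10)
  i1se <- match(cv$lambda.1se, cv$lambda)
  cf <- stats::coef(cv, s = "lambda.1se")
  intercept <- cf[1L]
  coefs <- stats::setNames(as.numeric(cf[-1L]), rownames(cf)[-1L])
  oof <- stats::plogis(cv$fit.preval[, i1se])
  model <- structure(list(
    coefficients = coefs, intercept = intercept,
    lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
    cv_curve = data.frame(lambda = cv$lambda, mean_loss = cv$cvm,
                          se_loss = cv$cvsd),
    oof_prob = oof, foldid = foldid,
    feature_names = colnames(X), age_standardization = std,
    config = config, cutoff = NA_real_, cv_f1 = NA_real_),
    class = "mbc_model")
  sel <- select_cutoff(model, y = y)
  model$cutoff <- sel$cutoff
  model$cv_f1 <- sel$f1
  model
}

#' Select the F1-optimal probability cutoff
#'
#' Scans the configured cutoff grid over the model's stored out-of-fold
#' cross-validated probabilities and returns the cutoff maximizing F1 of
#' `prob >= cutoff`; ties are broken toward 0.5 (then toward the smaller
#' cutoff). If every probability is identical the cutoff defaults to 0.5
#' with a warning.
#'
#' @param model An `mbc_model` (with stored out-of-fold probabilities), or
#'   any object with `$config`.
#' @param y The training labels the folds were built on.
#' @param prob Optional probability vector to use instead of the stored
#'   out-of-fold ones.
#' @return List with `cutoff` and achieved `f1`.
#' @export
select_cutoff <- function(model, y, prob = model$oof_prob) {
  grid <- model$config$cutoff_grid
  if (length(unique(prob)) == 1L) {
    warning("all predicted probabilities identical; cutoff defaults to 0.5")
    return(list(cutoff = 0.5, f1 = f1_score(y, as.integer(prob >= 0.5))))
  }
  f1s <- vapply(grid, function(cut) {
    f1_score(y, as.integer(prob >= cut))
  }, numeric(1))
  f1s[is.na(f1s)] <- -Inf
  best <- which(f1s == max(f1s))
  best <- best[order(abs(grid[best] - 0.5), grid[best])][1L]
  list(cutoff = grid[best], f1 = f1s[best])
}

f1_score <- function(y, yhat) {
  tp <- sum(y == 1 & yhat == 1)
  fp <- sum(y == 0 & yhat == 1)
  fn <- sum(y == 1 & yhat == 0)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Predict recurrence probabilities and labels
#'
#' Columns of `newdata` are aligned to the model's feature names by name; a
#' missing feature column is an error. `predict_prob` returns
#' `plogis(X b + b0)`; `classify` thresholds at the model's F1-optimized
#' cutoff.
#'
#' @param model An `mbc_model`.
#' @param newdata Numeric matrix with named columns.
#' @return Numeric probabilities in (0,1), or 0/1 integer labels.
#' @export
predict_prob <- function(model, newdata) {
  miss <- setdiff(model$feature_names, colnames(newdata))
  if (length(miss)) {
    stop("newdata is missing feature column(s): ", paste(miss, collapse = ", "))
  }
  X <- newdata[, model$feature_names, drop = FALSE]
  if ("ccr.age_at_dx" %in% colnames(X)) {
    s <- model$age_standardization
    X[, "ccr.age_at_dx"] <- (X[, "ccr.age_at_dx"] - s$center) / s$scale
  }
  as.numeric(stats::plogis(drop(X %*% model$coefficients) + model$intercept))
}

#' @rdname predict_prob
#' @param cutoff Probability threshold (defaults to the model's).
#' @export
classify <- function(model, newdata, cutoff = model$cutoff) {
  as.integer(predict_prob(model, newdata) >= cutoff)
}

#' @export
print.mbc_model <- function(x, ...) {
  cat("<mbc_model> ridge logistic regression, ",
      length(x$feature_names), " features\n", sep = "")
  cat(sprintf("  lambda.min %.4g, lambda.1se %.4g, cutoff %.2f (CV F1 %.3f)\n",
              x$lambda_min, x$lambda_1se, x$cutoff, x$cv_f1))
  nz <- sum(abs(x$coefficients) > 1e-8)
  cat("  ", nz, " coefficients with |b| > 1e-8\n", sep = "")
  invisible(x)
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model An `mbc_model`.
#' @param path Output path.
#' @return `path` invisibly; `read_model_json` returns the `mbc_model`.
#' @export
write_model_json <- function(model, path) {
  obj <- list(feature_names = model$feature_names,
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              lambda_min = model$lambda_min, lambda_1se = model$lambda_1se,
              cutoff = model$cutoff, cv_f1 = model$cv_f1,
              age_standardization = model$age_standardization,
              config = list(n_folds = model$config$n_folds,
                            seed = model$config$seed,
                            cv_loss = model$config$cv_loss),
              cv_curve = model$cv_curve)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- fit_config(n_folds = obj$config$n_folds, seed = obj$config$seed)
  structure(list(
    coefficients = stats::setNames(as.numeric(obj$coefficients),
                                   names(obj$coefficients)),
    intercept = obj$intercept, lambda_min = obj$lambda_min,
    lambda_1se = obj$lambda_1se, cutoff = obj$cutoff, cv_f1 = obj$cv_f1,
    cv_curve = as.data.frame(obj$cv_curve),
    feature_names = obj$feature_names,
    age_standardization = obj$age_standardization,
    config = cfg), class = "mbc_model")
}
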