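# Absorbed-dose reconstruction: per-timepoint quadratic and integrated
# bivariate cubic calibration models (dose regressed on marker level and
# time), R^2, dose-cutoff ROC, and repeated stratified k-fold
# cross-validation.

#' Bivariate cubic design basis
#'
#' The 10 monomials of total degree <= 3 in marker value m and time t, in
#' the fixed documented order
#' `1, m, t, m^2, m*t, t^2, m^3, m^2*t, m*t^2, t^3`.
#' With `basis = "tensor"`, the 16-term tensor basis `m^i t^j` for
#' `i, j <= 3` (column order j-major: `m^0..m^3` within `t^0`, then `t^1`,
#' ...).
#'
#' @param m,t Numeric vectors (recycled to a common length).
#' @param basis `"total_degree"` (default) or `"tensor"`.
#' @return Design matrix with named columns.
#' @export
cubic_basis <- function(m, t, basis = c("total_degree", "tensor")) {
  basis <- match.arg(basis)
  if (basis == "total_degree") {
    X <- cbind(1, m, t, m^2, m * t, t^2, m^3, m^2 * t, m * t^2, t^3)
    colnames(X) <- c("1", "m", "t", "m2", "mt", "t2", "m3", "m2t", "mt2", "t3")
  } else {
    X <- do.call(cbind, lapply(0:3, function(j) {
      sapply(0:3, function(i) m^i * t^j)
    }))
    colnames(X) <- as.vector(outer(0:3, 0:3, function(i, j) {
      sprintf("m%dt%d", i, j)
    }))
  }
  X
}

.check_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    deficient <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; deficient column(s): ",
         paste(deficient, collapse = ", "))
  }
  qrX
}

.ols_fit <- function(X, y) {
  qrX <- .check_rank(X)
  beta <- qr.coef(qrX, y)
  fitted <- as.vector(X %*% beta)
  resid <- y - fitted
  n <- length(y); p <- ncol(X)
  sigma2 <- sum(resid^2) / max(n - p, 1)
  piv <- qrX$pivot
  xtx_inv <- matrix(0, p, p)
  xtx_inv[piv, piv] <- chol2inv(qr.R(qrX))
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(coefficients = beta, r2 = r2, sigma2 = sigma2, xtx_inv = xtx_inv,
       fitted = fitted, residuals = resid)
}

#' Fit a per-timepoint quadratic dose-calibration model
#'
#' Ordinary least squares of absorbed dose on the marker value:
#' `dose = b0 + b1*m + b2*m^2`, fitted to observations sharing one time
#' post irradiation (inverse-regression orientation: the model maps an
#' observed marker level back to dose).
#'
#' @param points Data frame with columns `m6a_value`, `dose_gy`,
#'   `tpi_days` (all rows sharing one value).
#' @return A `dose_model` list: `kind = "per_tpi_quadratic"`, `coefficients`
#'   (b0, b1, b2 over 1, m, m^2), `tpi_days`, `r2`, `n_train`, and the
#'   covariance pieces needed for 95 percent confidence bands.
#' @export
fit_per_tpi_quadratic <- function(points) {
  tpis <- unique(points$tpi_days)
  if (length(tpis) != 1) stop("mixed TPIs: fit one model per timepoint")
  if (nrow(points) < 3 || length(unique(points$m6a_value)) < 3) {
    stop("need >= 3 points with >= 3 distinct marker values")
  }
  m <- points$m6a_value
  X <- cbind(1, m, m^2)
  colnames(X) <- c("1", "m", "m2")
  fit <- .ols_fit(X, points$dose_gy)
  structure(list(kind = "per_tpi_quadratic",
                 coefficients = stats::setNames(as.vector(fit$coefficients),
                                                colnames(X)),
                 tpi_days = tpis, r2 = fit$r2, n_train = nrow(points),
                 sigma2 = fit$sigma2, xtx_inv = fit$xtx_inv),
            class = "dose_model")
}

#' Fit the integrated bivariate cubic dose-calibration model
#'
#' Ordinary least squares of absorbed dose on the 10-term bivariate cubic
#' basis in marker value and time post irradiation (see [cubic_basis()]).
#' The design must span at least two timepoints; otherwise the t-columns are
#' collinear and the error names the deficient columns.
#'
#' @param points Data frame with `m6a_value`, `tpi_days`, `dose_gy`.
#' @param basis `"total_degree"` (10 terms, default) or `"tensor"` (16).
#' @return A `dose_model` list with `kind = "bivariate_cubic"`.
#' @export
fit_bivariate_cubic <- function(points, basis = "total_degree") {
  X <- cubic_basis(points$m6a_value, points$tpi_days, basis = basis)
  if (nrow(points) < ncol(X)) {
    stop("need at least ", ncol(X), " points for the ", basis, " cubic basis")
  }
  fit <- .ols_fit(X, points$dose_gy)
  structure(list(kind = "bivariate_cubic", basis = basis,
                 coefficients = stats::setNames(as.vector(fit$coefficients),
                                                colnames(X)),
                 tpi_days = NA_real_, r2 = fit$r2, n_train = nrow(points),
                 sigma2 = fit$sigma2, xtx_inv = fit$xtx_inv),
            class = "dose_model")
}

#' @export
print.dose_model <- function(x, ...) {
  cat("Dose calibration model (", x$kind, ")\n", sep = "")
  if (x$kind == "per_tpi_quadratic") cat("  TPI:", x$tpi_days, "days\n")
  cat("  coefficients:\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  training R^2 = %.4f on n = %d\n", x$r2, x$n_train))
  invisible(x)
}

.model_design <- function(model, m6a_value, tpi_days) {
  if (model$kind == "per_tpi_quadratic") {
    cbind(1, m6a_value, m6a_value^2)
  } else {
    if (is.null(tpi_days)) stop("tpi_days required for the bivariate model")
    cubic_basis(m6a_value, tpi_days,
                basis = if (is.null(model$basis)) "total_degree" else model$basis)
  }
}

#' Predict absorbed dose from a calibration model
#'
#' Polynomial evaluation of the fitted model; negative estimates are
#' reported as-is (flagged) unless `clamp = TRUE`, and 95 percent
#' confidence bands for the calibration curve are computed from the
#' least-squares covariance.
#'
#' @param model A `dose_model`.
#' @param m6a_value Observed marker values.
#' @param tpi_days Times post irradiation (required for the bivariate
#'   model).
#' @param clamp Truncate negative dose estimates at 0 (default `FALSE`).
#' @param interval If `TRUE`, add 95 percent confidence band columns.
#' @return Numeric vector of doses, or a data frame with `dose`,
#'   `negative_flag` and optionally `lwr`/`upr` when `interval = TRUE`.
#' @export
predict_dose <- function(model, m6a_value, tpi_days = NULL, clamp = FALSE,
                         interval = FALSE) {
  stopifnot(inherits(model, "dose_model"))
  X <- .model_design(model, m6a_value, tpi_days)
  dose <- as.vector(X %*% model$coefficients)
  neg <- dose < 0
  if (clamp) dose <- pmax(dose, 0)
  if (!interval) return(dose)
  se <- sqrt(model$sigma2 * rowSums((X %*% model$xtx_inv) * X))
  tq <- stats::qt(0.975, max(model$n_train - length(model$coefficients), 1))
  data.frame(dose = dose, lwr = dose - tq * se, upr = dose + tq * se,
             negative_flag = neg)
}

#' Coefficient of determination between actual and estimated doses
#'
#' `1 - SS_res / SS_tot`; can be negative for predictors worse than the
#' mean.
#'
#' @param actual,predicted Numeric vectors of equal length (>= 2, with
#'   non-zero variance in `actual`).
#' @return R squared.
#' @export
r_squared <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 2 || stats::var(actual) == 0) {
    stop("actual doses must have non-zero variance")
  }
  1 - sum((actual - predicted)^2) / sum((actual - mean(actual))^2)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative, ties credited one half. Equals exhaustive
#' positive-negative pair counting.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("need both classes present")
  r <- rank(scores)  # mid-ranks handle ties as half credit
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.fit_model_spec <- function(points, model_spec, basis = "total_degree") {
  switch(model_spec,
         bivariate_cubic = fit_bivariate_cubic(points, basis = basis),
         per_tpi_quadratic = fit_per_tpi_quadratic(points),
         stop("unknown model_spec: ", model_spec))
}

.predict_model_spec <- function(model, points) {
  if (model$kind == "bivariate_cubic") {
    predict_dose(model, points$m6a_value, points$tpi_days)
  } else {
    predict_dose(model, points$m6a_value)
  }
}

# Stratified fold assignment: within each stratum, members are shuffled and
# dealt round-robin over folds, so strata of size >= k appear in every fold
# and smaller strata degrade gracefully (spread over the first folds of a
# random rotation).
.stratified_folds <- function(strata, k) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    start <- sample.int(k, 1)
    fold[idx] <- ((start - 1 + seq_along(idx) - 1) %% k) + 1
  }
  fold
}

#' Repeated stratified k-fold cross-validated AUC at a dose cutoff
#'
#' For each repetition: points are split into k folds stratified by
#' (dose, TPI) group (or by subject); the calibration model is fitted on
#' k-1 folds and predicts the held-out fold; held-out predictions are pooled
#' and the ROC AUC for classifying `dose >= cutoff_gy` is computed. The mean
#' and sd over repetitions are reported. Fully deterministic given `seed`,
#' and the repetition stream is a prefix: more repetitions with the same
#' seed reproduce the earlier ones.
#'
#' @param points Dose-response data frame (`m6a_value`, `tpi_days`,
#'   `dose_gy`, optional `subject_id`).
#' @param cutoff_gy Dose cutoff; positives are points with
#'   `dose_gy >= cutoff_gy`.
#' @param k Folds (default 5).
#' @param reps Repetitions (default 100).
#' @param seed Integer seed.
#' @param stratify_by `"group"` (dose x TPI cell, default) or `"subject"`.
#' @param model_spec `"bivariate_cubic"` (default) or
#'   `"per_tpi_quadratic"`.
#' @param basis Basis for the cubic model.
#' @return List: `cv_mean_auc`, `cv_sd`, `per_rep` AUCs, `k`, `reps`,
#'   `seed`.
#' @export
repeated_cv_auc <- function(points, cutoff_gy, k = 5, reps = 100, seed = 1L,
                            stratify_by = c("group", "subject"),
                            model_spec = "bivariate_cubic",
                            basis = "total_degree") {
  stratify_by <- match.arg(stratify_by)
  n <- nrow(points)
  if (n < k) stop("fewer points than folds")
  labels <- points$dose_gy >= cutoff_gy
  if (!any(labels) || all(labels)) {
    stop("cutoff outside the observed dose range: one class is empty")
  }
  strata <- if (stratify_by == "group") {
    interaction(points$dose_gy, points$tpi_days, drop = TRUE)
  } else {
    if (is.null(points$subject_id)) stop("subject_id column required")
    factor(points$subject_id)
  }
  set.seed(seed)
  aucs <- numeric(reps)
  for (r in seq_len(reps)) {
    fold <- .stratified_folds(as.integer(strata), k)
    pred <- numeric(n)
    for (f in seq_len(k)) {
      test <- fold == f
      model <- .fit_model_spec(points[!test, , drop = FALSE], model_spec,
                               basis = basis)
      pred[test] <- .predict_model_spec(model, points[test, , drop = FALSE])
    }
    aucs[r] <- roc_auc(pred, labels)
  }
  list(cv_mean_auc = mean(aucs), cv_sd = stats::sd(aucs), per_rep = aucs,
       k = k, reps = reps, seed = as.integer(seed),
       stratify_by = stratify_by)
}

#' ROC evaluation of a dose cutoff, apparent and cross-validated
#'
#' Scores are model-predicted doses; positives are points at or above the
#' cutoff. Without `cv`, the model is fitted on all points and the apparent
#' AUC is reported; with `cv` (a list with `k`, `reps`, `seed`, optionally
#' `stratify_by`), the repeated cross-validated mean/sd AUC is added.
#'
#' @param points Dose-response data frame.
#' @param cutoff_gy Dose cutoff in Gy; must lie within the observed range so
#'   both classes are present.
#' @param model_spec,basis Calibration model selection.
#' @param cv Optional list of CV settings.
#' @return List of class `roc_evaluation`: `cutoff_gy`, `auc` (apparent),
#'   and `cv_mean_auc`, `cv_sd`, `k`, `reps`, `seed` when CV was run.
#' @export
evaluate_cutoff <- function(points, cutoff_gy, model_spec = "bivariate_cubic",
                            basis = "total_degree", cv = NULL) {
  labels <- points$dose_gy >= cutoff_gy
  if (!any(labels) || all(labels)) {
    stop("cutoff outside the observed dose range: one class is empty")
  }
  model <- .fit_model_spec(points, model_spec, basis = basis)
  scores <- .predict_model_spec(model, points)
  out <- list(cutoff_gy = cutoff_gy, auc = roc_auc(scores, labels),
              model = model)
  if (!is.null(cv)) {
    cvres <- repeated_cv_auc(points, cutoff_gy,
                             k = if (is.null(cv$k)) 5 else cv$k,
                             reps = if (is.null(cv$reps)) 100 else cv$reps,
                             seed = if (is.null(cv$seed)) 1L else cv$seed,
                             stratify_by = if (is.null(cv$stratify_by)) "group"
                                           else cv$stratify_by,
                             model_spec = model_spec, basis = basis)
    out <- c(out, cvres[c("cv_mean_auc", "cv_sd", "k", "reps", "seed")])
  }
  structure(out, class = "roc_evaluation")
}
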