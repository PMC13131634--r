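# Validation metrics and downstream statistics: functional connectivity,
# excess kurtosis, intraclass correlation, task GLM coefficients and
# behavioral regression models.

#' Functional connectivity matrix
#'
#' Pairwise Pearson correlations between parcel time series, optionally with
#' the Fisher z (atanh) transform applied to the off-diagonal entries.
#'
#' @param states n x T matrix (parcels by volumes), T >= 3, no constant rows.
#' @param fisher_z apply atanh to off-diagonals?
#' @return Symmetric n x n matrix.
#' @export
fc_matrix <- function(states, fisher_z = FALSE) {
  X <- as.matrix(states)
  if (ncol(X) < 3L) stopf("need at least 3 volumes")
  if (any(apply(X, 1, stats::sd) < 1e-12)) stopf("constant parcel series")
  R <- stats::cor(t(X))
  if (fisher_z) {
    z <- atanh(pmin(pmax(R, -1 + 1e-15), 1 - 1e-15))
    diag(z) <- diag(R)
    R <- z
  }
  R
}

#' Excess kurtosis
#'
#' Fourth standardized moment minus 3 (population moments); 0 for a normal
#' distribution, -2 for a symmetric two-point distribution.
#'
#' @param values numeric vector with at least 4 values and nonzero variance.
#' @return Scalar excess kurtosis.
#' @export
excess_kurtosis <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 4L) stopf("need at least 4 values")
  m <- mean(v)
  s2 <- mean((v - m)^2)
  if (s2 < 1e-24) stopf("zero variance")
  mean((v - m)^4) / s2^2 - 3
}

#' Intraclass correlation coefficient (test-retest)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC -- the
#' ICC(2,1) of Shrout and Fleiss -- computed from the ANOVA decomposition of
#' a subjects-by-visits table. A consistency variant, ICC(3,1), is available
#' as an option.
#'
#' @param visit1,visit2 numeric vectors of the same measure for S >= 3
#'   subjects at two visits.
#' @param type `"ICC(2,1)"` (absolute agreement, default) or `"ICC(3,1)"`
#'   (consistency).
#' @return Scalar in `[-1, 1]`.
#' @export
icc <- function(visit1, visit2, type = c("ICC(2,1)", "ICC(3,1)")) {
  type <- match.arg(type)
  Y <- cbind(as.numeric(visit1), as.numeric(visit2))
  S <- nrow(Y)
  if (S < 3L) stopf("need at least 3 subjects")
  k <- 2
  grand <- mean(Y)
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- S * sum((col_m - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (S - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((S - 1) * (k - 1))
  denom <- switch(type,
                  "ICC(2,1)" = msr + (k - 1) * mse + k * (msc - mse) / S,
                  "ICC(3,1)" = msr + (k - 1) * mse)
  if (abs(denom) < 1e-24) stopf("degenerate variance: ICC undefined")
  (msr - mse) / denom
}

#' Per-parcel task GLM coefficients
#'
#' Fits the pure noise-process model `x_t = mu + beta u_t + e_t` per parcel by
#' OLS, with the per-volume inputs of a [build_design()].
#'
#' @param states n x T matrix of neural states.
#' @param design a [build_design()] covering the same volumes.
#' @return A list with `mu` (length n) and `beta` (n x m).
#' @export
glm_task_betas <- function(states, design) {
  X <- as.matrix(states)
  U <- design$u
  if (ncol(U) != ncol(X)) stopf("design must cover every volume")
  Z <- cbind(1, t(U))
  if (qr(Z)$rank < ncol(Z)) stopf("collinear design")
  cf <- qr.solve(Z, t(X))
  beta <- t(cf[-1, , drop = FALSE])
  colnames(beta) <- design$conditions
  list(mu = as.numeric(cf[1, ]), beta = beta)
}

#' Fit a behavioral regression model
#'
#' OLS with intercept for a response in a feature table (e.g.
#' `accuracy ~ Bifurc + dist_DMN + dist_FPN + dist_TPN`), reporting
#' coefficients with standard errors, standardized coefficients, R-squared
#' and adjusted R-squared, the overall F test, AIC and BIC (Gaussian
#' likelihood with estimated variance).
#'
#' @param formula model formula.
#' @param data data frame with the response and predictors (typically a
#'   [build_feature_table()] plus behavioral columns).
#' @return An object of class `ols_result`; the underlying `lm` fit is in
#'   `$fit`.
#' @export
fit_behavior_model <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) stopf("singular design matrix")
  sm <- summary(fit)
  # standardized coefficients: fit on z-scored response and numeric predictors
  mf <- stats::model.frame(fit)
  zd <- as.data.frame(lapply(mf, function(col) {
    if (is.numeric(col) && stats::sd(col) > 0) as.numeric(scale(col)) else col
  }))
  zfit <- stats::lm(stats::formula(fit), data = zd)
  fstat <- sm$fstatistic
  structure(
    list(coefficients = stats::coef(sm),
         std_coefficients = stats::coef(zfit),
         r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         f_value = unname(fstat[1]), df = unname(fstat[2:3]),
         aic = stats::AIC(fit), bic = stats::BIC(fit), fit = fit),
    class = "ols_result")
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf("<ols_result> R2 = %.4f (adj %.4f), F(%g, %g) = %.3f, AIC = %.1f, BIC = %.1f\n",
              x$r_squared, x$adj_r_squared, x$df[1], x$df[2], x$f_value,
              x$aic, x$bic))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' Nested-model F test
#'
#' Compares a full behavioral model against a nested reduced model.
#'
#' @param full,reduced `ols_result` objects fit to the same data, with
#'   `reduced`'s terms a subset of `full`'s.
#' @return A list with `F`, `df` and `p_value`.
#' @export
compare_behavior_models <- function(full, reduced) {
  an <- stats::anova(reduced$fit, full$fit)
  list(F = an$F[2], df = c(an$Df[2], an$Res.Df[2]),
       p_value = an$`Pr(>F)`[2])
}

#' Preset behavioral model formulas
#'
#' The exploratory model family for a 3-motif task solution with motif labels
#' `DMN`, `FPN`, `TPN`: bifurcation-only, occupancy, distance, additive and
#' interaction models.
#'
#' @param response response column name (`"accuracy"` or `"logRT"`).
#' @return Named list of formulas.
#' @export
behavior_model_specs <- function(response = "accuracy") {
  f <- function(rhs) stats::as.formula(paste(response, "~", rhs))
  list(
    bifurcation = f("Bifurc"),
    occupancy   = f("occ_FPN + occ_TPN"),
    distance    = f("dist_DMN + dist_FPN + dist_TPN"),
    additive    = f("Bifurc + dist_DMN + dist_FPN + dist_TPN"),
    interaction = f("Bifurc * (dist_DMN + dist_FPN + dist_TPN)"))
}
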