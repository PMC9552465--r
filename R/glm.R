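#' Quasi-Poisson count regression with offset
#'
#' Fits a Poisson log-link GLM by iteratively reweighted least squares and
#' estimates the overdispersion factor from the Pearson statistic,
#' `phi = sum((y - mu)^2 / mu) / (n - p)`. Point estimates equal Poisson
#' maximum likelihood; reported standard errors scale by `sqrt(phi)`.
#'
#' @param y vector of nonnegative integer counts.
#' @param X design matrix (include an intercept column if wanted); must have
#'   full column rank.
#' @param offset log-exposure vector (e.g. `log(population)`); recycled if
#'   length 1.
#' @param tol IRLS convergence tolerance on relative deviance change.
#' @param max_iter maximum IRLS iterations.
#' @return an object of class `"qp_fit"`: coefficients, unscaled covariance
#'   (inverse Fisher information), Pearson `dispersion`, fitted values,
#'   `n_obs`, `n_params`, `converged`, and (when present) `smooth_info`.
#' @examples
#' f <- fit_quasipoisson(c(1, 3), X = matrix(1, 2, 1))
#' f$coef         # log(2)
#' f$dispersion   # 1
#' @export
fit_quasipoisson <- function(y, X, offset = 0, tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must match length(y)")
  if (anyNA(y) || any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("y must be nonnegative integer counts")
  offset <- rep_len(offset, n)
  if (any(!is.finite(offset))) stop("offset must be finite")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::glm.fit(X, y, offset = offset, family = stats::poisson(),
                        control = stats::glm.control(epsilon = tol,
                                                     maxit = max_iter))
  mu <- fit$fitted.values
  p <- ncol(X)
  pearson <- sum((y - mu)^2 / mu)
  dispersion <- if (n > p) pearson / (n - p) else NA_real_
  cov_unscaled <- chol2inv(chol(crossprod(X * sqrt(mu))))
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  structure(list(coef = stats::setNames(fit$coefficients, colnames(X)),
                 cov_unscaled = cov_unscaled,
                 dispersion = dispersion,
                 pearson = pearson,
                 fitted = mu,
                 y = y,
                 offset = offset,
                 deviance = fit$deviance,
                 n_obs = n, n_params = p,
                 converged = fit$converged,
                 smooth_info = NULL),
            class = "qp_fit")
}

#' @export
print.qp_fit <- function(x, ...) {
  cat("Quasi-Poisson fit:", x$n_obs, "observations,", x$n_params,
      "parameters\n")
  cat("Pearson dispersion:", format(x$dispersion, digits = 4), "\n")
  print(data.frame(estimate = x$coef,
                   se = sqrt(x$dispersion * diag(x$cov_unscaled))))
  invisible(x)
}

#' Rate ratio with dispersion-scaled, Bonferroni-adjusted Wald interval
#'
#' Exponentiates a fitted log-rate coefficient over a stated concentration
#' increment. Intervals are Wald on the log scale with standard errors scaled
#' by the square root of the Pearson dispersion; `m_comparisons > 1` applies a
#' Bonferroni correction to the interval level (each of `m` intervals is built
#' at level `1 - (1 - level)/m`).
#'
#' @param fit a [fit_quasipoisson()] (or smooth) fit.
#' @param term name of the coefficient to report.
#' @param scale concentration increment the rate ratio refers to (e.g. 1 index
#'   unit, or one interquartile range); must be positive.
#' @param level nominal coverage of the interval (default 0.95).
#' @param m_comparisons Bonferroni divisor; 1 means no correction.
#' @return object of class `"rate_ratio_ci"` with `estimate`, `lower`,
#'   `upper`, `scale`, `level`, `m_comparisons`, `term`.
#' @export
rate_ratio <- function(fit, term, scale = 1, level = 0.95, m_comparisons = 1) {
  stopifnot(inherits(fit, "qp_fit"), scale > 0, m_comparisons >= 1,
            level > 0, level < 1)
  if (!term %in% names(fit$coef))
    stop("unknown coefficient: ", term)
  beta <- fit$coef[[term]]
  se <- sqrt(fit$dispersion * fit$cov_unscaled[term, term])
  z <- stats::qnorm(1 - (1 - level) / (2 * m_comparisons))
  structure(list(estimate = exp(beta * scale),
                 lower = exp((beta - z * se) * scale),
                 upper = exp((beta + z * se) * scale),
                 scale = scale, level = level,
                 m_comparisons = m_comparisons, term = term),
            class = "rate_ratio_ci")
}

#' @export
print.rate_ratio_ci <- function(x, ...) {
  adj <- if (x$m_comparisons > 1)
    paste0(", Bonferroni m = ", x$m_comparisons) else ""
  cat(sprintf("RR %.4f (%.0f%% CI %.4f-%.4f) per %g unit(s) of %s%s\n",
              x$estimate, 100 * x$level, x$lower, x$upper, x$scale,
              x$term, adj))
  invisible(x)
}

#' Build a penalized B-spline (P-spline) smooth term
#'
#' Constructs a cubic (by default) B-spline basis on equally spaced knots
#' spanning the range of `x`, together with the difference penalty of the
#' requested order. Basis rows sum to 1 over the data range (partition of
#' unity); the penalty null space of order 2 contains straight lines, so an
#' infinitely penalized smooth degenerates to a linear trend.
#'
#' @param x covariate vector with at least `n_knots` distinct values.
#' @param n_knots number of interior knots spanning `range(x)` (default 20).
#' @param degree spline degree (default 3, cubic).
#' @param penalty_order order of the difference penalty (default 2).
#' @return object of class `"pspline_smooth"` with `basis` (n x K matrix),
#'   `penalty` (K x K), `knots`, and the parameters.
#' @export
build_pspline_smooth <- function(x, n_knots = 20, degree = 3,
                                 penalty_order = 2) {
  stopifnot(n_knots >= degree + 2, penalty_order >= 1)
  ux <- unique(x)
  if (length(ux) < n_knots)
    stop("too few distinct values: need at least ", n_knots, ", got ",
         length(ux))
  r <- range(x)
  h <- diff(r) / (n_knots - 1)
  knots <- seq(r[1] - degree * h, r[2] + degree * h, by = h)
  basis <- splines::splineDesign(knots, x, ord = degree + 1, outer.ok = TRUE)
  K <- ncol(basis)
  D <- diff(diag(K), differences = penalty_order)
  structure(list(basis = basis, penalty = crossprod(D), knots = knots,
                 x = x, degree = degree, n_knots = n_knots,
                 penalty_order = penalty_order),
            class = "pspline_smooth")
}

#' Quasi-Poisson regression with penalized-spline smooth confounders
#'
#' Fits a quasi-Poisson model with linear terms plus P-spline smooths for the
#' named covariates, each smoothing parameter chosen by restricted maximum
#' likelihood (REML) on the working model. The smooth machinery is
#' `mgcv::gam` with `bs = "ps"` bases, the standard implementation of this
#' estimator.
#'
#' @param y nonnegative integer counts.
#' @param linear_X data frame (or matrix) of covariates entering linearly;
#'   may be `NULL`.
#' @param smooths named list of covariate vectors to smooth, or a data frame;
#'   names become the smooth labels. Empty list reduces exactly to
#'   [fit_quasipoisson()].
#' @param offset log-exposure vector.
#' @param n_knots,degree,penalty_order P-spline basis parameters (defaults
#'   20 knots, cubic, second-order difference penalty).
#' @param fixed_df optional fixed effective degrees of freedom per smooth,
#'   bypassing REML selection.
#' @return a `"qp_fit"` object whose `smooth_info` lists per-smooth penalty
#'   parameter (`lambda`) and effective degrees of freedom (`edf`).
#' @export
fit_quasipoisson_smooth <- function(y, linear_X = NULL, smooths = list(),
                                    offset = 0, n_knots = 20, degree = 3,
                                    penalty_order = 2, fixed_df = NULL) {
  smooths <- as.list(smooths)
  if (!length(smooths)) {
    X <- if (is.null(linear_X)) matrix(1, length(y), 1,
                                       dimnames = list(NULL, "(Intercept)"))
         else cbind("(Intercept)" = 1, as.matrix(linear_X))
    return(fit_quasipoisson(y, X, offset = offset))
  }
  if (is.null(names(smooths)) || any(!nzchar(names(smooths))))
    stop("smooths must be a named list")
  n <- length(y)
  offset <- rep_len(offset, n)
  dat <- data.frame(.y = y, .off = offset)
  lin_terms <- character(0)
  if (!is.null(linear_X)) {
    linear_X <- as.data.frame(linear_X)
    if (length(intersect(names(linear_X), names(smooths))))
      stop("smooth covariates must be disjoint from linear covariates")
    dat <- cbind(dat, linear_X)
    lin_terms <- names(linear_X)
  }
  for (nm in names(smooths)) dat[[nm]] <- smooths[[nm]]
  k <- n_knots + degree - 1  # basis dimension for bs = "ps"
  sm <- if (is.null(fixed_df))
    sprintf("s(%s, bs = 'ps', k = %d, m = c(%d, %d))",
            names(smooths), k, degree - 1, penalty_order)
  else
    sprintf("s(%s, bs = 'ps', k = %d, m = c(%d, %d), fx = TRUE)",
            names(smooths), as.integer(fixed_df) + 1, degree - 1,
            penalty_order)
  fml <- stats::as.formula(paste(".y ~",
                                 paste(c(lin_terms, sm), collapse = " + "),
                                 "+ offset(.off)"))
  g <- mgcv::gam(fml, family = stats::quasipoisson(), data = dat,
                 method = "REML")
  cov_unscaled <- g$Vp / g$sig2  # remove gam's scale to match qp_fit contract
  structure(list(coef = stats::coef(g),
                 cov_unscaled = cov_unscaled,
                 dispersion = g$sig2,
                 pearson = sum(stats::residuals(g, type = "pearson")^2),
                 fitted = stats::fitted(g),
                 y = y, offset = offset,
                 deviance = g$deviance,
                 n_obs = n,
                 n_params = sum(g$edf),
                 converged = g$converged,
                 smooth_info = data.frame(
                   term = names(smooths),
                   lambda = if (is.null(fixed_df)) g$sp else NA_real_,
                   edf = vapply(seq_along(smooths), function(i) {
                     idx <- g$smooth[[i]]$first.para:g$smooth[[i]]$last.para
                     sum(g$edf[idx])
                   }, numeric(1))),
                 gam = g),
            class = "qp_fit")
}
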