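# Core machinery for split-sample weighted quantile sum estimation:
# the simplex-constrained Poisson fit inside each bootstrap, the sign filter
# and pooling of bootstrap weights, and the validation-split rate model.

#' Split rows into disjoint training and validation sets
#'
#' @param n number of rows (or a data frame, whose row count is used).
#' @param fraction training share in (0, 1); training size is
#'   `ceiling(n * fraction)`.
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return list with integer index vectors `train` and `validation`.
#' @export
split_train_validation <- function(n, fraction = 0.5, seed = 1L) {
  if (is.data.frame(n) || is.matrix(n)) n <- nrow(n)
  n <- as.integer(n)
  if (n < 1) stop("dataset is empty")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_train <- as.integer(ceiling(n * fraction))
  if (n_train == 0L || n_train == n)
    stop("split leaves an empty training or validation set")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  train <- sort(sample.int(n, n_train))
  list(train = train, validation = setdiff(seq_len(n), train))
}

# Preserve caller's RNG state around internally seeded draws.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Deterministic per-bootstrap seed derived from the master seed.
.derive_seed <- function(seed, b) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(b)) %% 2147483629)
}

# Maximize the Poisson log-likelihood of
#   log mu = th0 + th1 * (Q %*% w) + X th2 + offset,  w = softmax(z), z1 = 0,
# over the softmax scores z, with the regression coefficients profiled out
# by an inner IRLS fit at each candidate w; the outer gradient over z is the
# likelihood score in w at the inner optimum (envelope theorem). A final
# GLM at the pooled-optimal weights reports theta1 and its standard error.
.wqs_solve <- function(Q, y, X = NULL, offset = 0, tol = 1e-8,
                       max_iter = 1000) {
  Q <- as.matrix(Q)
  n <- length(y); p <- ncol(Q)
  offset <- rep_len(offset, n)
  has_X <- !is.null(X) && ncol(as.matrix(X)) > 0
  if (has_X) X <- as.matrix(X)

  glm_at <- function(w) {
    idx <- drop(Q %*% w)
    Xd <- if (has_X) cbind("(Intercept)" = 1, wqs = idx, X)
          else cbind("(Intercept)" = 1, wqs = idx)
    fit <- stats::glm.fit(Xd, y, offset = offset, family = stats::poisson())
    mu <- fit$fitted.values
    cov_u <- tryCatch(chol2inv(chol(crossprod(Xd * sqrt(mu)))),
                      error = function(e) NULL)
    list(coef = fit$coefficients, cov_unscaled = cov_u,
         converged = fit$converged, loglik = sum(y * log(mu) - mu))
  }

  if (p == 1L) {
    g <- glm_at(1)
    return(list(weights = stats::setNames(1, colnames(Q)),
                theta1 = g$coef[["wqs"]],
                se_theta1 = if (is.null(g$cov_unscaled)) NA_real_
                            else sqrt(g$cov_unscaled[2, 2]),
                converged = g$converged, loglik = g$loglik))
  }

  # Standardize covariate columns for the inner fits: raw covariates with
  # large means are nearly collinear with the intercept. The weights,
  # theta1 and its standard error are invariant to this affine
  # reparameterization of the nuisance covariates.
  if (has_X) {
    X_sd <- apply(X, 2, stats::sd)
    X_sd[X_sd == 0] <- 1
    X <- scale(X, center = TRUE, scale = X_sd)
  }

  # Tiny ridge on the unconstrained scores: the softmax gradient vanishes
  # as a weight saturates at 0 or 1, so an unpenalized search can stall on
  # the boundary plateau; the ridge keeps a restoring gradient there while
  # moving interior optima by a negligible amount.
  ridge <- 1e-6
  softmax <- function(z) {
    z <- z - max(z)
    ez <- exp(z)
    ez / sum(ez)
  }
  # Profiled objective and its envelope gradient share one evaluation,
  # cached because the solver asks for both at the same point.
  cache <- new.env(parent = emptyenv())
  cache$z <- NULL
  eval_at <- function(z) {
    if (identical(z, cache$z)) return(invisible())
    w <- softmax(c(0, z))
    idx <- drop(Q %*% w)
    Xd <- if (has_X) cbind(1, idx, X) else cbind(1, idx)
    fit <- tryCatch(
      stats::glm.fit(Xd, y, offset = offset, family = stats::poisson(),
                     etastart = cache$eta),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$coefficients))) {
      cache$z <- z
      cache$negll <- 1e12
      cache$gz <- rep(0, p - 1)
      return(invisible())
    }
    mu <- fit$fitted.values
    r <- y - mu
    g_w <- fit$coefficients[2] * drop(crossprod(Q, r))
    g_z_full <- w * (g_w - sum(w * g_w))
    cache$z <- z
    cache$eta <- log(mu)
    cache$negll <- -sum(y * log(mu) - mu) + ridge * sum(z^2)
    cache$gz <- -g_z_full[-1] + 2 * ridge * z
    invisible()
  }
  objective <- function(z) { eval_at(z); cache$negll }
  gradient <- function(z) { eval_at(z); cache$gz }

  # Box on the softmax scores: |z| <= 12 spans weight ratios of e^24, wide
  # enough for effectively one-hot weights, while keeping an overshooting
  # line-search step on a part of the plateau the gradient can recover from.
  zbound <- 12
  opt <- stats::nlminb(rep(0, p - 1), objective, gradient,
                       lower = rep(-zbound, p - 1),
                       upper = rep(zbound, p - 1),
                       control = list(iter.max = max_iter,
                                      eval.max = 2 * max_iter,
                                      rel.tol = tol))
  w <- softmax(c(0, opt$par))
  names(w) <- colnames(Q)
  polish <- glm_at(w)
  # Accept on first-order optimality, not just the solver's return code:
  # on flat simplex directions nlminb can report "false convergence" at a
  # point whose projected gradient is already negligible.
  g <- gradient(opt$par)
  at_bound <- (opt$par <= -zbound + 1e-8 & g > 0) |
    (opt$par >= zbound - 1e-8 & g < 0)
  g[at_bound] <- 0
  first_order_ok <- max(abs(g)) <= 1e-4 * (1 + abs(opt$objective))
  list(weights = w,
       theta1 = polish$coef[["wqs"]],
       se_theta1 = if (is.null(polish$cov_unscaled)) NA_real_
                   else sqrt(polish$cov_unscaled[2, 2]),
       converged = (opt$convergence == 0 || first_order_ok) &&
         polish$converged,
       loglik = polish$loglik)
}

#' Estimate simplex-constrained weights on one bootstrap resample
#'
#' Resamples training rows with replacement and maximizes the Poisson
#' log-likelihood of the rate model over the regression parameters and the
#' component weights jointly, with the weights constrained to the unit
#' simplex through a normalized-exponential (softmax) reparameterization
#' started at equal weights.
#'
#' @param scores integer score matrix (training rows x components) from
#'   [score_quantiles()].
#' @param y training counts.
#' @param X optional covariate matrix (no intercept column).
#' @param offset log-population offset.
#' @param seed seed for this bootstrap's resample.
#' @param tol,max_iter optimizer tolerance and iteration cap.
#' @return list with `weights` (on the simplex), `theta1` (index
#'   coefficient), `se_theta1`, `converged`, `seed_used`.
#' @export
fit_single_bootstrap <- function(scores, y, X = NULL, offset = 0,
                                 seed = 1L, tol = 1e-8, max_iter = 1000) {
  n <- length(y)
  stopifnot(nrow(scores) == n)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  idx <- sample.int(n, n, replace = TRUE)
  res <- tryCatch(
    .wqs_solve(scores[idx, , drop = FALSE], y[idx],
               if (is.null(X)) NULL else X[idx, , drop = FALSE],
               rep_len(offset, n)[idx], tol = tol, max_iter = max_iter),
    error = function(e) list(weights = rep(NA_real_, ncol(scores)),
                             theta1 = NA_real_, se_theta1 = NA_real_,
                             converged = FALSE, loglik = NA_real_,
                             error = conditionMessage(e)))
  res$seed_used <- seed
  res
}

#' Pool bootstrap weight estimates in the requested direction
#'
#' Retains converged bootstrap fits whose index coefficient points in the
#' requested direction (`"positive"` keeps `theta1 >= 0` — associations that
#' are positive or null) and averages their weight vectors. The default is
#' the plain mean; `rule = "signal_weighted"` weights each bootstrap by the
#' magnitude of its `theta1` t-statistic.
#'
#' @param results list of [fit_single_bootstrap()] results.
#' @param direction `"positive"` (default) or `"negative"`.
#' @param rule pooling rule, `"mean"` (default) or `"signal_weighted"`.
#' @return object of class `"wqs_weights"`: `w` (pooled simplex weights),
#'   `n_retained`, `n_total`, `components`.
#' @export
pool_weights <- function(results, direction = c("positive", "negative"),
                         rule = c("mean", "signal_weighted")) {
  direction <- match.arg(direction)
  rule <- match.arg(rule)
  if (!length(results)) stop("no bootstrap results to pool")
  th <- vapply(results, function(r) r$theta1, numeric(1))
  conv <- vapply(results, function(r) isTRUE(r$converged), logical(1))
  keep <- conv & !is.na(th) &
    (if (direction == "positive") th >= 0 else th <= 0)
  if (!any(keep))
    stop("no bootstraps in the requested direction (", direction, ")")
  W <- do.call(rbind, lapply(results[keep], function(r) r$weights))
  w <- if (rule == "mean") {
    colMeans(W)
  } else {
    tstat <- abs(th[keep] / vapply(results[keep], function(r) r$se_theta1,
                                   numeric(1)))
    tstat[!is.finite(tstat)] <- 0
    if (sum(tstat) == 0) colMeans(W)
    else colSums(W * (tstat / sum(tstat)))
  }
  w <- w / sum(w)
  structure(list(w = w, components = colnames(W),
                 n_retained = sum(keep), n_total = length(results)),
            class = "wqs_weights")
}

#' @export
print.wqs_weights <- function(x, ...) {
  cat("Pooled WQS weights (", x$n_retained, "of", x$n_total,
      "bootstraps retained)\n")
  print(round(sort(x$w, decreasing = TRUE), 4))
  invisible(x)
}

#' Weighted quantile sum index
#'
#' Computes, per row, `sum_i w_i * q_i` — the weighted sum of component
#' quantile scores. With weights on the simplex the index is bounded in
#' `[0, q - 1]`, and one index unit is approximately a one-quantile increase
#' in every component simultaneously.
#'
#' @param scores score matrix from [score_quantiles()].
#' @param weights a [pool_weights()] result, or a named numeric weight
#'   vector matching the score columns.
#' @return numeric index vector.
#' @export
compute_wqs_index <- function(scores, weights) {
  w <- if (inherits(weights, "wqs_weights")) weights$w else weights
  if (is.null(names(w))) {
    if (length(w) != ncol(scores)) stop("component mismatch")
    names(w) <- colnames(scores)
  }
  missing_w <- setdiff(colnames(scores), names(w))
  extra_w <- setdiff(names(w), colnames(scores))
  if (length(missing_w) || length(extra_w))
    stop("component mismatch: ",
         paste(c(missing_w, extra_w), collapse = ", "))
  drop(scores[, names(w), drop = FALSE] %*% w)
}

#' Fit the validation-split rate model for a pooled index
#'
#' Quasi-Poisson regression of validation counts on the WQS index plus linear
#' covariates with a log-population offset; reports the mortality rate ratio
#' per one index unit with a dispersion-scaled Wald interval.
#'
#' @param scores validation score matrix (scored with training-fitted
#'   breaks).
#' @param y validation counts.
#' @param weights pooled [pool_weights()] weights.
#' @param X optional covariate matrix.
#' @param offset log-population offset.
#' @param level interval coverage (default 0.95).
#' @return list with `glm` (a `"qp_fit"`), `rate_ratio` (a
#'   `"rate_ratio_ci"` per one index unit), and `index`.
#' @export
fit_final_model <- function(scores, y, weights, X = NULL, offset = 0,
                            level = 0.95) {
  idx <- compute_wqs_index(scores, weights)
  Xd <- if (is.null(X) || ncol(as.matrix(X)) == 0)
    cbind("(Intercept)" = 1, wqs = idx)
  else cbind("(Intercept)" = 1, wqs = idx, as.matrix(X))
  fit <- fit_quasipoisson(y, Xd, offset = offset)
  list(glm = fit,
       rate_ratio = rate_ratio(fit, "wqs", scale = 1, level = level),
       index = idx)
}
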