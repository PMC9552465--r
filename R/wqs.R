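#' Split-sample weighted quantile sum regression for count outcomes
#'
#' Fits a weighted quantile sum (WQS) regression: the data are split into a
#' training and a validation half; component concentrations are scored into
#' quantiles (deciles by default) with cut points learned on the training
#' split; simplex-constrained component weights are estimated on bootstrap
#' resamples of the training split by maximizing the Poisson likelihood of
#' the rate model; converged bootstraps whose mixture coefficient points in
#' the analysis direction (positive or null, by default) are averaged into
#' the final weights; and the cumulative mixture-outcome association is
#' estimated on the validation split by quasi-Poisson regression of counts on
#' the pooled index plus linear covariates, with a log-population offset.
#'
#' The reported rate ratio is per one index unit — approximately a
#' one-quantile increase in all components simultaneously.
#'
#' @param formula model formula `counts ~ covariates` naming the outcome
#'   count column and the covariates that enter the rate model linearly
#'   (use `counts ~ 1` for no covariates).
#' @param data data frame holding the outcome, covariates, mixture component
#'   concentrations and the population column.
#' @param mix character vector naming the mixture component columns.
#' @param population name of the population-at-risk column (log-offset), or a
#'   numeric vector; `NULL` fits an unoffset count model.
#' @param q number of quantile groups (default 10, deciles).
#' @param n_bootstrap number of bootstrap resamples of the training split
#'   (default 250).
#' @param split_fraction training share of the 50:50-style split
#'   (default 0.5).
#' @param direction retain bootstraps with a `"positive"` (theta1 >= 0,
#'   default) or `"negative"` association.
#' @param pooling `"mean"` (default) or `"signal_weighted"` averaging of
#'   retained bootstrap weights.
#' @param drop optional component labels to exclude before scoring (the
#'   drop-one sensitivity analysis).
#' @param seed master seed; the split and every bootstrap derive their seeds
#'   deterministically from it.
#' @param tol,max_iter optimizer tolerance and iteration cap per bootstrap.
#' @param max_fail error if more than this fraction of bootstraps fails to
#'   converge (default 0.2).
#' @param level confidence level of the reported interval.
#' @return an object of class `"wqs"`; see [summary.wqs()]. Key elements:
#'   `weights` (pooled simplex weights), `rate_ratio` (per index unit),
#'   `fit` (validation quasi-Poisson `"qp_fit"`), `breaks`
#'   (training-fitted quantile cut points), `bootstrap` (per-bootstrap
#'   diagnostics), `split` (row indices).
#' @examples
#' sim <- make_study_like_dataset(n_units = 40, n_years = 4, seed = 7)
#' fit <- wqs(cardiovascular ~ temperature + humidity, data = sim$data,
#'            mix = sim$components, population = "population",
#'            n_bootstrap = 5, seed = 7)
#' fit
#' @export
wqs <- function(formula, data, mix, population = "population", q = 10,
                n_bootstrap = 250, split_fraction = 0.5,
                direction = c("positive", "negative"),
                pooling = c("mean", "signal_weighted"),
                drop = NULL, seed = 1L, tol = 1e-8, max_iter = 1000,
                max_fail = 0.2, level = 0.95) {
  direction <- match.arg(direction)
  pooling <- match.arg(pooling)
  cl <- match.call()
  data <- as.data.frame(data)
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1")

  mix_use <- setdiff(mix, drop)
  if (!length(mix_use))
    stop("drop list removes every component")
  missing_mix <- setdiff(mix_use, names(data))
  if (length(missing_mix))
    stop("mixture component(s) not in data: ",
         paste(missing_mix, collapse = ", "))

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  outcome_label <- deparse(formula[[2]])
  X <- stats::model.matrix(stats::terms(formula), mf)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  if (ncol(X) == 0) X <- NULL

  offset <- if (is.null(population)) {
    rep(0, nrow(data))
  } else {
    pop <- if (is.character(population)) data[[population]] else population
    if (is.null(pop)) stop("population column not found: ", population)
    if (any(pop <= 0)) stop("population must be positive on every row")
    log(pop)
  }

  sp <- split_train_validation(nrow(data), split_fraction, seed)
  breaks <- quantile_breaks(data[sp$train, , drop = FALSE], q = q,
                            components = mix_use)
  Qtr <- score_quantiles(data[sp$train, , drop = FALSE], breaks)
  Qval <- score_quantiles(data[sp$validation, , drop = FALSE], breaks)

  boots <- lapply(seq_len(n_bootstrap), function(b) {
    fit_single_bootstrap(Qtr, y[sp$train],
                         if (is.null(X)) NULL else X[sp$train, , drop = FALSE],
                         offset[sp$train],
                         seed = .derive_seed(seed, b),
                         tol = tol, max_iter = max_iter)
  })
  n_conv <- sum(vapply(boots, function(b) isTRUE(b$converged), logical(1)))
  if ((n_bootstrap - n_conv) / n_bootstrap > max_fail)
    stop("too many non-converged bootstraps: ", n_bootstrap - n_conv,
         " of ", n_bootstrap)

  weights <- pool_weights(boots, direction = direction, rule = pooling)
  final <- fit_final_model(Qval, y[sp$validation], weights,
                           if (is.null(X)) NULL
                           else X[sp$validation, , drop = FALSE],
                           offset[sp$validation], level = level)

  structure(list(call = cl,
                 outcome_label = outcome_label,
                 components = mix_use,
                 dropped = drop,
                 weights = weights$w,
                 pooled = weights,
                 rate_ratio = final$rate_ratio,
                 fit = final$glm,
                 index = final$index,
                 breaks = breaks,
                 bootstrap = data.frame(
                   theta1 = vapply(boots, function(b) b$theta1, numeric(1)),
                   se_theta1 = vapply(boots, function(b) b$se_theta1,
                                      numeric(1)),
                   converged = vapply(boots, function(b) isTRUE(b$converged),
                                      logical(1)),
                   seed = vapply(boots, function(b) b$seed_used, numeric(1))),
                 bootstrap_weights = do.call(rbind, lapply(boots, `[[`,
                                                           "weights")),
                 split = sp,
                 config = list(q = q, n_bootstrap = n_bootstrap,
                               split_fraction = split_fraction,
                               direction = direction, pooling = pooling,
                               seed = seed, tol = tol, max_iter = max_iter,
                               level = level,
                               population_col = if (is.character(population))
                                 population else NULL)),
            class = "wqs")
}

#' @export
print.wqs <- function(x, ...) {
  cat("Weighted quantile sum regression (", x$outcome_label, ")\n", sep = "")
  cat("  ", length(x$components), " components scored into ", x$config$q,
      " quantile groups; ", x$pooled$n_retained, "/", x$pooled$n_total,
      " bootstraps retained\n", sep = "")
  print(x$rate_ratio)
  top <- sort(x$weights, decreasing = TRUE)[seq_len(min(5, length(x$weights)))]
  cat("Largest weights:\n")
  print(round(top, 4))
  invisible(x)
}

#' Summarize a fitted WQS model
#'
#' @param object a [wqs()] fit.
#' @param ... unused.
#' @return a `"summary.wqs"` list with the weight table, rate ratio,
#'   dispersion and bootstrap retention counts.
#' @export
summary.wqs <- function(object, ...) {
  structure(list(call = object$call,
                 outcome_label = object$outcome_label,
                 weight_table = data.frame(
                   component = names(object$weights),
                   weight = unname(object$weights),
                   row.names = NULL)[order(-object$weights), ],
                 rate_ratio = object$rate_ratio,
                 dispersion = object$fit$dispersion,
                 coef = object$fit$coef,
                 se = sqrt(object$fit$dispersion *
                             diag(object$fit$cov_unscaled)),
                 n_retained = object$pooled$n_retained,
                 n_total = object$pooled$n_total,
                 n_train = length(object$split$train),
                 n_validation = length(object$split$validation)),
            class = "summary.wqs")
}

#' @export
print.summary.wqs <- function(x, ...) {
  cat("Weighted quantile sum regression (", x$outcome_label, ")\n", sep = "")
  cat("Split: ", x$n_train, " training / ", x$n_validation,
      " validation rows; ", x$n_retained, "/", x$n_total,
      " bootstraps retained\n", sep = "")
  print(x$rate_ratio)
  cat("Validation-model Pearson dispersion:",
      format(x$dispersion, digits = 4), "\n\nWeights:\n")
  print(transform(x$weight_table, weight = round(weight, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.wqs <- function(object, ...) object$fit$coef

#' @export
weights.wqs <- function(object, ...) object$weights

#' @export
residuals.wqs <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  y <- object$fit$y; mu <- object$fit$fitted
  if (type == "pearson") (y - mu) / sqrt(mu)
  else sign(y - mu) * sqrt(2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu)))
}

#' Predict from a fitted WQS model
#'
#' Scores new concentrations with the training-fitted quantile breaks, forms
#' the pooled index, and (for `type` `"link"`/`"response"`) evaluates the
#' validation rate model, which requires the model covariates and population
#' column in `newdata`.
#'
#' @param object a [wqs()] fit.
#' @param newdata data frame with the mixture components (and, for rate
#'   predictions, covariates and population); defaults to refitting rows are
#'   not stored, so `newdata` is required.
#' @param type `"index"` (the WQS index), `"link"` (log expected count) or
#'   `"response"` (expected count).
#' @param ... unused.
#' @export
predict.wqs <- function(object, newdata,
                        type = c("index", "link", "response"), ...) {
  type <- match.arg(type)
  scores <- score_quantiles(newdata, object$breaks)
  idx <- compute_wqs_index(scores, object$pooled)
  if (type == "index") return(idx)
  fml <- stats::formula(object$call$formula)
  rhs <- stats::delete.response(stats::terms(fml))
  X <- stats::model.matrix(rhs, stats::model.frame(rhs, newdata))
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  pop_col <- object$config$population_col
  off <- if (is.null(pop_col)) 0 else log(newdata[[pop_col]])
  beta <- object$fit$coef
  eta <- beta[["(Intercept)"]] + beta[["wqs"]] * idx + off
  if (ncol(X)) eta <- eta + drop(X %*% beta[colnames(X)])
  if (type == "link") eta else exp(eta)
}

#' Plot pooled WQS weights
#'
#' Bar plot of the pooled component weights, sorted, with a dashed reference
#' line at `1/p` (the weight every component would get if none mattered more
#' than any other).
#'
#' @param x a [wqs()] fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.wqs <- function(x, ...) {
  w <- sort(x$weights, decreasing = TRUE)
  bp <- graphics::barplot(w, las = 2, ylab = "pooled weight",
                          main = paste("WQS weights:", x$outcome_label), ...)
  graphics::abline(h = 1 / length(w), lty = 2, col = "red")
  invisible(bp)
}
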