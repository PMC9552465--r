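test_that("quasi-Poisson fit reproduces hand calculations", {
  f <- fit_quasipoisson(c(1, 3), matrix(1, 2, 1,
                                        dimnames = list(NULL, "b0")))
  expect_equal(unname(f$coef), log(2), tolerance = 1e-8)
  # Pearson statistic (1-2)^2/2 + (3-2)^2/2 = 1, df = 1
  expect_equal(f$dispersion, 1, tolerance = 1e-8)
})

test_that("offset shifts translate the intercept exactly", {
  set.seed(1)
  y <- rpois(50, 5)
  X <- cbind(1, rnorm(50))
  f0 <- fit_quasipoisson(y, X, offset = 0)
  f1 <- fit_quasipoisson(y, X, offset = log(2))
  expect_equal(f1$coef[[1]], f0$coef[[1]] - log(2), tolerance = 1e-9)
  expect_equal(f1$coef[[2]], f0$coef[[2]], tolerance = 1e-9)
  expect_equal(f1$dispersion, f0$dispersion, tolerance = 1e-9)
})

test_that("dispersion is near 1 for pure Poisson data", {
  set.seed(7)
  n <- 5000
  x <- rnorm(n)
  y <- rpois(n, exp(1 + 0.3 * x))
  f <- fit_quasipoisson(y, cbind(1, x))
  expect_gt(f$dispersion, 0.9)
  expect_lt(f$dispersion, 1.1)
})

test_that("fit validation catches bad inputs and satisfies score equations", {
  expect_error(fit_quasipoisson(c(1, -1), matrix(1, 2, 1)), "nonnegative")
  expect_error(fit_quasipoisson(c(1.5, 2), matrix(1, 2, 1)), "integer")
  X <- cbind(a = rep(1, 10), b = 1:10, c = 2 * (1:10))
  expect_error(fit_quasipoisson(rpois(10, 3), X), "c")
  # X'(y - mu) = 0 at convergence
  set.seed(3)
  Xok <- cbind(1, rnorm(100))
  y <- rpois(100, exp(0.5 + 0.2 * Xok[, 2]))
  f <- fit_quasipoisson(y, Xok)
  expect_lt(max(abs(crossprod(Xok, y - f$fitted))), 1e-6)
})

test_that("rate ratios exponentiate over the stated increment", {
  set.seed(5)
  x <- rnorm(200)
  y <- rpois(200, exp(1 + 0.01 * x))
  f <- fit_quasipoisson(y, cbind(b0 = 1, pm = x))
  beta <- f$coef[["pm"]]
  rr <- rate_ratio(f, "pm", scale = 2.80)
  expect_equal(rr$estimate, exp(beta * 2.80), tolerance = 1e-12)
  # with beta forced to ~0 the interval contains 1
  y0 <- rpois(2000, 3)
  f0 <- fit_quasipoisson(y0, cbind(b0 = 1, pm = rnorm(2000)))
  rr0 <- rate_ratio(f0, "pm")
  expect_true(rr0$lower < 1 && 1 < rr0$upper)
  expect_error(rate_ratio(f, "nope"), "unknown")
})

test_that("Bonferroni adjustment uses the right quantile and is monotone", {
  set.seed(5)
  y <- rpois(100, 4)
  f <- fit_quasipoisson(y, cbind(b0 = 1, x = rnorm(100)))
  rr15 <- rate_ratio(f, "x", level = 0.95, m_comparisons = 15)
  se <- sqrt(f$dispersion * f$cov_unscaled["x", "x"])
  z <- qnorm(1 - 0.05 / 30)
  expect_equal(log(rr15$upper), f$coef[["x"]] + z * se, tolerance = 1e-10)
  widths <- vapply(c(1, 2, 5, 15), function(m) {
    r <- rate_ratio(f, "x", m_comparisons = m)
    log(r$upper) - log(r$lower)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("P-spline basis is a partition of unity with the right penalty", {
  set.seed(11)
  x <- runif(300, -2, 5)
  sm <- build_pspline_smooth(x, n_knots = 12, degree = 3, penalty_order = 2)
  expect_equal(rowSums(sm$basis), rep(1, 300), tolerance = 1e-10)
  expect_equal(sm$penalty, t(sm$penalty))
  expect_true(all(eigen(sm$penalty, only.values = TRUE)$values > -1e-10))
  expect_error(build_pspline_smooth(rep(1:3, 10), n_knots = 12), "distinct")
})

test_that("difference-penalty limits recover linear and unpenalized fits", {
  set.seed(12)
  x <- sort(runif(200))
  y <- 2 + 3 * x + rnorm(200, sd = 0.1)
  sm <- build_pspline_smooth(x, n_knots = 10)
  B <- sm$basis
  pen_fit <- function(lambda) {
    drop(B %*% solve(crossprod(B) + lambda * sm$penalty, crossprod(B, y)))
  }
  # lambda -> infinity: order-2 penalty null space is a straight line
  lin <- unname(fitted(lm(y ~ x)))
  expect_equal(pen_fit(1e9), lin, tolerance = 1e-4)
  # lambda = 0: plain regression on the basis columns
  expect_equal(pen_fit(0), fitted(lm(y ~ B - 1)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("smooth quasi-Poisson reduces to the parametric fit and adjusts
           nonlinear confounding", {
  set.seed(13)
  n <- 600
  z <- runif(n, -2, 2)
  x <- rnorm(n)
  y <- rpois(n, exp(0.5 + 0.2 * x + 0.4 * z^2))
  # empty smooth list: identical to fit_quasipoisson
  f_plain <- fit_quasipoisson(y, cbind("(Intercept)" = 1, x = x))
  f_empty <- fit_quasipoisson_smooth(y, linear_X = data.frame(x = x))
  expect_equal(f_empty$coef, f_plain$coef, tolerance = 1e-10)
  # smooth recovers the quadratic shape better than a linear term
  f_sm <- fit_quasipoisson_smooth(y, linear_X = data.frame(x = x),
                                  smooths = list(z = z))
  f_lin <- fit_quasipoisson(y, cbind(1, x, z))
  truth <- exp(0.5 + 0.2 * x + 0.4 * z^2)
  mse_sm <- mean((f_sm$fitted - truth)^2)
  mse_lin <- mean((f_lin$fitted - truth)^2)
  expect_lt(mse_sm, mse_lin)
  expect_equal(nrow(f_sm$smooth_info), 1L)
  expect_gt(f_sm$smooth_info$edf, 1)
})

test_that("smooth adjustment keeps the exposure coefficient unbiased", {
  set.seed(14)
  reps <- 30
  est <- vapply(seq_len(reps), function(r) {
    n <- 400
    z <- runif(n, -2, 2)
    x <- rnorm(n) + 0.5 * z          # exposure correlated with confounder
    y <- rpois(n, exp(0.3 + 0.15 * x + 0.5 * z^2))
    f <- fit_quasipoisson_smooth(y, linear_X = data.frame(x = x),
                                 smooths = list(z = z))
    f$coef[["x"]]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.15), 3 * sd(est) / sqrt(reps))
})
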