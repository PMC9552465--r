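test_that("train/validation split is disjoint, exhaustive and seeded", {
  sp <- split_train_validation(100, 0.5, seed = 3)
  expect_length(sp$train, 50)
  expect_length(sp$validation, 50)
  expect_length(intersect(sp$train, sp$validation), 0)
  sp101 <- split_train_validation(101, 0.5, seed = 3)
  expect_length(sp101$train, 51)
  expect_length(sp101$validation, 50)
  expect_setequal(c(sp101$train, sp101$validation), 1:101)
  expect_identical(split_train_validation(100, 0.5, seed = 9),
                   split_train_validation(100, 0.5, seed = 9))
  expect_false(identical(split_train_validation(100, 0.5, seed = 9)$train,
                         split_train_validation(100, 0.5, seed = 10)$train))
  expect_error(split_train_validation(0, 0.5), "empty")
  expect_error(split_train_validation(10, 1.2), "fraction")
})

test_that("a one-component mixture forces weight 1 and the plain GLM slope", {
  toy <- toy_wqs_data(n = 120, p = 1, weights = 1, seed = 21)
  b <- fit_single_bootstrap(toy$scores, toy$y, seed = 5)
  expect_identical(unname(b$weights), 1)
  # theta1 equals the plain Poisson slope on the resampled rows
  set.seed(5)
  idx <- sample.int(120, 120, replace = TRUE)
  ref <- glm(toy$y[idx] ~ toy$scores[idx, 1], family = poisson())
  expect_equal(b$theta1, unname(coef(ref)[2]), tolerance = 1e-6)
})

test_that("the simplex optimizer agrees with a profile grid search", {
  for (seed in c(101, 202, 303)) {
    toy <- toy_wqs_data(n = 40, p = 2, weights = c(0.7, 0.3),
                        theta1 = 0.5, seed = seed)
    sol <- wqsmix:::.wqs_solve(toy$scores, toy$y)
    w1_grid <- grid_w1_oracle(toy$scores[, 1], toy$scores[, 2], toy$y)
    expect_lt(abs(sol$weights[[1]] - w1_grid), 0.02)
  }
})

test_that("a dominant component is recovered across seeded bootstraps", {
  toy <- toy_wqs_data(n = 300, p = 3, weights = c(1, 0, 0),
                      theta1 = 0.6, seed = 31)
  hits <- vapply(1:20, function(b) {
    r <- fit_single_bootstrap(toy$scores, toy$y, seed = 1000 + b)
    r$weights[[1]] > 0.8
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("pooling filters by sign and preserves the simplex", {
  mk <- function(th, w) list(weights = w, theta1 = th, se_theta1 = 0.1,
                             converged = TRUE)
  # sign filter
  pooled <- pool_weights(list(mk(0.1, c(a = 1, b = 0)),
                              mk(-0.1, c(a = 0, b = 1))))
  expect_equal(unname(pooled$w), c(1, 0))
  expect_equal(pooled$n_retained, 1L)
  # all-negative retention errors
  expect_error(pool_weights(list(mk(-0.2, c(a = 1, b = 0)))),
               "no bootstraps")
  # mean of identical inputs is the input
  pooled2 <- pool_weights(list(mk(0.1, c(a = 0.4, b = 0.6)),
                               mk(0.2, c(a = 0.4, b = 0.6))))
  expect_equal(pooled2$w, c(a = 0.4, b = 0.6))
  # signal-weighted pooling leans toward the stronger bootstrap
  r1 <- list(weights = c(a = 1, b = 0), theta1 = 0.5, se_theta1 = 0.05,
             converged = TRUE)
  r2 <- list(weights = c(a = 0, b = 1), theta1 = 0.05, se_theta1 = 0.5,
             converged = TRUE)
  psw <- pool_weights(list(r1, r2), rule = "signal_weighted")
  expect_gt(psw$w[["a"]], 0.9)
  # non-converged results are excluded
  p3 <- pool_weights(list(mk(0.1, c(a = 1, b = 0)),
                          list(weights = c(a = 0, b = 1), theta1 = 0.3,
                               se_theta1 = 0.1, converged = FALSE)))
  expect_equal(p3$n_retained, 1L)
})

test_that("the index is the weighted score sum, bounded in [0, q-1]", {
  Q <- matrix(c(2L, 4L, 0L, 3L), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(compute_wqs_index(Q, c(a = 0.5, b = 0.5)), c(1, 3.5))
  expect_equal(compute_wqs_index(Q, c(a = 1, b = 0)), c(2, 4))
  Qmax <- matrix(9L, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(compute_wqs_index(Qmax, c(a = 0.5, b = 0.5)), rep(9, 3))
  expect_error(compute_wqs_index(Q, c(a = 1, zz = 0)), "mismatch")
})

test_that("a constant validation index triggers a rank-deficiency error", {
  Q <- matrix(1L, 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rpois(30, 3)
  expect_error(fit_final_model(Q, y, c(a = 0.5, b = 0.5)),
               "rank deficient")
})

test_that("wqs() is equivariant under component relabeling", {
  toy <- toy_wqs_data(n = 500, p = 4, q = 4,
                      weights = c(0.5, 0.3, 0.2, 0), theta1 = 0.5,
                      seed = 88)
  d <- cbind(toy$conc, y = toy$y)
  fit1 <- wqs(y ~ 1, d, mix = names(toy$conc), population = NULL,
              q = 4, n_bootstrap = 6, seed = 88)
  fit2 <- wqs(y ~ 1, d, mix = rev(names(toy$conc)), population = NULL,
              q = 4, n_bootstrap = 6, seed = 88)
  expect_equal(fit2$weights[names(fit1$weights)], fit1$weights,
               tolerance = 1e-2)
  expect_equal(fit2$rate_ratio$estimate, fit1$rate_ratio$estimate,
               tolerance = 1e-4)
})

test_that("every reported weight vector lies on the simplex", {
  toy <- toy_wqs_data(n = 150, p = 5, weights = c(0.5, 0.3, 0.2, 0, 0),
                      theta1 = 0.4, seed = 41)
  for (b in 1:25) {
    r <- fit_single_bootstrap(toy$scores, toy$y, seed = 5000 + b)
    expect_true(all(r$weights >= 0 & r$weights <= 1))
    expect_lt(abs(sum(r$weights) - 1), 1e-8)
  }
})

test_that("dropping components and degenerate drops behave as declared", {
  toy <- make_study_like_dataset(n_units = 40, n_years = 5, seed = 19)
  expect_error(wqs(nonaccidental ~ 1, toy$data, mix = toy$components,
                   population = "population", drop = toy$components,
                   n_bootstrap = 2, seed = 1),
               "every component")
  fit <- wqs(nonaccidental ~ 1, toy$data, mix = toy$components,
             population = "population", drop = "K", n_bootstrap = 4,
             seed = 19)
  expect_false("K" %in% names(fit$weights))
  expect_length(fit$weights, length(toy$components) - 1)
})
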