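test_that("copula panels honour the requested correlation structure", {
  marg <- default_marginals()[1:4, ]
  # identity correlation: pairwise rank correlations near 0
  p0 <- generate_exposure_panel(2500, 4, marg, correlation = diag(4) * 1 +
                                  0 * diag(4), seed = 2)
  R0 <- cor(as.matrix(p0[marg$component]), method = "spearman")
  expect_lt(max(abs(R0[upper.tri(R0)])), 0.05)
  # latent correlation 0.87: Spearman near its copula-implied value
  R <- diag(4); R[1, 2] <- R[2, 1] <- 0.87
  p1 <- generate_exposure_panel(2500, 4, marg, correlation = R, seed = 2)
  implied <- 6 / pi * asin(0.87 / 2)   # Gaussian-copula Spearman rho
  got <- cor(p1[[marg$component[1]]], p1[[marg$component[2]]],
             method = "spearman")
  expect_lt(abs(got - implied), 0.05)
})

test_that("log-normal marginals are moment-matched", {
  marg <- data.frame(component = "SO4", mean = 2.21, sd = 0.75,
                     unit = "ug/m3")
  p <- generate_exposure_panel(10000, 1, marg, correlation = diag(1),
                               seed = 4)
  expect_lt(abs(mean(p$SO4) - 2.21) / 2.21, 0.02)
  expect_lt(abs(sd(p$SO4) - 0.75) / 0.75, 0.05)
  expect_true(all(p$SO4 > 0))
})

test_that("invalid correlation matrices are rejected with the eigenvalue", {
  marg <- default_marginals()[1:3, ]
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(generate_exposure_panel(10, 2, marg, correlation = bad),
               "positive definite")
})

test_that("count generation inverts the rate model", {
  marg <- default_marginals()
  panel <- generate_exposure_panel(3125, 16, marg, seed = 6)  # 50k rows
  pop <- rep(1000, nrow(panel))
  w <- setNames(c(0.4, 0.3, 0.2, 0.1, rep(0, 11)), marg$component)
  # theta1 = 0: mean count / population ~ exp(theta0) within 1%
  tr0 <- synthetic_truth(w, theta1 = 0, theta0 = -4.6, psi = 1)
  y0 <- generate_counts(panel, tr0, NULL, pop, seed = 6)
  expect_lt(abs(mean(y0 / pop) - exp(-4.6)) / exp(-4.6), 0.01)
  # dispersion round trip at psi = 1 and psi = 2
  br <- quantile_breaks(panel, q = 10, components = marg$component)
  idx <- compute_wqs_index(score_quantiles(panel, br), w)
  X <- cbind(1, idx)
  tr1 <- synthetic_truth(w, theta1 = log(1.05), theta0 = -4.6, psi = 1)
  f1 <- fit_quasipoisson(generate_counts(panel, tr1, NULL, pop, seed = 7),
                         X, offset = log(pop))
  expect_gt(f1$dispersion, 0.9); expect_lt(f1$dispersion, 1.1)
  tr2 <- synthetic_truth(w, theta1 = log(1.05), theta0 = -4.6, psi = 2)
  f2 <- fit_quasipoisson(generate_counts(panel, tr2, NULL, pop, seed = 7),
                         X, offset = log(pop))
  expect_gt(f2$dispersion, 1.8); expect_lt(f2$dispersion, 2.2)
  expect_error(generate_counts(panel, tr1, NULL, rep(0, nrow(panel))),
               "positive")
})

test_that("study-like datasets are aligned, truthful and reproducible", {
  sim <- make_study_like_dataset(n_units = 30, n_years = 4, seed = 9)
  expect_equal(nrow(sim$data), 120)
  expect_true(all(c(sim$components, sim$covariate_names, "population",
                    sim$outcomes) %in% names(sim$data)))
  expect_equal(sum(sim$truth$weights), 1)
  expect_true(all(sim$data$population > 0))
  # same seed: byte-identical CSV output
  sim2 <- make_study_like_dataset(n_units = 30, n_years = 4, seed = 9)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(sim$data, f1, row.names = FALSE)
  write.csv(sim2$data, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  sim3 <- make_study_like_dataset(n_units = 30, n_years = 4, seed = 10)
  expect_false(identical(sim$data$nonaccidental, sim3$data$nonaccidental))
  # generator leaves the caller's RNG stream untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(make_study_like_dataset(n_units = 5, n_years = 2,
                                                   seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("the default correlation scenario mirrors the component blocks", {
  R <- default_latent_correlation()
  expect_true(isSymmetric(R))
  expect_true(min(eigen(R, only.values = TRUE)$values) > 0)
  off <- R[setdiff(rownames(R), "K"), setdiff(colnames(R), "K")]
  off <- off[upper.tri(off)]
  expect_gt(min(off), 0.35)
  expect_lt(max(off), 0.88)
  expect_lt(max(R["K", setdiff(colnames(R), "K")]), 0.1)
})
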