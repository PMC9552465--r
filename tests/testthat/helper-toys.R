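# Small seeded toy datasets and independent oracles used across tests.

# Independent-component toy mixture with Poisson counts driven by a known
# weighted quantile index.
toy_wqs_data <- function(n = 200, p = 4, q = 4,
                         weights = c(0.7, 0.3, rep(0, p - 2)),
                         theta1 = 0.5, theta0 = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("c", 1:p)))
  conc <- as.data.frame(X)
  br <- quantile_breaks(conc, q = q)
  Q <- score_quantiles(conc, br)
  w <- weights / sum(weights)
  y <- rpois(n, exp(theta0 + theta1 * drop(Q %*% w)))
  list(conc = conc, scores = Q, y = y, weights = w, q = q, breaks = br)
}

# Brute-force profile grid search for the two-component weight: at each w1
# on the grid the regression parameters are profiled out by an ordinary
# Poisson GLM and the log-likelihood recorded.
grid_w1_oracle <- function(q1, q2, y, offset = 0, grid = seq(0, 1, by = 0.01)) {
  off <- rep_len(offset, length(y))
  ll <- vapply(grid, function(w1) {
    idx <- w1 * q1 + (1 - w1) * q2
    f <- suppressWarnings(glm(y ~ idx, family = poisson(), offset = off))
    as.numeric(logLik(f))
  }, numeric(1))
  grid[which.max(ll)]
}

# Hand-coded linear-interpolation empirical quantile (independent of
# stats::quantile): the type-7 convention, h = (n-1) p + 1.
linear_interp_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
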