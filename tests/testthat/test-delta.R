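test_that("estimate_density integrates to one and recovers known densities", {
  set.seed(21)
  y <- rnorm(1e5)
  h <- corrdelta:::silverman_bw(y)
  grid <- seq(min(y) - 3 * h, max(y) + 3 * h, length.out = 512)
  f <- estimate_density(y, grid)
  expect_gte(corrdelta:::trapz_grid(grid, f$density), 0.98)
  expect_lte(corrdelta:::trapz_grid(grid, f$density), 1.02)
  at0 <- f$density[which.min(abs(grid))]
  expect_gt(at0, 0.37); expect_lt(at0, 0.43) # phi(0) = 0.3989
  expect_error(estimate_density(rep(1, 100), grid), "degenerate")
  expect_error(estimate_density(rnorm(5), grid), "at least 8")
})

test_that("separation_measure matches quadrature on shifted normals", {
  grid <- seq(-8, 9, length.out = 4096)
  f1 <- list(grid = grid, density = dnorm(grid))
  f2 <- list(grid = grid, density = dnorm(grid, 1))
  # independent oracle: adaptive quadrature of |phi(y) - phi(y-1)|
  expected <- integrate(function(y) abs(dnorm(y) - dnorm(y, 1)),
                        -Inf, Inf)$value
  expect_equal(separation_measure(f1, f2), expected, tolerance = 1e-4)
  expect_equal(separation_measure(f1, f1), 0)
  # disjoint unit-mass densities: L1 = 2
  g <- seq(-20, 20, length.out = 8192)
  d1 <- list(grid = g, density = dnorm(g, -10, 0.5))
  d2 <- list(grid = g, density = dnorm(g, 10, 0.5))
  expect_gt(separation_measure(d1, d2), 1.96)
  expect_lte(separation_measure(d1, d2), 2.0 + 1e-9)
  expect_error(separation_measure(f1, list(grid = g, density = dnorm(g))),
               "grid")
})

test_that("deterministic bijection drives delta toward 1", {
  set.seed(33)
  X <- matrix(rnorm(1e5), ncol = 1, dimnames = list(NULL, "X1"))
  d <- estimate_delta(X, X[, 1], partitions = 50)
  expect_gte(d[["X1"]], 0.8)
  expect_lte(d[["X1"]], 1)
})

test_that("delta estimates are invariant under monotone input transforms", {
  lb <- linear_benchmark(2e4, seed = 3, independent = TRUE)
  d0 <- estimate_delta(lb$X, lb$Y, partitions = 20)
  Xt <- lb$X
  Xt[, "X1"] <- exp(Xt[, "X1"])        # strictly increasing
  Xt[, "X2"] <- Xt[, "X2"]^3           # strictly increasing
  Xt[, "X3"] <- qnorm(pnorm(Xt[, "X3"])) # identity via probability scale
  dt <- estimate_delta(Xt, lb$Y, partitions = 20)
  expect_lt(max(abs(d0 - dt)), 1e-12)
})

test_that("delta estimates are stable under smooth monotone output transforms", {
  lb <- linear_benchmark(5e4, seed = 4, independent = TRUE)
  d0 <- estimate_delta(lb$X, lb$Y, partitions = 30)
  dt <- estimate_delta(lb$X, exp(lb$Y / 300), partitions = 30)
  expect_lt(max(abs(d0 - dt)), 0.02)
})

test_that("constant columns are excluded with a warning; non-finite rows dropped", {
  lb <- linear_benchmark(2e3, seed = 5, independent = TRUE)
  X <- cbind(lb$X, const = 1)
  expect_warning(d <- estimate_delta(X, lb$Y, partitions = 10), "const")
  expect_false("const" %in% names(d))
  Y <- lb$Y; Y[1:17] <- NA
  d2 <- estimate_delta(lb$X, Y, partitions = 10)
  expect_equal(attr(d2, "dropped"), 17)
  expect_error(estimate_delta(lb$X[1:400, ], lb$Y[1:400], partitions = 10),
               "too few")
})

test_that("bootstrap honours order statistics, determinism, and n-scaling", {
  lb <- linear_benchmark(8e3, seed = 6, independent = TRUE)
  Xn <- append_noise_column(lb$X, seed = 7)
  b1 <- bootstrap_deltas(Xn, lb$Y, partitions = 10, B = 80, seed = 8)
  expect_true(all(b1$estimates$ci_low <= b1$estimates$bootstrap_median))
  expect_true(all(b1$estimates$bootstrap_median <= b1$estimates$ci_high))
  expect_true(all(b1$estimates$point >= 0 & b1$estimates$point <= 1))
  b2 <- bootstrap_deltas(Xn, lb$Y, partitions = 10, B = 80, seed = 8)
  expect_identical(b1$estimates, b2$estimates)
  expect_identical(b1$replicates, b2$replicates)
  # halving n widens the bootstrap CI for the weak input X3
  lbs <- linear_benchmark(4e3, seed = 6, independent = TRUE)
  Xs <- append_noise_column(lbs$X, seed = 7)
  bs <- bootstrap_deltas(Xs, lbs$Y, partitions = 10, B = 80, seed = 8)
  w_small <- with(bs$estimates, ci_high - ci_low)[bs$estimates$name == "X3"]
  w_large <- with(b1$estimates, ci_high - ci_low)[b1$estimates$name == "X3"]
  expect_gt(w_small, w_large)
  expect_error(bootstrap_deltas(Xn, lb$Y, partitions = 10, B = 1), "B must")
})

test_that("noise threshold is the linear-interpolation 97.5th percentile", {
  expect_equal(noise_threshold(rep(0.42, 50)), 0.42)
  v <- 0.01 * (1:1000)
  expect_equal(noise_threshold(v), unname(quantile(v, 0.975, type = 7)))
  expect_error(noise_threshold(numeric(0)), "empty")
})

test_that("significance thresholding zeroes sub-threshold estimates", {
  est <- data.frame(name = c("a", "b"), point = c(0.05, 0.01),
                    bootstrap_median = c(0.05, 0.01),
                    ci_low = c(0.04, 0.005), ci_high = c(0.06, 0.02),
                    significant = NA, zeroed_value = NA_real_)
  out <- apply_significance(est, 0.02)
  expect_identical(out$significant, c(TRUE, FALSE))
  expect_identical(out$zeroed_value, c(0.05, 0))
})

test_that("the Noise control itself is declared non-significant", {
  lb <- linear_benchmark(2e4, seed = 9, independent = TRUE)
  Xn <- append_noise_column(lb$X, seed = 10)
  b <- bootstrap_deltas(Xn, lb$Y, partitions = 20, B = 100, seed = 11)
  thr <- noise_threshold(b$replicates[, "Noise"])
  expect_gt(thr, 0) # KDE estimator has positive bias on pure noise
  out <- apply_significance(b, thr)
  noise_row <- out$estimates[out$estimates$name == "Noise", ]
  expect_false(noise_row$significant)
})
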