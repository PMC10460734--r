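test_that("lognormal parametrization: typical value is the median, sigma^2 = log(1+cv^2)", {
  specs <- parameter_spec(c("k2", "point"), c(0.129, 1), c(0.40, 0))
  joint <- build_joint(specs)
  expect_equal(unname(joint$log_location["k2"]), log(0.129))
  expect_equal(unname(joint$log_scale["k2"]), sqrt(log(1.16)))
  # cv = 0 collapses to a point mass at the typical value
  expect_equal(unname(joint$log_location["point"]), 0)
  expect_equal(unname(joint$log_scale["point"]), 0)
  expect_equal(unname(joint$correlation), diag(2))
})

test_that("parameter_spec and build_joint reject invalid input", {
  expect_error(parameter_spec(c("a", "a"), c(1, 2), c(0.1, 0.1)), "unique")
  expect_error(parameter_spec("a", -1, 0.1), "positive")
  expect_error(parameter_spec("a", 1, -0.1), "non-negative")
  specs <- parameter_spec(c("a", "b"), c(1, 1), c(0.1, 0.1))
  expect_error(build_joint(specs, diag(3)), "dimension")
  bad <- matrix(c(1, 2, 2, 1), 2, 2) # |corr| > 1, not PD
  expect_error(build_joint(specs, bad), "positive definite")
})

test_that("draw_samples is seed-deterministic and reproduces the marginals", {
  specs <- parameter_spec("x", 1, 0.5)
  joint <- build_joint(specs)
  X1 <- draw_samples(joint, 1e5, seed = 42)
  X2 <- draw_samples(joint, 1e5, seed = 42)
  expect_identical(X1, X2)
  # lognormal median equals the typical value
  expect_gt(median(X1[, "x"]), 0.99)
  expect_lt(median(X1[, "x"]), 1.01)
  # natural-scale CV round-trip, relative error < 2% at n = 1e5
  cv_hat <- sd(X1[, "x"]) / mean(X1[, "x"])
  expect_lt(abs(cv_hat - 0.5) / 0.5, 0.02)
  expect_error(draw_samples(joint, 1, seed = 1), "at least 2")
})

test_that("cv = 0 parameters are carried as exact constants", {
  joint <- build_joint(parameter_spec(c("a", "b"), c(2.5, 1), c(0, 0.3)))
  X <- draw_samples(joint, 100, seed = 1)
  expect_true(all(X[, "a"] == 2.5))
})

test_that("sampled correlations match the target on the Gaussian scale", {
  R <- matrix(c(1, 0.8, 0, 0.8, 1, -0.4, 0, -0.4, 1), 3, 3)
  specs <- parameter_spec(c("a", "b", "c"), c(1, 2, 3), c(0.3, 0.5, 0.2))
  joint <- build_joint(specs, R)
  X <- draw_samples(joint, 1e5, seed = 11)
  emp <- cor(log(X))
  expect_lt(max(abs(emp - R)), 0.01)
  # independent draws: off-diagonal empirical correlation ~ 0
  Xi <- draw_samples(joint, 1e5, seed = 11, independent = TRUE)
  empi <- cor(log(Xi))
  expect_lt(max(abs(empi - diag(3))), 0.01)
  # identical marginals in the two modes (two-sample KS < 0.01 per column)
  for (j in 1:3) {
    ks <- suppressWarnings(ks.test(X[, j], Xi[, j]))
    expect_lt(unname(ks$statistic), 0.01)
  }
})

test_that("append_noise_column adds an independent standard-normal control", {
  joint <- build_joint(parameter_spec(c("a", "b"), c(1, 2), c(0.3, 0.4)))
  X <- draw_samples(joint, 1e5, seed = 5)
  Xn <- append_noise_column(X, seed = 6)
  expect_identical(colnames(Xn), c("a", "b", "Noise"))
  z <- Xn[, "Noise"]
  expect_lt(abs(mean(z)), 0.02)
  expect_gt(sd(z), 0.99); expect_lt(sd(z), 1.01)
  expect_lt(max(abs(cor(z, log(X)))), 0.01)
  expect_identical(append_noise_column(X, seed = 6), Xn) # seed-reproducible
  expect_error(append_noise_column(Xn, seed = 6), "Noise")
})

test_that("complete_correlation is the identity on fully known PD matrices", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  out <- complete_correlation(correlation_template(R))
  expect_equal(unclass(out), unclass(correlation_template(R)),
               ignore_attr = TRUE)
  expect_equal(attr(out, "max_perturbation"), 0)
})

test_that("complete_correlation fills all-unknown templates with the identity", {
  tpl <- matrix(NA_real_, 4, 4); diag(tpl) <- 1
  out <- complete_correlation(correlation_template(tpl))
  expect_equal(unname(out[, ]), diag(4), ignore_attr = TRUE)
})

test_that("completed entries respect positive definiteness constraints", {
  # known r12 = r13 = 0.95 forces r23 >= 2*0.95^2 - 1 = 0.805
  tpl <- matrix(c(1, 0.95, 0.95, 0.95, 1, NA, 0.95, NA, 1), 3, 3)
  out <- complete_correlation(correlation_template(tpl))
  ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_gte(out[2, 3], 2 * 0.95^2 - 1)
  expect_lte(out[2, 3], 1)
  expect_equal(out[1, 2], 0.95) # known entries preserved
  expect_equal(out[1, 3], 0.95)
  expect_equal(out, t(out))
})

test_that("completion always returns symmetric PD matrices (random templates)", {
  set.seed(404)
  for (rep in 1:20) {
    p <- sample(3:7, 1)
    # random PD source, then hide a random subset of entries
    A <- matrix(rnorm(p * p), p)
    S <- cov2cor(crossprod(A) + diag(p) * 0.1)
    hide <- matrix(runif(p * p) < 0.4, p, p)
    hide <- hide | t(hide); diag(hide) <- FALSE
    S[hide] <- NA
    out <- complete_correlation(correlation_template(S))
    expect_equal(out, t(out))
    expect_gt(min(eigen(out, only.values = TRUE)$values), 0)
    expect_equal(unname(diag(out)), rep(1, p))
  }
})

test_that("correlation template validation catches asymmetry and range", {
  expect_error(correlation_template(matrix(c(1, 0.5, NA, 1), 2, 2)),
               "pattern")
  expect_error(correlation_template(matrix(c(1, 1.5, 1.5, 1), 2, 2)),
               "\\[-1, 1\\]")
  expect_error(correlation_template(matrix(c(2, 0, 0, 1), 2, 2)),
               "diagonal")
})

test_that("parameter and sample CSVs round-trip", {
  specs <- table2_scenario("CV1")
  expect_s3_class(specs, "parameter_spec")
  joint <- build_joint(specs[specs$name %in% c("mu_u", "g_u"), ])
  X <- draw_samples(joint, 50, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_sample_csv(X, f)
  X2 <- read_sample_csv(f)
  expect_equal(unname(X2), unname(X[, ]), tolerance = 1e-15)
  expect_identical(colnames(X2), colnames(X))
})
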