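test_that("noiseless degenerate specs give constant realizations", {
  sp <- class_spec("flat", I = 5, mean_offset = c(1, 2, 3, 4, 5),
                   alpha = 0, beta = 0, sigma = 0, init_sd = 0)
  s <- simulate_class(sp, 4, seed = 1)
  expect_equal(s$X, matrix(rep(c(1, 2, 3, 4, 5), each = 4), 4, 5))
})

test_that("the linear recursion reproduces AR(1) autocorrelation", {
  sp <- class_spec("ar", I = 14, alpha = 0.5, beta = 0,
                   sigma = sqrt(1 - 0.25), init_sd = 1)
  s <- simulate_class(sp, 2000, seed = 2)
  lag1 <- mean(vapply(2:14, function(i) cor(s$X[, i - 1], s$X[, i]), numeric(1)))
  expect_equal(lag1, 0.5, tolerance = 0.05)
  # calibrated to unit stationary variance
  expect_equal(mean(apply(s$X, 2, var)), 1, tolerance = 0.1)
})

test_that("simulation is seed-deterministic and leaves the RNG alone", {
  sp <- class_spec("a", I = 6, alpha = 0.3, sigma = 1)
  s1 <- simulate_class(sp, 30, seed = 7)
  s2 <- simulate_class(sp, 30, seed = 7)
  expect_identical(s1$X, s2$X)
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_class(sp, 10, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("innovation families are unit variance and plug in", {
  for (innov in c("gaussian", "uniform", "laplace")) {
    sp <- class_spec("x", I = 2, alpha = 0, sigma = 1, init_sd = 1,
                     innovation = innov)
    s <- simulate_class(sp, 4000, seed = 11)
    expect_equal(var(s$X[, 2]), 1, tolerance = 0.1)
  }
})

test_that("gaussian_shift marginals stay near-Gaussian and separable", {
  b <- make_benchmark("gaussian_shift", K = 2, I = 14, L_train = 5000,
                      L_test = 10, seed = 13)
  X <- b$train[[1]]$X
  kurt <- vapply(seq_len(ncol(X)), function(i) {
    z <- (X[, i] - mean(X[, i])) / sd(X[, i])
    mean(z^4) - 3
  }, numeric(1))
  expect_lte(max(abs(kurt)), 0.3)
  # adjacent class means differ by delta at every index
  expect_equal(colMeans(b$train[[2]]$X) - colMeans(X),
               rep(b$config$delta, 14), tolerance = 0.15)
})

test_that("quadratic_coupling matches first and second moments, not third", {
  # the mirror construction matches the two classes exactly in population;
  # the sample size is chosen so estimation noise (a per-index variance
  # estimate carries ~sqrt((kurtosis + 2) / L) relative error, and kurtosis
  # reaches ~9 here) sits well below the asserted bands
  b <- make_benchmark("quadratic_coupling", K = 2, I = 14, L_train = 50000,
                      L_test = 10, seed = 17)
  m1 <- colMeans(b$train[[1]]$X)
  m2 <- colMeans(b$train[[2]]$X)
  expect_lte(max(abs(m1 - m2)), 0.03)
  expect_lte(mean(abs(m1 - m2)), 0.02)
  v1 <- apply(b$train[[1]]$X, 2, var)
  v2 <- apply(b$train[[2]]$X, 2, var)
  expect_true(all(v1 / v2 >= 0.95 & v1 / v2 <= 1.05))
  expect_gte(mean(v1 / v2), 0.98)
  expect_lte(mean(v1 / v2), 1.02)
  # third cross-moments E[z(i-1)^2 z(i)] have opposite signs by construction
  third <- b$moment_match$third_cross_moment
  expect_true(all(third[, 1] * sign(b$specs[[1]]$beta[2]) > 0))
  expect_true(all(third[, 2] * sign(b$specs[[2]]$beta[2]) > 0))
  expect_true(all(third[, 1] * third[, 2] < 0))
  # diagnostics are measured and reported
  expect_lte(b$moment_match$variance_ratio_range[2], 1.1)
})

test_that("benchmarks are reproducible and validate their configuration", {
  b1 <- make_benchmark("quadratic_coupling", L_train = 30, L_test = 20, seed = 3)
  b2 <- make_benchmark("quadratic_coupling", L_train = 30, L_test = 20, seed = 3)
  expect_identical(b1$train[[1]]$X, b2$train[[1]]$X)
  expect_identical(b1$test[[2]]$X, b2$test[[2]]$X)
  # train and test splits are disjoint draws
  expect_false(identical(b1$train[[1]]$X[1, ], b1$test[[1]]$X[1, ]))

  expect_error(make_benchmark("quadratic_coupling", K = 1),
               class = "canondx_invalid_input")
  expect_error(make_benchmark("quadratic_coupling", ar = 0.9, beta_max = 0.4),
               class = "canondx_invalid_input")
  expect_error(class_spec("x", I = 3, sigma = -1),
               class = "canondx_invalid_input")
  expect_error(class_spec("x", I = 3, alpha = c(1, 2)),
               class = "canondx_invalid_input")
})
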