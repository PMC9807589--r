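test_that("the linear two-index model has its closed form", {
  rho <- 0.6
  X <- canondx:::with_seed(21, {
    x1 <- rnorm(4000)
    cbind(x1, rho * x1 + sqrt(1 - rho^2) * rnorm(4000))
  })
  std <- standardize_features(X)$sets
  tab <- moment_table(std)
  dict <- build_dictionary(2, kind = "linear")
  r <- mean(std[, 1] * std[, 2])  # empirical cross-moment after standardization
  for (builder in list(build_canonical_model, gram_schmidt_oracle)) {
    m <- builder(tab, dict)
    expect_equal(m$W[2, 1], r, tolerance = 1e-12)
    expect_equal(m$D[1], 1, tolerance = 1e-12)
    expect_equal(m$D[2], 1 - r^2, tolerance = 1e-12)
    expect_equal(diag(m$W), rep(1, 2))
  }
})

test_that("moment recursion and Gram-Schmidt oracle agree on random instances", {
  for (seed in 1:6) {
    I <- sample(2:5, 1)
    N <- sample(2:4, 1)
    inst <- build_instance(L = 120, I = I, N = N, seed = 100 + seed)
    m1 <- build_canonical_model(inst$tab, inst$dict)
    m2 <- gram_schmidt_oracle(inst$tab, inst$dict)
    expect_identical(m1$degenerate, m2$degenerate)
    expect_lt(max(abs(m1$W - m2$W)), 1e-8)
    expect_lt(max(abs(m1$D - m2$D)), 1e-8)
    expect_identical(m1$decision_idx, m2$decision_idx)
  }
})

test_that("training-set coefficients are empirically uncorrelated (whitening)", {
  inst <- build_instance(L = 150, I = 5, N = 4, seed = 9)
  m <- build_canonical_model(inst$tab, inst$dict)
  P <- extract_coefficients(m, inst$X)
  G <- crossprod(P) / nrow(P)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)), 1e-8)
  # coefficient sample variances equal the model variances D
  expect_equal(unname(diag(G)), m$D, tolerance = 1e-10)
})

test_that("extraction follows the hand recursion and inverts exactly", {
  inst <- build_instance(L = 100, I = 2, N = 2, seed = 4, kind = "linear")
  m <- build_canonical_model(inst$tab, inst$dict)
  c12 <- c(0.7, -1.2)
  p <- extract_coefficients(m, c12)
  expect_equal(unname(p[1]), c12[1] - m$mean[1])
  expect_equal(unname(p[2]), (c12[2] - m$mean[2]) - m$W[2, 1] * (c12[1] - m$mean[1]))

  # realization equal to the mean function -> zero coefficients
  p0 <- extract_coefficients(m, m$mean)
  expect_equal(as.numeric(p0), c(0, 0))

  # reconstruct(extract(c)) is the identity; zero coefficients give the mean
  expect_equal(reconstruct_first_component(m, p), c12, tolerance = 1e-10)
  expect_equal(reconstruct_first_component(m, c(0, 0)), m$mean)

  # linear hand expansion: (p1, p2) -> (m1 + p1, m2 + w*p1 + p2)
  expect_equal(reconstruct_first_component(m, c(1, 2)),
               c(m$mean[1] + 1, m$mean[2] + m$W[2, 1] * 1 + 2))
})

test_that("nonlinear extraction round-trips on random realizations", {
  inst <- build_instance(L = 150, I = 5, N = 4, seed = 12)
  m <- build_canonical_model(inst$tab, inst$dict)
  Y <- random_realizations(20, 5, seed = 33)
  P <- extract_coefficients(m, Y)
  expect_lt(max(abs(reconstruct_first_component(m, P) - Y)), 1e-10)
})

test_that("deterministic training data degenerates every coefficient", {
  Xc <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  tab <- moment_table(Xc)
  dict <- build_dictionary(3, N = 3, B = 2)
  m <- build_canonical_model(tab, dict)
  expect_true(all(m$degenerate))
  expect_true(all(is.na(m$decision_idx)))
  expect_error(select_decision_coefficients(m), class = "canondx_config_error")
  expect_match(tryCatch(select_decision_coefficients(m),
                        error = conditionMessage), "block")
})

test_that("degenerate directions are excluded but the rest still whitens", {
  # column 3 is an exact linear function of column 2: its linear coefficient
  # is degenerate while others survive
  X <- random_realizations(120, 3, seed = 8)
  X[, 3] <- 2 * X[, 2] - 1
  std <- standardize_features(X)$sets
  tab <- moment_table(std)
  m <- build_canonical_model(tab, build_dictionary(3, N = 3, B = 2, max_lag = 2))
  expect_true(any(m$degenerate))
  P <- extract_coefficients(m, std)
  expect_true(all(P[, m$degenerate] == 0))
  G <- crossprod(P) / nrow(P)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # oracle flags the same directions
  mo <- gram_schmidt_oracle(tab, build_dictionary(3, N = 3, B = 2, max_lag = 2))
  expect_identical(m$degenerate, mo$degenerate)
})

test_that("decision coefficients are the named last entries per block", {
  inst <- build_instance(L = 200, I = 4, N = 4, seed = 2)
  m <- build_canonical_model(inst$tab, inst$dict)
  dec <- select_decision_coefficients(m)
  expect_equal(dec[[1]]$powers, 3L)                      # highest power at i=1
  expect_equal(dec[[2]]$lags, 1L)
  expect_equal(dec[[2]]$powers, c(1L, 2L))               # lag 1, powers (1,2)
  expect_equal(dec[[3]]$lags, c(1L, 2L))
  expect_equal(dec[[3]]$powers, c(1L, 1L, 1L))           # lags (1,2), powers (1,1,1)
  expect_equal(dec[[4]]$lags, c(1L, 2L))

  lin <- build_canonical_model(inst$tab, build_dictionary(4, kind = "linear"))
  dec_lin <- select_decision_coefficients(lin)
  expect_true(all(vapply(dec_lin, function(mm) identical(mm$powers, 1L), logical(1))))
})

test_that("projection never increases the linear term's variance", {
  inst <- build_instance(L = 150, I = 5, N = 4, seed = 14)
  m <- build_canonical_model(inst$tab, inst$dict)
  raw_var <- vapply(seq_len(5), function(i) {
    mean(inst$X[, i]^2) - mean(inst$X[, i])^2
  }, numeric(1))
  expect_true(all(m$D[m$block_first] <= raw_var + 1e-12))
})

test_that("model building rejects unusable inputs", {
  tab <- moment_table(random_realizations(20, 3, seed = 1))
  expect_error(build_canonical_model(tab, structure(
    list(I = 3, N = 2, B = 1, max_lag = 2, kind = "linear",
         monomials = list(), block = integer(0), labels = character(0)),
    class = "cdx_dictionary")), class = "canondx_invalid_input")
  dict5 <- build_dictionary(5, kind = "linear")
  expect_error(build_canonical_model(tab, dict5),
               class = "canondx_invalid_input")
  m <- build_canonical_model(tab, build_dictionary(3, kind = "linear"))
  expect_error(extract_coefficients(m, c(1, 2)), class = "canondx_invalid_input")
  expect_error(extract_coefficients(m, c(1, NA, 3)),
               class = "canondx_invalid_input")
  expect_error(reconstruct_first_component(m, c(1, 2)),
               class = "canondx_invalid_input")
})
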