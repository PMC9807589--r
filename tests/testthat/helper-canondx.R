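# Shared fixtures, built in code.

# Correlated Gaussian realizations with mild nonlinearity in the mean,
# general-position data for model-building tests.
random_realizations <- function(L, I, seed) {
  canondx:::with_seed(seed, {
    X <- matrix(rnorm(L * I), L, I)
    for (i in seq_len(I)[-1]) {
      X[, i] <- 0.4 * X[, i - 1] + 0.15 * (X[, i - 1]^2 - 1) + X[, i]
    }
    X
  })
}

# Standardized moment table + dictionary + both model paths for one instance.
build_instance <- function(L, I, N, seed, max_lag = 2L, kind = "nonlinear") {
  X <- random_realizations(L, I, seed)
  std <- standardize_features(X)$sets
  dict <- build_dictionary(I, N = N, B = N - 1L, max_lag = max_lag, kind = kind)
  tab <- moment_table(std)
  list(X = std, dict = dict, tab = tab)
}

# Brute-force count of admissible monomials at one time index (independent
# enumeration oracle: filters the full cross product of candidates).
brute_count_monomials <- function(nu, N, B, max_lag = Inf) {
  count <- 0L
  g_max <- min(nu, N - 1L, B)
  for (g in seq_len(g_max)) {
    lag_cands <- if (g == 1L) list(integer(0)) else {
      combos <- utils::combn(seq_len(nu - 1L), g - 1L, simplify = FALSE)
      Filter(function(r) all(r <= pmin(nu - g + seq_len(g - 1L), max_lag)), combos)
    }
    pow_cands <- as.matrix(expand.grid(rep(list(seq_len(B)), g)))
    n_pow <- sum(rowSums(pow_cands) <= B)
    count <- count + length(lag_cands) * n_pow
  }
  count
}

two_class_sets <- function(L = 60, I = 4, sep = 6, seed = 1) {
  canondx:::with_seed(seed, {
    list(class_data("a", matrix(rnorm(L * I), L, I)),
         class_data("b", matrix(rnorm(L * I, mean = sep), L, I)))
  })
}
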