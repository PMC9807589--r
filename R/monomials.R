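# Monomial dictionary of the generalized decomposition.
#
# A monomial names one product C^{xi_g}(nu - r_{g-1}) ... C^{xi_1}(nu) of
# sequence values at and before time index nu. The ordered set of all
# admissible monomials (the dictionary) is what the sequential
# orthogonalization consumes; its last entry per time block is the decision
# coefficient of the classifier.

#' Construct a monomial index
#'
#' A monomial is identified by its time index `nu`, a strictly increasing
#' tuple of positive lags (possibly empty) and a parallel tuple of positive
#' integer powers. `powers[1]` applies at `nu`, `powers[j + 1]` at
#' `nu - lags[j]`.
#'
#' @param nu 1-based time index.
#' @param lags Strictly increasing positive integer lags; `integer(0)` for a
#'   single-factor monomial.
#' @param powers Positive integer powers, length `length(lags) + 1`.
#' @return An object of class `cdx_monomial` with fields `nu`, `lags`,
#'   `powers`, plus derived `times` (the feature indices touched) and
#'   `degree` (total power).
#' @export
monomial <- function(nu, lags = integer(0), powers) {
  nu <- as.integer(nu)
  lags <- as.integer(lags)
  powers <- as.integer(powers)
  if (nu < 1L) stop_invalid("monomial time index must be >= 1")
  if (length(powers) != length(lags) + 1L) {
    stop_invalid("monomial needs length(powers) == length(lags) + 1")
  }
  if (any(powers < 1L)) stop_invalid("monomial powers must be >= 1")
  if (length(lags) > 0 &&
      (any(lags < 1L) || any(diff(lags) <= 0L) || max(lags) > nu - 1L)) {
    stop_invalid("monomial lags must be strictly increasing and < nu")
  }
  structure(
    list(nu = nu, lags = lags, powers = powers,
         times = c(nu, nu - lags), degree = sum(powers)),
    class = "cdx_monomial")
}

#' @export
format.cdx_monomial <- function(x, ...) {
  sprintf("P[%s;%s](%d)",
          paste(x$lags, collapse = ","),
          paste(x$powers, collapse = ","),
          x$nu)
}

#' @export
print.cdx_monomial <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# All integer vectors of length g, entries >= 1, total <= total_max,
# in lexicographic order.
power_tuples <- function(g, total_max) {
  if (total_max < g) return(list())
  if (g == 1L) return(as.list(seq_len(total_max)))
  out <- list()
  for (first in seq_len(total_max - g + 1L)) {
    for (rest in power_tuples(g - 1L, total_max - first)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

# Strictly increasing (g-1)-tuples of lags with r_j <= min(nu - g + j, cap),
# lexicographic order.
lag_tuples <- function(nu, g, cap) {
  if (g == 1L) return(list(integer(0)))
  bounds <- pmin(nu - g + seq_len(g - 1L), cap)
  if (any(bounds < seq_len(g - 1L))) return(list())
  grow <- function(prefix, j) {
    if (j > g - 1L) return(list(prefix))
    lo <- if (j == 1L) 1L else prefix[j - 1L] + 1L
    hi <- bounds[j]
    if (lo > hi) return(list())
    out <- list()
    for (r in lo:hi) out <- c(out, grow(c(prefix, r), j + 1L))
    out
  }
  grow(integer(0), 1L)
}

#' Enumerate the monomials of one time block
#'
#' Lists, in canonical order, every admissible monomial at time index `nu`
#' for decomposition order `N` and total-degree bound `B`: the number of
#' factors satisfies `g <= min(nu, N - 1)`, lags satisfy
#' `r_j <= nu - g + j` (and optionally `r_j <= max_lag`), and the total
#' degree satisfies `sum(powers) <= B`.
#'
#' Within a block monomials are sorted by factor count ascending, then total
#' degree ascending, then leading power descending, then lexicographically on
#' lags and powers. This puts the single linear term first and the maximally
#' conditioned cross product last, so the block's final entry is the decision
#' coefficient of the classifier (for `N = 4`: power 3 at `nu = 1`; lag 1
#' with powers (1, 2) at `nu = 2`; lags (1, 2) with powers (1, 1, 1) from
#' `nu = 3` on).
#'
#' @param nu Time index (block) to enumerate.
#' @param N Decomposition order (`N >= 2`).
#' @param B Total-degree bound; defaults to `N - 1`.
#' @param max_lag Maximum admissible lag; `Inf` reproduces the unrestricted
#'   bound `r_j <= nu - g + j`. See [build_dictionary()] for why a finite
#'   window is the default at the dictionary level.
#' @param max_factors Maximum factor count; defaults to `N - 1`. Set to 1 for
#'   single-time (polynomial) dictionaries.
#' @return List of [monomial()] objects in canonical block order.
#' @export
enumerate_monomials <- function(nu, N, B = N - 1L, max_lag = Inf,
                                max_factors = N - 1L) {
  nu <- as.integer(nu)
  if (nu < 1L) stop_invalid("nu must be >= 1")
  if (N < 2L) stop_invalid("decomposition order N must be >= 2")
  if (B < 1L) stop_invalid("degree bound B must be >= 1")
  g_max <- min(nu, N - 1L, max_factors, B)
  out <- list()
  for (g in seq_len(g_max)) {
    cap <- if (is.finite(max_lag)) as.integer(max_lag) else nu - 1L
    lag_sets <- lag_tuples(nu, g, cap)
    if (length(lag_sets) == 0) next
    tuples <- power_tuples(g, as.integer(B))
    if (length(tuples) == 0) next
    block <- list()
    for (p in tuples) {
      for (lg in lag_sets) {
        block[[length(block) + 1L]] <- monomial(nu, lg, p)
      }
    }
    # (degree asc, leading power desc, lags lex, powers lex); g fixed here
    key <- vapply(block, function(m) {
      sprintf("%02d_%02d_%s_%s", m$degree, B + 1L - m$powers[1],
              paste(sprintf("%02d", m$lags), collapse = ""),
              paste(sprintf("%02d", m$powers), collapse = ""))
    }, character(1))
    out <- c(out, block[order(key)])
  }
  out
}

#' Build the ordered monomial dictionary
#'
#' Concatenates [enumerate_monomials()] over `nu = 1..I`. The dictionary kind
#' selects the criterion family: `"nonlinear"` uses the full cross-time
#' dictionary (decision rule on maximally conditioned cross products),
#' `"polynomial"` restricts to single-time powers `1..B`, and `"linear"`
#' keeps only the first power at each index.
#'
#' The nonlinear dictionary is windowed to `max_lag` (default 2): cross
#' products reach at most `max_lag` indices back. The window is the package's
#' complexity control — the unrestricted dictionary at `I = 14`, `N = 4` has
#' 679 entries, more than the span of typical training sets (a sample of
#' `L` realizations supports at most `L - 1` empirically non-degenerate
#' coefficients), whereas the default window gives 129. `max_lag = Inf`
#' restores the unrestricted bound `r_j <= nu - g + j` for large-`L` use.
#'
#' @param I Sequence length (number of feature indices).
#' @param N Decomposition order.
#' @param B Total-degree bound; defaults to `N - 1` (`B = 1` yields the
#'   linear dictionary whatever the kind).
#' @param max_lag Lag window for cross products (nonlinear kind only).
#' @param kind `"nonlinear"`, `"polynomial"` or `"linear"`.
#' @return An object of class `cdx_dictionary`: fields `I`, `N`, `B`,
#'   `max_lag`, `kind`, `monomials` (ordered list), `block` (time index per
#'   entry), `labels`.
#' @export
build_dictionary <- function(I, N = 4L, B = N - 1L, max_lag = 2L,
                             kind = c("nonlinear", "polynomial", "linear")) {
  kind <- match.arg(kind)
  I <- as.integer(I)
  if (I < 1L) stop_invalid("I must be >= 1")
  if (kind == "linear") B <- 1L
  max_factors <- if (kind == "nonlinear") N - 1L else 1L
  monos <- list()
  block <- integer(0)
  for (nu in seq_len(I)) {
    ms <- enumerate_monomials(nu, N = N, B = B,
                              max_lag = if (kind == "nonlinear") max_lag else 0L,
                              max_factors = max_factors)
    monos <- c(monos, ms)
    block <- c(block, rep(nu, length(ms)))
  }
  structure(
    list(I = I, N = as.integer(N), B = as.integer(B),
         max_lag = max_lag, kind = kind,
         monomials = monos, block = block,
         labels = vapply(monos, format, character(1))),
    class = "cdx_dictionary")
}

#' @export
print.cdx_dictionary <- function(x, ...) {
  cat(sprintf("Monomial dictionary (%s): I=%d N=%d B=%d max_lag=%s, %d entries\n",
              x$kind, x$I, x$N, x$B, format(x$max_lag), length(x$monomials)))
  invisible(x)
}

#' @export
length.cdx_dictionary <- function(x) length(x$monomials)

# First/last dictionary positions of each time block.
dict_block_range <- function(dict) {
  idx <- seq_along(dict$block)
  list(first = vapply(seq_len(dict$I), function(i) min(idx[dict$block == i]),
                      integer(1)),
       last = vapply(seq_len(dict$I), function(i) max(idx[dict$block == i]),
                     integer(1)))
}
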