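# Canonical model: sequential orthogonalization of the monomial dictionary.
#
# Processing monomials in dictionary order, each centered monomial value is
# decomposed as its projection onto all earlier non-degenerate coefficients
# plus a new coefficient P. The deterministic weights (coordinate functions
# omega) equal the cross-moment of an earlier coefficient with the centered
# target divided by that coefficient's variance D; D of the new coefficient
# is its residual second moment. All quantities are functions of the sample
# mixed moments only, so the trained model is a finite parameter set.

#' Build a canonical model from a moment table
#'
#' Runs the coordinate-function / variance recursion over the ordered
#' dictionary. For monomial m, the cross-moments `S[a, m] = E[P_a * X_m]`
#' (X = centered monomial value) are obtained by forward substitution through
#' the already-computed coordinate functions; then
#' `omega[a, m] = S[a, m] / D[a]` and
#' `D[m] = E[X_m^2] - sum_a omega[a, m] * S[a, m]`.
#'
#' Monomials whose variance falls at or below `var_tol` times their centered
#' second moment are marked degenerate: their coefficient is fixed at 0 and
#' they are excluded from all later conditioning (the recursion divides by
#' D). Negative variances within tolerance are clipped to 0.
#'
#' @param table A [moment_table()] over the same feature length as `dict`.
#' @param dict A [build_dictionary()] result.
#' @param var_tol Relative degeneracy tolerance (default `1e-10`).
#' @return An object of class `cdx_model`: `dict`, `mu` (mean of each
#'   monomial), `mean` (mean function, per feature index), `W` (lower
#'   uni-triangular matrix, `W[m, a] = omega[a][m]`), `D` (coefficient
#'   variances), `degenerate` (flags), `decision_idx` (position of the last
#'   non-degenerate monomial of each block; `NA` if the block has none),
#'   `block_first`, `var_tol`.
#' @export
build_canonical_model <- function(table, dict, var_tol = 1e-10) {
  J <- length(dict$monomials)
  if (J == 0L) stop_invalid("empty dictionary")
  if (dict$I > table$I) {
    stop_invalid("dictionary needs %d feature indices, table has %d",
                 dict$I, table$I)
  }
  V <- monomial_value_matrix(table$X, dict)
  mu <- colMeans(V)
  # Sample central cross-moment matrix E[X_a X_m]; identical to evaluating
  # central_mixed_moment() on every monomial pair, computed in bulk.
  G <- crossprod(V) / table$L - tcrossprod(mu)
  finish_model(G, mu, dict, var_tol, recursion = "moment")
}

# Shared assembly of the recursion output. `recursion = "moment"` runs the
# forward-substitution recursion on G; callers supplying their own W/D use
# assemble_model() directly.
finish_model <- function(G, mu, dict, var_tol, recursion) {
  J <- length(dict$monomials)
  W <- diag(1, J)
  D <- numeric(J)
  degenerate <- logical(J)
  scale2 <- pmax(diag(G), 0)
  for (m in seq_len(J)) {
    if (m == 1L) {
      s <- numeric(0)
      Dm <- G[1, 1]
    } else {
      k <- m - 1L
      s <- forwardsolve(W[seq_len(k), seq_len(k), drop = FALSE],
                        G[seq_len(k), m])
      keep <- !degenerate[seq_len(k)]
      wcol <- numeric(k)
      wcol[keep] <- s[keep] / D[seq_len(k)][keep]
      W[m, seq_len(k)] <- wcol
      Dm <- G[m, m] - sum(wcol[keep] * s[keep])
    }
    if (!is.finite(Dm) || Dm <= var_tol * max(scale2[m], .Machine$double.xmin)) {
      degenerate[m] <- TRUE
      D[m] <- max(Dm, 0)
      if (D[m] <= var_tol * max(scale2[m], .Machine$double.xmin)) D[m] <- 0
      W[m, seq_len(m - 1L)] <- 0
    } else {
      D[m] <- Dm
    }
  }
  assemble_model(dict, mu, W, D, degenerate, var_tol)
}

assemble_model <- function(dict, mu, W, D, degenerate, var_tol) {
  rng <- dict_block_range(dict)
  decision_idx <- vapply(seq_len(dict$I), function(i) {
    idx <- rng$first[i]:rng$last[i]
    ok <- idx[!degenerate[idx]]
    if (length(ok) == 0) NA_integer_ else max(ok)
  }, integer(1))
  n_deg <- sum(degenerate)
  cdx_log("info", "canonical model: %d monomials, %d degenerate, %d usable blocks",
          length(D), n_deg, sum(!is.na(decision_idx)))
  structure(
    list(dict = dict, mu = mu, mean = mu[rng$first],
         W = W, D = D, degenerate = degenerate,
         decision_idx = decision_idx, block_first = rng$first,
         var_tol = var_tol),
    class = "cdx_model")
}

#' @export
print.cdx_model <- function(x, ...) {
  cat(sprintf("Canonical model (%s): I=%d, %d coefficients (%d degenerate), %d usable blocks\n",
              x$dict$kind, x$dict$I, length(x$D), sum(x$degenerate),
              sum(!is.na(x$decision_idx))))
  invisible(x)
}

#' Data-level Gram-Schmidt oracle
#'
#' Independent verification path for [build_canonical_model()]: materializes
#' the centered monomial value columns over the training sample and
#' orthogonalizes them sequentially (modified Gram-Schmidt under the
#' empirical inner product `<u, v> = mean(u * v)`), reading off the same
#' coordinate functions, variances and degeneracy flags. Intended for tests
#' and validation; it scales with `L x J^2` memory/time.
#'
#' @inheritParams build_canonical_model
#' @return A `cdx_model`, structurally identical to the production path's.
#' @export
gram_schmidt_oracle <- function(table, dict, var_tol = 1e-10) {
  J <- length(dict$monomials)
  if (J == 0L) stop_invalid("empty dictionary")
  V <- monomial_value_matrix(table$X, dict)
  mu <- colMeans(V)
  Xc <- sweep(V, 2, mu)
  U <- matrix(0, nrow(Xc), J)
  W <- diag(1, J)
  D <- numeric(J)
  degenerate <- logical(J)
  for (m in seq_len(J)) {
    u <- Xc[, m]
    scale2 <- mean(Xc[, m]^2)
    if (m > 1L) {
      for (a in seq_len(m - 1L)) {
        if (degenerate[a]) next
        w <- mean(U[, a] * u) / D[a]
        W[m, a] <- w
        u <- u - w * U[, a]
      }
    }
    Dm <- mean(u^2)
    if (!is.finite(Dm) || Dm <= var_tol * max(scale2, .Machine$double.xmin)) {
      degenerate[m] <- TRUE
      D[m] <- 0
      W[m, seq_len(m - 1L)] <- 0
    } else {
      D[m] <- Dm
      U[, m] <- u
    }
  }
  assemble_model(dict, mu, W, D, degenerate, var_tol)
}

#' Map realizations to canonical coefficients
#'
#' In dictionary order, each coefficient is the centered monomial value minus
#' its projections onto all earlier non-degenerate coefficients:
#' `p[m] = x_m - mu[m] - sum_a omega[a][m] * p[a]`. Degenerate positions
#' carry 0.
#'
#' @param model A `cdx_model`.
#' @param x One realization (numeric vector of length I) or a matrix with
#'   realizations as rows, on the same (standardized) scale the model was
#'   built on.
#' @return For a vector input, a named coefficient vector with attribute
#'   `"degenerate"`; for a matrix, a rows-by-coefficients matrix.
#' @export
extract_coefficients <- function(model, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  check_finite(X, "realization")
  if (ncol(X) != model$dict$I) {
    stop_invalid("realization length %d does not match model I=%d",
                 ncol(X), model$dict$I)
  }
  V <- monomial_value_matrix(X, model$dict)
  Xc <- sweep(V, 2, model$mu)
  P <- t(forwardsolve(model$W, t(Xc)))
  P[, model$degenerate] <- 0
  colnames(P) <- model$dict$labels
  if (vec) {
    p <- drop(P)
    attr(p, "degenerate") <- model$degenerate
    p
  } else {
    P
  }
}

#' Rebuild the first component from coefficients
#'
#' Inverts [extract_coefficients()] on the power-one monomials: for each
#' feature index i, `c(i) = mean(i) + sum_a p[a] * omega[a][(i, 1)] +
#' p[(i, 1)]`, the canonical expansion of the sequence itself. Round-trips
#' extraction exactly (up to floating point) when the power-one monomials are
#' non-degenerate.
#'
#' @param model A `cdx_model`.
#' @param coeffs Coefficient vector (length = dictionary size) or matrix
#'   (rows = realizations) from this model.
#' @return Realization vector or matrix on the model's scale.
#' @export
reconstruct_first_component <- function(model, coeffs) {
  vec <- is.null(dim(coeffs))
  P <- if (vec) matrix(coeffs, nrow = 1) else as.matrix(coeffs)
  if (ncol(P) != length(model$D)) {
    stop_invalid("coefficient length %d does not match dictionary size %d",
                 ncol(P), length(model$D))
  }
  idx <- model$block_first
  # c = mu1 + P %*% t(W[idx, ]) row-wise (W rows include the unit diagonal)
  Crec <- P %*% t(model$W[idx, , drop = FALSE])
  Crec <- sweep(Crec, 2, model$mu[idx], `+`)
  colnames(Crec) <- NULL
  if (vec) drop(Crec) else Crec
}

#' Decision coefficients of a model
#'
#' For each feature index, the last non-degenerate monomial of its block in
#' dictionary order — the maximally conditioned coefficient whose
#' class-conditional density the decision rule multiplies. For `N = 4` these
#' are the cubic term at i = 1, the lag-1 cross term with powers (1, 2) at
#' i = 2, and the lags-(1, 2) cross term with powers (1, 1, 1) from i = 3 on
#' (falling back to the block's previous non-degenerate entry where the
#' training sample degenerates one).
#'
#' @param model A `cdx_model`.
#' @return List of [monomial()] objects, one per feature index, with the
#'   dictionary positions as attribute `"index"`.
#' @export
select_decision_coefficients <- function(model) {
  if (anyNA(model$decision_idx)) {
    bad <- which(is.na(model$decision_idx))
    stop(errorCondition(
      sprintf("no usable (non-degenerate) coefficient in block(s) %s",
              paste(bad, collapse = ", ")),
      class = c("canondx_config_error", "canondx_error")))
  }
  out <- model$dict$monomials[model$decision_idx]
  attr(out, "index") <- model$decision_idx
  out
}
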