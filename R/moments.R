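# Sample mixed moments of a training set.
#
# Everything downstream (coordinate functions, coefficient variances) is a
# function of expectations E[C^{xi_g}(i - r_{g-1}) ... C^{xi_1}(i)]. Here
# they are estimated as plain sample averages over the training realizations,
# with denominator L (the maximum-likelihood convention). Denominator L, not
# L - 1, keeps the empirical Gram matrix of monomials exactly positive
# semidefinite, which the sequential orthogonalization relies on.

#' Bundle one class's realizations
#'
#' @param label Class identifier (coerced to character).
#' @param X Numeric matrix, one row per realization, `I` columns of feature
#'   values.
#' @return An object of class `cdx_class_data`.
#' @export
class_data <- function(label, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  check_finite(X, sprintf("realizations of class '%s'", label))
  if (nrow(X) < 1L) stop_invalid("class '%s' has no realizations", label)
  structure(list(label = as.character(label), X = X), class = "cdx_class_data")
}

#' @export
print.cdx_class_data <- function(x, ...) {
  cat(sprintf("Class '%s': %d realizations of length %d\n",
              x$label, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Pooled per-index standardization
#'
#' Computes one affine transform per feature index (offset = pooled mean,
#' scale = pooled standard deviation with denominator L) over the union of
#' the supplied classes, and applies it to every class. The same transform
#' must be applied to test realizations. A shared invertible per-feature
#' affine map leaves the per-class argmax of the decision rule unchanged
#' (the density Jacobian is common to all classes) while greatly improving
#' the conditioning of high-order moments.
#'
#' Zero-variance indices keep scale 1 and are flagged degenerate.
#'
#' @param sets A `cdx_class_data`, a numeric matrix, or a list of either.
#' @return List with `transform` (class `cdx_transform`: `offset`, `scale`,
#'   `degenerate`) and `sets` (the standardized input, same shape).
#' @export
standardize_features <- function(sets) {
  single <- inherits(sets, "cdx_class_data") || is.matrix(sets)
  if (single) sets <- list(sets)
  mats <- lapply(sets, function(s) if (inherits(s, "cdx_class_data")) s$X else as.matrix(s))
  pooled <- do.call(rbind, mats)
  check_finite(pooled, "feature values")
  if (nrow(pooled) < 2L) stop_invalid("standardization needs at least 2 realizations")
  offset <- colMeans(pooled)
  ctr <- sweep(pooled, 2, offset)
  scale <- sqrt(colMeans(ctr^2))
  degenerate <- scale <= .Machine$double.eps^0.5 * pmax(abs(offset), 1)
  scale[degenerate] <- 1
  tr <- structure(list(offset = offset, scale = scale, degenerate = degenerate),
                  class = "cdx_transform")
  out <- lapply(sets, function(s) {
    if (inherits(s, "cdx_class_data")) {
      class_data(s$label, apply_transform(tr, s$X))
    } else {
      apply_transform(tr, as.matrix(s))
    }
  })
  if (single) out <- out[[1]]
  list(transform = tr, sets = out)
}

#' Apply (or invert) a standardization transform
#'
#' @param tr A `cdx_transform` from [standardize_features()].
#' @param x Numeric vector (one realization) or matrix (rows = realizations).
#' @param invert If `TRUE`, maps standardized values back to the native scale.
#' @return Transformed vector or matrix.
#' @export
apply_transform <- function(tr, x, invert = FALSE) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  check_finite(m, "feature values")
  if (ncol(m) != length(tr$offset)) {
    stop_invalid("realization length %d does not match transform length %d",
                 ncol(m), length(tr$offset))
  }
  out <- if (invert) {
    sweep(sweep(m, 2, tr$scale, `*`), 2, tr$offset, `+`)
  } else {
    sweep(sweep(m, 2, tr$offset), 2, tr$scale, `/`)
  }
  if (vec) drop(out) else out
}

#' Moment table over one class's training sample
#'
#' Wraps a realization matrix with a cache of sample mixed moments. Moments
#' are keyed by the canonical (time-aggregated, sorted) form of their index
#' set, so permuting (time, power) pairs returns the cached value.
#'
#' @param X Numeric matrix of realizations (rows), typically standardized.
#' @return An object of class `cdx_moments`.
#' @export
moment_table <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  check_finite(X, "training realizations")
  env <- new.env(parent = emptyenv())
  env$X <- X
  env$L <- nrow(X)
  env$I <- ncol(X)
  env$cache <- new.env(parent = emptyenv())
  structure(env, class = "cdx_moments")
}

#' @export
print.cdx_moments <- function(x, ...) {
  cat(sprintf("Moment table: L=%d realizations, I=%d indices, %d cached moments\n",
              x$L, x$I, length(ls(x$cache))))
  invisible(x)
}

# Canonical form: aggregate powers on repeated time points, sort by time.
canonical_spec <- function(time_points, powers) {
  time_points <- as.integer(time_points)
  powers <- as.integer(powers)
  if (length(time_points) != length(powers)) {
    stop_invalid("time_points and powers must have equal length")
  }
  if (length(powers) > 0 && any(powers < 1L)) stop_invalid("powers must be >= 1")
  if (length(time_points) == 0) {
    return(list(time_points = integer(0), powers = integer(0), key = "1"))
  }
  agg <- tapply(powers, time_points, sum)
  tp <- as.integer(names(agg))
  pw <- as.integer(agg)
  o <- order(tp)
  list(time_points = tp[o], powers = pw[o],
       key = paste(tp[o], pw[o], sep = "^", collapse = "*"))
}

#' Estimate a sample mixed moment
#'
#' Returns the average over the L training realizations of the product
#' `prod(c(time_points[j])^powers[j])`. The empty specification has moment 1.
#' Results are cached and deterministic for a fixed training set.
#'
#' @param table A [moment_table()].
#' @param time_points 1-based feature indices (repeats allowed; powers on a
#'   repeated index are summed).
#' @param powers Positive integer powers, parallel to `time_points`.
#' @return The sample moment (scalar).
#' @export
estimate_moment <- function(table, time_points, powers) {
  spec <- canonical_spec(time_points, powers)
  if (length(spec$time_points) == 0) return(1)
  if (any(spec$time_points < 1L) || any(spec$time_points > table$I)) {
    stop(errorCondition(
      sprintf("moment time point out of range 1..%d", table$I),
      class = c("canondx_index_error", "canondx_error")))
  }
  cached <- table$cache[[spec$key]]
  if (!is.null(cached)) return(cached)
  P <- table$X[, spec$time_points, drop = FALSE]
  P <- sweep(P, 2, spec$powers, `^`)
  val <- mean(.rowProds(P))
  assign(spec$key, val, envir = table$cache)
  val
}

.rowProds <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- out * m[, j]
  out
}

#' Central mixed moment of two index groups
#'
#' The numerator pattern of the coordinate-function recursions:
#' `E[prod_a * prod_b] - E[prod_a] * E[prod_b]`, where each group is a
#' (time_points, powers) specification. This is the empirical covariance of
#' the two monomial values (denominator L).
#'
#' @param table A [moment_table()].
#' @param spec_a,spec_b Lists with elements `time_points` and `powers`.
#' @return The central mixed moment (scalar).
#' @export
central_mixed_moment <- function(table, spec_a, spec_b) {
  joint <- estimate_moment(table,
                           c(spec_a$time_points, spec_b$time_points),
                           c(spec_a$powers, spec_b$powers))
  joint -
    estimate_moment(table, spec_a$time_points, spec_a$powers) *
    estimate_moment(table, spec_b$time_points, spec_b$powers)
}

# Raw value columns of every dictionary monomial on a realization matrix.
monomial_value_matrix <- function(X, dict) {
  J <- length(dict$monomials)
  V <- matrix(0, nrow(X), J)
  for (j in seq_len(J)) {
    m <- dict$monomials[[j]]
    P <- X[, m$times, drop = FALSE]
    P <- sweep(P, 2, m$powers, `^`)
    V[, j] <- .rowProds(P)
  }
  V
}
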