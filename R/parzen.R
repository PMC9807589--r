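# One-dimensional Parzen (kernel) density estimates for coefficient samples.

#' Fit a Parzen density
#'
#' Kernel density estimate `f(x) = mean(K((x - s_l) / h)) / h` over the
#' stored sample points. The default bandwidth is Silverman's rule
#' `h = 0.9 * min(sd, IQR / 1.34) * L^(-1/5)`; a sample with zero spread
#' falls back to a fixed small bandwidth, giving a narrow bump at the point.
#' The fitted object stores the sample, bandwidth and kernel id, so
#' evaluation is reproducible after serialization.
#'
#' @param samples Finite numeric sample values (length >= 1).
#' @param h Bandwidth; if `NULL`, taken from `rule`.
#' @param rule Bandwidth rule, currently `"silverman"`.
#' @param kernel Kernel id, currently `"gaussian"`.
#' @param floor Positive density floor used by [log_density()]; one
#'   out-of-support coefficient must not erase all other evidence with an
#'   infinite log penalty.
#' @return An object of class `cdx_parzen`.
#' @export
fit_parzen <- function(samples, h = NULL, rule = "silverman",
                       kernel = "gaussian", floor = 1e-300) {
  if (length(samples) < 1L) stop_invalid("empty sample for density estimation")
  check_finite(samples, "density sample")
  kernel <- match.arg(kernel, "gaussian")
  rule <- match.arg(rule, "silverman")
  if (is.null(h)) {
    n <- length(samples)
    spread <- if (n >= 2L) {
      s <- stats::sd(samples)
      iqr <- stats::IQR(samples) / 1.34
      if (iqr > 0) min(s, iqr) else s
    } else 0
    h <- if (is.finite(spread) && spread > 0) {
      0.9 * spread * n^(-1 / 5)
    } else {
      1e-3  # zero-spread fallback: narrow bump at the point
    }
  }
  if (!is.finite(h) || h <= 0) stop_invalid("bandwidth must be positive")
  structure(list(samples = as.double(samples), h = as.double(h),
                 kernel = kernel, floor = as.double(floor)),
            class = "cdx_parzen")
}

#' Evaluate a Parzen density
#'
#' @param d A `cdx_parzen` object.
#' @param x Evaluation points (finite numeric).
#' @return Density values, nonnegative, same length as `x`.
#' @export
parzen_density <- function(d, x) {
  check_finite(x, "evaluation points")
  z <- outer(x, d$samples, `-`) / d$h
  rowMeans(stats::dnorm(z)) / d$h
}

#' Log density with floor
#'
#' `log(max(f(x), floor))`; never `-Inf`.
#'
#' @inheritParams parzen_density
#' @return Log-density values.
#' @export
log_density <- function(d, x) {
  log(pmax(parzen_density(d, x), d$floor))
}

#' @export
print.cdx_parzen <- function(x, ...) {
  cat(sprintf("Parzen density: %d points, h=%.4g (%s kernel)\n",
              length(x$samples), x$h, x$kernel))
  invisible(x)
}
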