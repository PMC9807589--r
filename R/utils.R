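# Internal helpers: logging, input checks, seeded evaluation, checksums.

cdx_log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

#' Set the package log level
#'
#' Controls the verbosity of training and command-line runs. At `"info"` the
#' package reports dictionary sizes, degeneracy counts and per-stage wall
#' times; `"debug"` adds per-block detail; `"warn"` (the default) only emits
#' warnings.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @return The previous level, invisibly.
#' @export
cdx_log_level <- function(level = c("warn", "info", "debug", "quiet")) {
  level <- match.arg(level)
  old <- getOption("canondx.log_level", "warn")
  options(canondx.log_level = level)
  invisible(old)
}

cdx_log <- function(level, fmt, ...) {
  threshold <- getOption("canondx.log_level", "warn")
  if (cdx_log_levels[[level]] >= cdx_log_levels[[threshold]]) {
    message(sprintf("[canondx %s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

stop_invalid <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("canondx_invalid_input", "canondx_error")))
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_invalid("%s must be numeric and finite", what)
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation; keeps results below 2^31 - 1.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 7919 + as.double(k) * 104729
  as.integer(s %% 2147483563) + 1L
}

# Order-sensitive checksum of a numeric payload; used as the integrity field
# in serialized model files. Values are rounded to 10 significant digits so
# the checksum survives decimal round-tripping.
content_checksum <- function(values) {
  v <- signif(as.double(values), 10)
  v[!is.finite(v)] <- 0
  n <- length(v)
  if (n == 0) return("chk0_0_0")
  w <- sin(seq_len(n) * 0.7292) + 2
  sprintf("chk%d_%.8e_%.8e", n, sum(v * w), sum(abs(v)))
}
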