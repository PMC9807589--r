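# Model adequacy: chi-squared independence testing of extracted coefficients
# and selection of the smallest adequate decomposition order.

#' Pearson chi-squared test on a contingency table
#'
#' Direct entry point for pre-tabulated counts: Pearson statistic with
#' expected counts from the margins, no continuity correction.
#'
#' @param counts Integer matrix of cell counts.
#' @return List with `statistic`, `df`, `p.value` and the input `counts`.
#' @export
chi2_independence_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts)) stop_invalid("counts must be nonnegative")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = unname(res$p.value), counts = counts)
}

#' Chi-squared independence test of two samples
#'
#' Bins each sample at its marginal quantiles (equalizing expected counts)
#' and applies the Pearson chi-squared test to the resulting bins-by-bins
#' contingency table; with full tables the degrees of freedom are
#' `(bins - 1)^2`. Quantile binning makes the statistic invariant under
#' monotone transforms of either sample. Ties that collapse quantile breaks
#' reduce the realized number of bins (and the degrees of freedom)
#' accordingly.
#'
#' @param x,y Equal-length numeric samples; length must be at least
#'   `5 * bins^2` so every cell has an adequate expected count.
#' @param bins Marginal bins per axis (default 4).
#' @return As [chi2_independence_table()].
#' @export
chi2_independence <- function(x, y, bins = 4L) {
  check_finite(x, "x"); check_finite(y, "y")
  bins <- as.integer(bins)
  if (bins < 2L) stop_invalid("bins must be >= 2")
  if (length(x) != length(y)) stop_invalid("samples must have equal length")
  if (length(x) < 5L * bins^2) {
    stop_invalid("need at least %d paired observations for %d x %d bins; use fewer bins",
                 5L * bins^2, bins, bins)
  }
  bx <- quantile_bins(x, bins)
  by <- quantile_bins(y, bins)
  if (nlevels(bx) < 2L || nlevels(by) < 2L) {
    stop_invalid("too many ties to form at least 2 quantile bins")
  }
  chi2_independence_table(table(bx, by))
}

quantile_bins <- function(x, bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE))
  br[1] <- -Inf
  br[length(br)] <- Inf
  cut(x, breaks = br, labels = FALSE, include.lowest = TRUE) |> factor()
}

#' Coefficient independence report
#'
#' The model-adequacy step: extracts the decision coefficients of every
#' supplied realization, tests all coefficient pairs for independence with
#' [chi2_independence()], controls the family-wise error over pairs by
#' Holm's step-down rule at level `alpha`, and accepts the independence
#' hypothesis iff no pair rejects.
#'
#' @param model A `cdx_model`.
#' @param X Realization matrix (rows), on the model's (standardized) scale —
#'   typically the training set the model was built from.
#' @param alpha Family-wise level (default 0.05).
#' @param bins Quantile bins per axis.
#' @return An object of class `cdx_indep_report`: data frame `pairs` (one
#'   row per coefficient pair with statistic, df, raw and Holm-adjusted p,
#'   reject flag), plus `accept`, `alpha`, `bins`, `n`, and the tested
#'   coefficient labels.
#' @export
coefficient_independence_report <- function(model, X, alpha = 0.05, bins = 4L) {
  X <- as.matrix(X)
  if (nrow(X) < 5L * as.integer(bins)^2) {
    stop_invalid("need at least %d realizations for %d x %d bins; use fewer bins",
                 5L * as.integer(bins)^2, bins, bins)
  }
  dec <- select_decision_coefficients(model)
  idx <- attr(dec, "index")
  P <- extract_coefficients(model, X)[, idx, drop = FALSE]
  labels <- model$dict$labels[idx]
  pairs <- utils::combn(length(idx), 2)
  rows <- apply(pairs, 2, function(pr) {
    t <- chi2_independence(P[, pr[1]], P[, pr[2]], bins = bins)
    c(statistic = t$statistic, df = t$df, p = t$p.value)
  })
  df <- data.frame(i = labels[pairs[1, ]], j = labels[pairs[2, ]],
                   t(rows), check.names = FALSE)
  df$p_holm <- stats::p.adjust(df$p, method = "holm")
  df$reject <- df$p_holm <= alpha
  structure(list(pairs = df, accept = !any(df$reject), alpha = alpha,
                 bins = as.integer(bins), n = nrow(X), labels = labels),
            class = "cdx_indep_report")
}

#' @export
print.cdx_indep_report <- function(x, ...) {
  cat(sprintf("Coefficient independence: %d pairs of %d decision coefficients, n=%d, alpha=%.3g\n",
              nrow(x$pairs), length(x$labels), x$n, x$alpha))
  cat(sprintf("  decision: %s (%d pair(s) reject after Holm)\n",
              if (x$accept) "ACCEPT independence" else "REJECT independence",
              sum(x$pairs$reject)))
  invisible(x)
}

#' Write an independence report as CSV
#'
#' One row per pair (pair, statistic, df, p, decision) plus a one-line
#' summary comment.
#'
#' @param report A `cdx_indep_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_independence_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# independence %s: %d/%d pairs reject (alpha=%g, n=%d)",
                     if (report$accept) "accepted" else "rejected",
                     sum(report$pairs$reject), nrow(report$pairs),
                     report$alpha, report$n), con)
  utils::write.csv(report$pairs, con, row.names = FALSE)
  invisible(path)
}

#' Smallest adequate decomposition order
#'
#' Builds the generalized model for each candidate order `N` (degree bound
#' `N - 1`) on one class's realizations and returns the smallest candidate
#' whose coefficient-independence report accepts.
#'
#' @param X One class's realization matrix or a [class_data()] object;
#'   standardized internally.
#' @param candidates Candidate orders, ascending (default `2:4`; `N = 2` is
#'   the linear model).
#' @param alpha,bins Passed to [coefficient_independence_report()].
#' @param max_lag,var_tol Model-building parameters.
#' @return List with `N` (selected order), `report` (its accepted report)
#'   and `failed` (per-rejected-candidate summaries).
#' @export
choose_order <- function(X, candidates = 2:4, alpha = 0.05, bins = 4L,
                         max_lag = 2L, var_tol = 1e-10) {
  if (inherits(X, "cdx_class_data")) X <- X$X
  X <- as.matrix(X)
  if (length(candidates) < 1L) stop_invalid("need at least one candidate order")
  candidates <- sort(as.integer(candidates))
  Xstd <- standardize_features(X)$sets
  failed <- character(0)
  for (N in candidates) {
    dict <- build_dictionary(ncol(X), N = N, B = N - 1L, max_lag = max_lag,
                             kind = "nonlinear")
    model <- build_canonical_model(moment_table(Xstd), dict, var_tol = var_tol)
    rep_N <- tryCatch(
      coefficient_independence_report(model, Xstd, alpha = alpha, bins = bins),
      canondx_error = function(e) e)
    if (inherits(rep_N, "error")) {
      failed <- c(failed, sprintf("N=%d: %s", N, conditionMessage(rep_N)))
      next
    }
    if (rep_N$accept) {
      return(list(N = N, report = rep_N, failed = failed))
    }
    failed <- c(failed, sprintf("N=%d: %d pair(s) reject independence",
                                N, sum(rep_N$pairs$reject)))
  }
  stop(errorCondition(
    paste0("no candidate order accepted:\n  ", paste(failed, collapse = "\n  ")),
    class = c("canondx_config_error", "canondx_error")))
}

#' Permutation test of independence on mutual information
#'
#' Optional second check with the same role as the chi-squared test: the
#' plug-in mutual information of the quantile-binned contingency table is
#' compared against its permutation null (shuffling `y`).
#'
#' @param x,y Equal-length samples.
#' @param bins Quantile bins per axis.
#' @param n_perm Number of permutations.
#' @return List with `mi`, `p.value`, `n_perm`.
#' @export
mi_permutation_test <- function(x, y, bins = 4L, n_perm = 199L) {
  check_finite(x, "x"); check_finite(y, "y")
  if (length(x) != length(y)) stop_invalid("samples must have equal length")
  bx <- quantile_bins(x, bins)
  by <- quantile_bins(y, bins)
  mi_of <- function(a, b) {
    tab <- table(a, b) / length(a)
    px <- rowSums(tab); py <- colSums(tab)
    nz <- tab > 0
    sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
  }
  mi <- mi_of(bx, by)
  null <- vapply(seq_len(n_perm), function(i) mi_of(bx, sample(by)), numeric(1))
  list(mi = mi, p.value = (1 + sum(null >= mi)) / (n_perm + 1), n_perm = n_perm)
}
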