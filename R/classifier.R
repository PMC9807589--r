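# Maximum-likelihood diagnostic classifier.
#
# Training: pooled standardization, then per class a moment table, a
# canonical model and Parzen densities of that class's own decision
# coefficients. Classification: a test realization is decomposed separately
# under each class's model (the densities are class-conditional, so each
# class's own moments define its coefficients) and assigned to the class
# maximizing the sum of log densities over the decision coefficients.

criterion_dictionary <- function(criterion, I, N, Np, max_lag) {
  switch(criterion,
    linear = build_dictionary(I, N = 2L, B = 1L, kind = "linear"),
    polynomial = build_dictionary(I, N = Np + 1L, B = Np, kind = "polynomial"),
    nonlinear = build_dictionary(I, N = N, B = N - 1L, max_lag = max_lag,
                                 kind = "nonlinear"))
}

#' Train a diagnostic classifier
#'
#' @param sets List of [class_data()] training sets (one per class, unique
#'   labels, consistent realization length, each with at least 2
#'   realizations).
#' @param criterion Decision-rule family: `"nonlinear"` (full cross-time
#'   dictionary of order `N`), `"polynomial"` (single-time powers `1..Np`) or
#'   `"linear"` (first powers only).
#' @param N Decomposition order for the nonlinear criterion (default 4).
#' @param Np Polynomial criterion order (default 3).
#' @param max_lag Lag window of the nonlinear dictionary; see
#'   [build_dictionary()].
#' @param var_tol Degeneracy tolerance passed to [build_canonical_model()].
#' @param unknown_quantile If non-`NULL`, sets the low-likelihood "unknown"
#'   threshold to this quantile of each class's own training log-likelihoods
#'   (the minimum over classes is used). Off by default.
#' @return An object of class `cdx_classifier`.
#' @export
train_classifier <- function(sets, criterion = c("nonlinear", "polynomial", "linear"),
                             N = 4L, Np = 3L, max_lag = 2L, var_tol = 1e-10,
                             unknown_quantile = NULL) {
  criterion <- match.arg(criterion)
  if (inherits(sets, "cdx_class_data")) sets <- list(sets)
  if (length(sets) < 1L) stop_invalid("need at least one training class")
  if (!all(vapply(sets, inherits, logical(1), "cdx_class_data"))) {
    stop_invalid("training sets must be class_data objects")
  }
  labels <- vapply(sets, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop_invalid("class labels must be unique")
  Is <- vapply(sets, function(s) ncol(s$X), integer(1))
  if (length(unique(Is)) != 1L) {
    stop_invalid("inconsistent realization length across classes: %s",
                 paste(Is, collapse = ", "))
  }
  Ls <- vapply(sets, function(s) nrow(s$X), integer(1))
  if (any(Ls < 2L)) stop_invalid("every class needs at least 2 realizations")
  I <- Is[1]
  sets <- sets[order(labels)]
  labels <- sort(labels)

  t0 <- proc.time()[["elapsed"]]
  std <- standardize_features(sets)
  dict <- criterion_dictionary(criterion, I, N, Np, max_lag)
  cdx_log("info", "training %s criterion: K=%d classes, I=%d, dictionary %d entries",
          criterion, length(sets), I, length(dict$monomials))

  classes <- vector("list", length(sets))
  train_ll <- numeric(0)
  for (k in seq_along(sets)) {
    Xk <- std$sets[[k]]$X
    tab <- moment_table(Xk)
    model <- build_canonical_model(tab, dict, var_tol = var_tol)
    if (anyNA(model$decision_idx)) {
      bad <- which(is.na(model$decision_idx))
      stop(errorCondition(
        sprintf("training failed for class '%s': no usable coefficient in block(s) %s (degenerate variances)",
                labels[k], paste(bad, collapse = ", ")),
        class = c("canondx_training_error", "canondx_error")))
    }
    P <- extract_coefficients(model, Xk)
    dec <- model$decision_idx
    # studentize the in-sample coefficients before density fitting: the
    # residual of a monomial conditioned on p earlier coefficients (plus its
    # mean) under-disperses by the usual regression factor sqrt(1 - p/n),
    # so the raw in-sample spread underestimates that of fresh realizations
    n_used <- cumsum(!model$degenerate) - !model$degenerate  # earlier nondeg
    dens <- lapply(seq_along(dec), function(j) {
      p_eff <- n_used[dec[j]] + 1L
      infl <- if (p_eff < nrow(Xk)) sqrt(nrow(Xk) / (nrow(Xk) - p_eff)) else 1
      fit_parzen(P[, dec[j]] * infl)
    })
    names(dens) <- model$dict$labels[dec]
    cdx_log("info", "class '%s': %d/%d degenerate coefficients",
            labels[k], sum(model$degenerate), length(model$D))
    classes[[k]] <- list(label = labels[k], model = model,
                         densities = dens, n_train = nrow(Xk))
  }
  clf <- structure(
    list(criterion = criterion, N = as.integer(N), Np = as.integer(Np),
         B = dict$B, max_lag = dict$max_lag, I = I,
         transform = std$transform, labels = labels, classes = classes,
         var_tol = var_tol, unknown_threshold = NULL),
    class = "cdx_classifier")
  if (!is.null(unknown_quantile)) {
    per_class <- vapply(seq_along(classes), function(k) {
      ll <- class_loglik(clf, k, std$sets[[k]]$X)
      stats::quantile(ll, unknown_quantile, names = FALSE)
    }, numeric(1))
    clf$unknown_threshold <- min(per_class)
  }
  cdx_log("info", "training finished in %.2fs", proc.time()[["elapsed"]] - t0)
  clf
}

# Log-likelihood of standardized realizations under one class's model.
class_loglik <- function(clf, k, Xstd) {
  cls <- clf$classes[[k]]
  P <- extract_coefficients(cls$model, Xstd)
  dec <- cls$model$decision_idx
  ll <- numeric(nrow(Xstd))
  for (j in seq_along(dec)) {
    ll <- ll + log_density(cls$densities[[j]], P[, dec[j]])
  }
  ll
}

#' @export
print.cdx_classifier <- function(x, ...) {
  cat(sprintf("canondx classifier (%s criterion, N=%d): %d classes [%s], I=%d\n",
              x$criterion, x$N, length(x$classes),
              paste(x$labels, collapse = ", "), x$I))
  if (!is.null(x$unknown_threshold)) {
    cat(sprintf("  unknown-disease threshold: log-likelihood < %.3f\n",
                x$unknown_threshold))
  }
  invisible(x)
}

#' Classify realizations
#'
#' Standardizes the input with the classifier's shared transform, extracts
#' coefficients under every class's model, sums log Parzen densities over the
#' decision coefficients and returns the per-class log-likelihoods and the
#' argmax label. Exact ties go to the smallest label. If an unknown
#' threshold is set and the best log-likelihood falls below it, the
#' prediction is `"unknown"` (a realization far from every trained disease
#' pattern).
#'
#' @param clf A [train_classifier()] result.
#' @param x Realization vector of length I, or matrix with realizations as
#'   rows, on the native feature scale.
#' @param unknown_threshold Optional override of the trained threshold.
#' @return A data frame with columns `predicted`, one `loglik_<label>` per
#'   class, and `unknown`.
#' @export
classify <- function(clf, x, unknown_threshold = NULL) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != clf$I) {
    stop_invalid("realization length %d does not match classifier I=%d",
                 ncol(X), clf$I)
  }
  Xstd <- apply_transform(clf$transform, X)
  LL <- vapply(seq_along(clf$classes), function(k) class_loglik(clf, k, Xstd),
               numeric(nrow(X)))
  LL <- matrix(LL, nrow = nrow(X))
  colnames(LL) <- paste0("loglik_", clf$labels)
  best <- max.col(LL, ties.method = "first")
  predicted <- clf$labels[best]
  thr <- if (is.null(unknown_threshold)) clf$unknown_threshold else unknown_threshold
  unknown <- if (is.null(thr)) rep(FALSE, nrow(X)) else LL[cbind(seq_len(nrow(X)), best)] < thr
  predicted[unknown] <- "unknown"
  out <- data.frame(predicted = predicted, LL, unknown = unknown,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-class percent-correct of a classifier
#'
#' @param clf A trained classifier.
#' @param test_sets List of labeled [class_data()] test sets; labels must be
#'   among the classifier's.
#' @return A list with `per_class` (named percentages), `overall`
#'   (percentage) and `n` (test counts per class).
#' @export
evaluate_accuracy <- function(clf, test_sets) {
  if (inherits(test_sets, "cdx_class_data")) test_sets <- list(test_sets)
  labs <- vapply(test_sets, `[[`, character(1), "label")
  if (!all(labs %in% clf$labels)) {
    stop_invalid("unseen test label(s): %s",
                 paste(setdiff(labs, clf$labels), collapse = ", "))
  }
  per <- numeric(length(test_sets))
  n <- integer(length(test_sets))
  correct_total <- 0L
  for (j in seq_along(test_sets)) {
    pred <- classify(clf, test_sets[[j]]$X)$predicted
    n[j] <- length(pred)
    hits <- sum(pred == labs[j])
    per[j] <- 100 * hits / n[j]
    correct_total <- correct_total + hits
  }
  names(per) <- labs
  names(n) <- labs
  list(per_class = per, overall = 100 * correct_total / sum(n), n = n)
}

#' Accuracy table of the three criteria on a benchmark
#'
#' Trains the linear, polynomial and nonlinear criteria on a benchmark's
#' training split and evaluates per-class percent-correct on its test split,
#' mirroring the criteria-by-classes layout of published comparison tables.
#'
#' @param bench A [make_benchmark()] result.
#' @param criteria Subset of `c("linear", "polynomial", "nonlinear")`.
#' @param N,Np,max_lag,var_tol Passed to [train_classifier()].
#' @return A data frame: one row per criterion, one column per class label
#'   plus `overall` (percentages).
#' @export
benchmark_accuracy <- function(bench, criteria = c("linear", "polynomial", "nonlinear"),
                               N = 4L, Np = 3L, max_lag = 2L, var_tol = 1e-10) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  rows <- lapply(criteria, function(cr) {
    clf <- train_classifier(bench$train, criterion = cr, N = N, Np = Np,
                            max_lag = max_lag, var_tol = var_tol)
    acc <- evaluate_accuracy(clf, bench$test)
    c(acc$per_class, overall = acc$overall)
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  cbind(criterion = criteria, out)
}
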