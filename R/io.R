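# File formats: feature CSV and JSON model persistence.

#' Write a feature table CSV
#'
#' Layout: header `label,c1,...,cI`, one row per realization, comma
#' separator, `.` decimal, full decimal precision.
#'
#' @param sets A [class_data()] or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(sets, path) {
  if (inherits(sets, "cdx_class_data")) sets <- list(sets)
  I <- ncol(sets[[1]]$X)
  lines <- c(paste(c("label", paste0("c", seq_len(I))), collapse = ","))
  for (s in sets) {
    if (ncol(s$X) != I) stop_invalid("inconsistent realization length across classes")
    vals <- apply(s$X, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                            collapse = ","))
    lines <- c(lines, paste(s$label, vals, sep = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature table CSV
#'
#' Parses and validates a `label,c1,...,cI` table and groups rows by label
#' (order of first appearance). Malformed headers, ragged rows and
#' non-numeric cells raise parse errors citing the offending line.
#'
#' @param path Input file.
#' @return List of [class_data()] objects.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2L) stop_invalid("%s: need a header and at least one row", path)
  parse_error <- function(line_no, fmt, ...) {
    stop(errorCondition(
      sprintf("%s: line %d: %s", path, line_no, sprintf(fmt, ...)),
      class = c("canondx_parse_error", "canondx_error")))
  }
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  I <- length(header) - 1L
  if (I < 1L || header[1] != "label" ||
      !identical(header[-1], paste0("c", seq_len(I)))) {
    parse_error(1L, "malformed header; expected label,c1,...,cI")
  }
  labels <- character(length(lines) - 1L)
  vals <- matrix(NA_real_, length(lines) - 1L, I)
  for (r in seq_along(labels)) {
    cells <- strsplit(lines[r + 1L], ",", fixed = TRUE)[[1]]
    if (length(cells) != I + 1L) {
      parse_error(r + 1L, "expected %d fields, found %d", I + 1L, length(cells))
    }
    labels[r] <- cells[1]
    v <- suppressWarnings(as.numeric(cells[-1]))
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(cells[-1]))))[1]
      parse_error(r + 1L, "non-numeric or non-finite value '%s' in column c%d",
                  cells[-1][bad], bad)
    }
    vals[r, ] <- v
  }
  out <- lapply(unique(labels), function(lb) {
    class_data(lb, vals[labels == lb, , drop = FALSE])
  })
  counts <- vapply(out, function(s) nrow(s$X), integer(1))
  cdx_log("info", "read %s: %d rows, %d classes (%s)", path, length(labels),
          length(out), paste(sprintf("%s:%d", unique(labels), counts),
                             collapse = ", "))
  out
}

model_schema_version <- "canondx-model/1"

classifier_payload <- function(clf) {
  unlist(c(clf$transform$offset, clf$transform$scale,
           lapply(clf$classes, function(cl) {
             c(cl$model$mu, as.vector(cl$model$W), cl$model$D,
               unlist(lapply(cl$densities, function(d) c(d$samples, d$h))))
           })))
}

#' Save a classifier to a JSON model file
#'
#' Serializes the standardization transform, every class's dictionary
#' (explicit monomial list), coordinate-function table, variances,
#' degeneracy flags, decision indices and Parzen densities (samples,
#' bandwidth, kernel id) at full precision, plus provenance (training row
#' counts, optional seed, content checksum). Reloading reproduces
#' classification results bit-for-bit.
#'
#' @param clf A trained [train_classifier()] result.
#' @param path Output file.
#' @param seed Optional integer recorded as provenance.
#' @return `path`, invisibly.
#' @export
save_model <- function(clf, path, seed = NULL) {
  if (!inherits(clf, "cdx_classifier")) stop_invalid("clf must be a cdx_classifier")
  doc <- list(
    schema_version = model_schema_version,
    criterion = clf$criterion, N = clf$N, Np = clf$Np, B = clf$B,
    max_lag = if (is.finite(clf$max_lag)) clf$max_lag else "Inf",
    I = clf$I, labels = clf$labels,
    unknown_threshold = clf$unknown_threshold,
    var_tol = clf$var_tol,
    transform = list(offset = clf$transform$offset,
                     scale = clf$transform$scale,
                     degenerate = clf$transform$degenerate),
    classes = lapply(clf$classes, function(cl) {
      m <- cl$model
      list(label = cl$label, n_train = cl$n_train,
           dictionary = lapply(m$dict$monomials, function(mm) {
             list(nu = mm$nu, lags = mm$lags, powers = mm$powers)
           }),
           dict_kind = m$dict$kind, dict_N = m$dict$N, dict_B = m$dict$B,
           mu = m$mu, mean = m$mean, W = m$W, D = m$D,
           degenerate = m$degenerate, decision_idx = m$decision_idx,
           densities = lapply(cl$densities, function(d) {
             list(samples = d$samples, h = d$h, kernel = d$kernel,
                  floor = d$floor)
           }))
    }),
    provenance = list(seed = seed,
                      n_train = vapply(clf$classes, `[[`, integer(1), "n_train"),
                      checksum = content_checksum(classifier_payload(clf)))
  )
  # digits = I(17): full significant-digit printing, so doubles round-trip
  # exactly and reloaded classification is bit-identical
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Load a classifier from a JSON model file
#'
#' Checks the schema version and the content checksum before returning.
#'
#' @param path Model file written by [save_model()].
#' @return A `cdx_classifier`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = TRUE),
    error = function(e) {
      stop(errorCondition(sprintf("%s: not a valid model file (%s)",
                                  path, conditionMessage(e)),
                          class = c("canondx_parse_error", "canondx_error")))
    })
  if (!identical(doc$schema_version, model_schema_version)) {
    stop(errorCondition(
      sprintf("%s: unsupported model schema '%s' (expected '%s')",
              path, doc$schema_version, model_schema_version),
      class = c("canondx_version_error", "canondx_error")))
  }
  max_lag <- if (identical(doc$max_lag, "Inf")) Inf else as.numeric(doc$max_lag)
  classes <- lapply(doc$classes, function(cl) {
    monos <- lapply(cl$dictionary, function(mm) {
      monomial(mm$nu, unlist(mm$lags) %||% integer(0), unlist(mm$powers))
    })
    block <- vapply(monos, `[[`, integer(1), "nu")
    dict <- structure(
      list(I = as.integer(doc$I), N = as.integer(cl$dict_N),
           B = as.integer(cl$dict_B), max_lag = max_lag,
           kind = cl$dict_kind, monomials = monos, block = block,
           labels = vapply(monos, format, character(1))),
      class = "cdx_dictionary")
    W <- cl$W
    if (!is.matrix(W)) W <- do.call(rbind, lapply(W, unlist))
    storage.mode(W) <- "double"
    if (!all(dim(W) == length(monos))) {
      stop(errorCondition(
        sprintf("%s: coordinate-function table has wrong shape", path),
        class = c("canondx_parse_error", "canondx_error")))
    }
    model <- assemble_model(dict, as.double(cl$mu), W, as.double(cl$D),
                            as.logical(cl$degenerate), as.double(doc$var_tol))
    if (!identical(model$decision_idx, as.integer(cl$decision_idx))) {
      stop(errorCondition(
        sprintf("%s: decision indices inconsistent with degeneracy flags", path),
        class = c("canondx_parse_error", "canondx_error")))
    }
    dens <- lapply(cl$densities, function(d) {
      fit_parzen(unlist(d$samples), h = d$h, kernel = d$kernel, floor = d$floor)
    })
    names(dens) <- dict$labels[model$decision_idx]
    list(label = cl$label, model = model, densities = dens,
         n_train = as.integer(cl$n_train))
  })
  transform <- structure(
    list(offset = as.double(doc$transform$offset),
         scale = as.double(doc$transform$scale),
         degenerate = as.logical(doc$transform$degenerate)),
    class = "cdx_transform")
  clf <- structure(
    list(criterion = doc$criterion, N = as.integer(doc$N),
         Np = as.integer(doc$Np), B = as.integer(doc$B), max_lag = max_lag,
         I = as.integer(doc$I), transform = transform,
         labels = as.character(doc$labels), classes = classes,
         var_tol = as.double(doc$var_tol),
         unknown_threshold = doc$unknown_threshold),
    class = "cdx_classifier")
  expected <- doc$provenance$checksum
  actual <- content_checksum(classifier_payload(clf))
  if (!identical(expected, actual)) {
    stop(errorCondition(
      sprintf("%s: content checksum mismatch (file corrupted or edited)", path),
      class = c("canondx_parse_error", "canondx_error")))
  }
  clf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an accuracy table CSV
#'
#' Criteria as rows, class labels as columns (the layout of published
#' percent-correct comparison tables).
#'
#' @param acc A [benchmark_accuracy()] data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_accuracy_table <- function(acc, path) {
  utils::write.csv(acc, path, row.names = FALSE)
  invisible(path)
}
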