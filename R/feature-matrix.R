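#' Trials-by-features matrix with provenance
#'
#' The tabular output of every feature pipeline: one row per trial, labels
#' and subject ids carried from the source dataset, and a provenance tag
#' naming the producing pipeline.
#'
#' @param values numeric matrix `[n_trials x n_features]`, all finite.
#' @param labels,subjects per-trial integer vectors from the source dataset.
#' @param provenance one of `"raw"`, `"ica"`, `"pca"`, `"csp_pair"`,
#'   `"csp_ova"`, `"car_dwt"`, `"all"`.
#' @param feature_names character vector of length `n_features`.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, labels, subjects, provenance,
                           feature_names = NULL) {
  values <- as.matrix(values)
  if (is.null(feature_names)) {
    feature_names <- sprintf("f%04d", seq_len(ncol(values)))
  }
  fm <- structure(
    list(values = values, labels = as.integer(labels),
         subjects = as.integer(subjects),
         provenance = provenance,
         feature_names = as.character(feature_names)),
    class = "feature_matrix")
  validate_feature_matrix(fm)
  fm
}

feature_provenances <- c("raw", "ica", "pca", "csp_pair", "csp_ova",
                         "car_dwt", "all")

validate_feature_matrix <- function(fm) {
  if (!all(is.finite(fm$values))) {
    abort("values: contains non-finite entries",
          class = "eegseek_validation_error")
  }
  if (length(fm$labels) != nrow(fm$values) ||
      length(fm$subjects) != nrow(fm$values)) {
    abort("labels/subjects: length must equal the number of rows",
          class = "eegseek_validation_error")
  }
  if (!fm$provenance %in% feature_provenances) {
    abort(sprintf("provenance: must be one of %s",
                  paste(feature_provenances, collapse = ", ")),
          class = "eegseek_validation_error")
  }
  if (length(fm$feature_names) != ncol(fm$values)) {
    abort("feature_names: length must equal the number of columns",
          class = "eegseek_validation_error")
  }
  invisible(fm)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%s)\n",
              nrow(x$values), ncol(x$values), x$provenance))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  df <- as.data.frame(x$values)
  names(df) <- x$feature_names
  cbind(data.frame(label = x$labels, subject = x$subjects), df)
}

#' Coerce a feature matrix to a tibble
#' @param x a `feature_matrix`.
#' @param ... unused.
#' @return A tibble with `label`, `subject` and one column per feature.
#' @exportS3Method tibble::as_tibble
as_tibble.feature_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

subset_feature_rows <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE], fm$labels[idx],
                 fm$subjects[idx], fm$provenance, fm$feature_names)
}

#' Concatenate feature pipelines column-wise
#'
#' Builds the combined "all" feature set by concatenating pipeline outputs
#' for the same trials in the fixed order raw, ica, pca, csp_pair, csp_ova,
#' car_dwt (any subset of that order is accepted, in that order).
#'
#' @param parts list of `feature_matrix` objects over identical trials.
#' @return A `feature_matrix` with provenance `"all"`.
#' @export
concat_features <- function(parts) {
  if (length(parts) < 1L) {
    abort("need at least one part", class = "eegseek_validation_error")
  }
  n <- vapply(parts, function(p) nrow(p$values), integer(1))
  if (any(n == 0L) || length(unique(n)) != 1L) {
    abort("all parts must have the same nonzero number of rows",
          class = "eegseek_validation_error")
  }
  ref <- parts[[1]]
  for (p in parts[-1]) {
    if (!identical(p$labels, ref$labels) ||
        !identical(p$subjects, ref$subjects)) {
      abort("parts disagree on trial labels/subjects (row order mismatch)",
            class = "eegseek_validation_error")
    }
  }
  ord <- order(match(vapply(parts, `[[`, "", "provenance"),
                     feature_provenances))
  parts <- parts[ord]
  feature_matrix(
    do.call(cbind, lapply(parts, `[[`, "values")),
    ref$labels, ref$subjects, "all",
    unlist(lapply(parts, function(p) {
      paste(p$provenance, p$feature_names, sep = ".")
    }), use.names = FALSE))
}
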