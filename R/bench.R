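# Benchmark grid: every (model, method) cell runs split -> featurize (fit
# on train only) -> normalize (fit on train only) -> train -> evaluate,
# deterministically under one master seed. Failed cells are flagged, never
# silently dropped.

#' Built-in classifier interfaces
#'
#' Each model is a named list with a `fit(train_fm, dev_fm, seed)` closure
#' returning an object usable with `predict()`. Any classifier exposing
#' this contract can be benchmarked.
#'
#' `brute_extra_tree_model()` is the seed-searched tree (the package's
#' core method); `single_tree_model()` is one extremely randomized tree
#' with the cell seed (the natural baseline); `majority_class_model()`
#' always predicts the most frequent training label (ties to the lowest
#' code).
#'
#' @param m candidate-seed count for the search; `"auto"` applies
#'   [budget()] to the training size.
#' @param params a [tree_params()] template.
#' @return A model specification list with fields `name` and `fit`.
#' @export
brute_extra_tree_model <- function(m = "auto", params = tree_params()) {
  list(name = "BruteExtraTree",
       fit = function(train, dev, seed) {
         brute_fit(train, dev, params = params, m = m, seed0 = seed,
                   audit = FALSE)
       })
}

#' @rdname brute_extra_tree_model
#' @export
single_tree_model <- function(params = tree_params()) {
  list(name = "ExtraTree",
       fit = function(train, dev, seed) {
         p <- params
         p$seed <- seed
         fit_tree(train, params = p)
       })
}

#' @rdname brute_extra_tree_model
#' @export
majority_class_model <- function() {
  list(name = "MajorityClass",
       fit = function(train, dev, seed) {
         tab <- tabulate(train$labels + 1L, nbins = 4L)
         structure(list(label = which.max(tab) - 1L),
                   class = "majority_model")
       })
}

#' @export
predict.majority_model <- function(object, newdata, ...) {
  n <- if (inherits(newdata, "feature_matrix")) nrow(newdata$values)
       else nrow(as.matrix(newdata))
  rep(object$label, n)
}

run_cell <- function(feats, model, cell_seed) {
  nz <- normalize_fit(feats$train)
  tr <- normalize_apply(nz, feats$train)
  dv <- normalize_apply(nz, feats$dev)
  te <- normalize_apply(nz, feats$test)
  fitted <- model$fit(tr, dv, cell_seed)
  list(train_acc = accuracy(predict(fitted, tr), tr$labels),
       test_acc = accuracy(predict(fitted, te), te$labels),
       fitted = fitted)
}

#' Run the model-by-preprocessing benchmark grid
#'
#' For every (model, method) cell — and, in subject-dependent mode, every
#' subject — performs the full leakage-free protocol: split, featurize
#' (fitted on train only), z-score normalize (fitted on train only), train
#' (model selection on the development split only), and evaluate train and
#' test accuracy. All per-cell seeds derive deterministically from
#' `seed`, so a rerun reproduces the grid exactly. A cell whose pipeline
#' raises an error is flagged `failed: <message>` and the grid continues.
#'
#' @param ds an `eeg_epochs` dataset.
#' @param models named list of model specifications (see
#'   [brute_extra_tree_model()]).
#' @param methods feature pipelines to run, subset of
#'   [pipeline_methods()].
#' @param mode `"subject_dependent"` (one split per subject, results per
#'   subject) or `"subject_independent"` (one split holding out
#'   `test_subjects`).
#' @param subjects subject ids for subject-dependent mode; default all.
#' @param test_subjects held-out subject ids for subject-independent mode.
#' @param test_frac,dev_frac split fractions.
#' @param n_keep CSP filters retained per contrast.
#' @param seed master seed; every split and model seed derives from it.
#' @return A `results_grid` tibble with columns `model`, `method`,
#'   `subject` (`NA` in subject-independent mode), `train_acc`,
#'   `test_acc`, `status`, `seed`, and metadata attributes
#'   `dataset_hash`, `master_seed`, `mode`.
#' @export
run_benchmark <- function(ds, models, methods = "raw",
                          mode = c("subject_dependent",
                                   "subject_independent"),
                          subjects = NULL, test_subjects = NULL,
                          test_frac = 0.2, dev_frac = 0.2, n_keep = 4L,
                          seed = 1L) {
  validate_epochs(ds)
  mode <- match.arg(mode)
  methods <- match.arg(methods, pipeline_methods(), several.ok = TRUE)
  if (length(models) < 1L) {
    abort("need at least one model", class = "eegseek_validation_error")
  }
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- vapply(models, `[[`, "", "name")
  }

  units <- if (mode == "subject_dependent") {
    if (is.null(subjects)) subjects <- sort(unique(ds$subjects))
    subjects
  } else {
    if (is.null(test_subjects)) {
      abort("subject-independent mode needs test_subjects",
            class = "eegseek_validation_error")
    }
    list(test_subjects)
  }

  rows <- list()
  for (u in seq_along(units)) {
    unit <- units[[u]]
    split_seed <- substream_seed(seed, paste0("split", u))
    split <- if (mode == "subject_dependent") {
      split_subject_dependent(ds, unit, test_frac, dev_frac, split_seed)
    } else {
      split_subject_independent(ds, unit, dev_frac, split_seed)
    }
    for (method in methods) {
      feats <- tryCatch(featurize_split(ds, method, split, n_keep = n_keep),
                        error = function(e) e)
      for (mn in names(models)) {
        cell_seed <- substream_seed(seed, paste("cell", mn, method, u))
        res <- if (inherits(feats, "error")) {
          feats
        } else {
          tryCatch(run_cell(feats, models[[mn]], cell_seed),
                   error = function(e) e)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          model = mn, method = method,
          subject = if (mode == "subject_dependent") as.integer(unit)
                    else NA_integer_,
          train_acc = if (inherits(res, "error")) NA_real_ else res$train_acc,
          test_acc = if (inherits(res, "error")) NA_real_ else res$test_acc,
          status = if (inherits(res, "error")) {
            paste0("failed: ", conditionMessage(res))
          } else "ok",
          seed = cell_seed)
      }
    }
  }
  grid <- dplyr::bind_rows(rows)
  attr(grid, "dataset_hash") <- rlang::hash(ds)
  attr(grid, "master_seed") <- as.integer(seed)
  attr(grid, "mode") <- mode
  class(grid) <- c("results_grid", class(grid))
  grid
}

#' Aggregate a results grid over subjects
#'
#' Subject-dependent grids carry one row per subject; the reported cell
#' value is the unweighted mean accuracy over subjects. Subject-independent
#' grids pass through.
#'
#' @param grid a `results_grid`.
#' @return A tibble with one row per (model, method).
#' @export
summarize_grid <- function(grid) {
  grid |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$model, .data$method) |>
    dplyr::summarise(train_acc = mean(.data$train_acc),
                     test_acc = mean(.data$test_acc),
                     n_units = dplyr::n(), .groups = "drop")
}

#' Write a results grid to CSV
#'
#' Fixed schema `axis1,axis2,train_acc,test_acc,status,seed`. With
#' `by = "model"` (default) axis1 is the model and rows aggregate over
#' subjects; with `by = "subject"` axis1 is the subject (one model
#' expected). Byte-identical output for identical grids.
#'
#' @param grid a `results_grid`.
#' @param path output CSV path.
#' @param by `"model"` or `"subject"` for axis1.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(grid, path, by = c("model", "subject")) {
  by <- match.arg(by)
  df <- if (by == "model") {
    agg <- grid |>
      dplyr::group_by(.data$model, .data$method) |>
      dplyr::summarise(
        train_acc = mean(.data$train_acc),
        test_acc = mean(.data$test_acc),
        status = if (all(.data$status == "ok")) "ok"
                 else paste(unique(.data$status[.data$status != "ok"]),
                            collapse = "; "),
        seed = attr(grid, "master_seed"), .groups = "drop") |>
      dplyr::arrange(.data$model, .data$method)
    data.frame(axis1 = agg$model, axis2 = agg$method,
               train_acc = agg$train_acc, test_acc = agg$test_acc,
               status = agg$status, seed = agg$seed)
  } else {
    agg <- grid |>
      dplyr::arrange(.data$subject, .data$method)
    data.frame(axis1 = agg$subject, axis2 = agg$method,
               train_acc = agg$train_acc, test_acc = agg$test_acc,
               status = agg$status, seed = agg$seed)
  }
  con <- file(path, open = "wb")           # fixed EOL for byte-identity
  on.exit(close(con))
  writeLines("axis1,axis2,train_acc,test_acc,status,seed", con, sep = "\n")
  writeLines(sprintf("%s,%s,%.10g,%.10g,%s,%d", df$axis1, df$axis2,
                     df$train_acc, df$test_acc, df$status, df$seed),
             con, sep = "\n")
  invisible(path)
}

#' Heatmap of a results grid
#'
#' Test accuracy per cell, mirroring the model-by-preprocessing (or
#' subject-by-preprocessing) accuracy heatmaps this benchmark reproduces.
#'
#' @param object a `results_grid`.
#' @param value column to plot, default `"test_acc"`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.results_grid <- function(object, value = "test_acc", ...) {
  df <- summarize_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$model,
                                   fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data[[value]])), size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "preprocessing", y = NULL, fill = value) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.results_grid
#' @param grid a `results_grid`.
#' @export
plot_results_heatmap <- function(grid, value = "test_acc") {
  autoplot.results_grid(grid, value = value)
}
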