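# The seed-search meta-procedure: train many independently seeded
# extremely randomized trees and keep the development-set argmax. This is
# a single selected tree, not an ensemble.

#' Seed-search budget from the training-set size
#'
#' `clamp(round(450000 / n_train), 1000, 2500)`: smaller training sets get
#' more candidate seeds, larger ones fewer, keeping total training effort
#' roughly constant. Always within the documented 1,000-2,500 range and
#' non-increasing in `n_train`.
#'
#' @param n_train number of training rows (>= 1).
#' @return Integer number of candidate seeds.
#' @export
budget <- function(n_train) {
  if (any(n_train < 1)) {
    abort("n_train must be >= 1", class = "eegseek_validation_error")
  }
  as.integer(pmin(2500, pmax(1000, round(450000 / n_train))))
}

#' Seed-searched extremely randomized tree ("BruteExtraTree")
#'
#' Trains `m` completely independent trees with seeds `seed0, seed0 + 1,
#' ..., seed0 + m - 1`, scores each on the development split by accuracy,
#' and returns the argmax; ties go to the smallest seed. Selection uses the
#' development split only — test rows are never touched.
#'
#' @param train a `feature_matrix` (or plain matrix) of training rows.
#' @param dev a `feature_matrix` (or matrix) of development rows, disjoint
#'   from `train`.
#' @param y_train,y_dev integer labels when matrices are plain.
#' @param params a [tree_params()] template (its seed field is ignored).
#' @param m number of candidate seeds (>= 1); `"auto"` uses
#'   [budget()] of the training size.
#' @param seed0 first candidate seed.
#' @param audit keep the full per-seed development accuracy trail.
#' @return A `brute_result` with `best_seed`, `best_model`, `dev_accuracy`,
#'   `m_trained`, and (optionally) `dev_accuracies`.
#' @export
brute_fit <- function(train, dev, y_train = NULL, y_dev = NULL,
                      params = tree_params(), m = "auto", seed0 = 0L,
                      audit = TRUE) {
  if (inherits(train, "feature_matrix")) {
    y_train <- train$labels; train <- train$values
  }
  if (inherits(dev, "feature_matrix")) {
    y_dev <- dev$labels; dev <- dev$values
  }
  train <- as.matrix(train); dev <- as.matrix(dev)
  if (nrow(dev) < 1L) {
    abort("development split must be non-empty",
          class = "eegseek_validation_error")
  }
  if (identical(m, "auto")) m <- budget(nrow(train))
  m <- as.integer(m)
  if (m < 1L) abort("m must be >= 1", class = "eegseek_validation_error")
  seed0 <- as.integer(seed0)

  best <- NULL; best_acc <- -Inf; best_seed <- NA_integer_
  trail <- if (audit) numeric(m) else NULL
  for (i in seq_len(m)) {
    p <- params
    p$seed <- seed0 + i - 1L
    tr <- fit_tree(train, y_train, p)
    acc <- accuracy(predict(tr, dev), y_dev)
    if (audit) trail[i] <- acc
    if (acc > best_acc) {            # strict: ties keep the smallest seed
      best_acc <- acc; best <- tr; best_seed <- p$seed
    }
  }
  structure(list(best_seed = best_seed, best_model = best,
                 dev_accuracy = best_acc, m_trained = m,
                 seed0 = seed0, dev_accuracies = trail),
            class = "brute_result")
}

#' @export
print.brute_result <- function(x, ...) {
  cat(sprintf(
    "<brute_result> best seed %d of %d candidates; dev accuracy %.3f\n",
    x$best_seed, x$m_trained, x$dev_accuracy))
  invisible(x)
}

#' @export
predict.brute_result <- function(object, newdata, ...) {
  predict(object$best_model, newdata, ...)
}

#' Tidy the per-seed audit trail of a seed search
#'
#' @param x a `brute_result` fitted with `audit = TRUE`.
#' @param ... unused.
#' @return A tibble with one row per candidate seed: `seed`,
#'   `dev_accuracy`, `selected`.
#' @exportS3Method generics::tidy
tidy.brute_result <- function(x, ...) {
  if (is.null(x$dev_accuracies)) {
    abort("no audit trail retained; refit with audit = TRUE",
          class = "eegseek_state_error")
  }
  tibble::tibble(
    seed = x$seed0 + seq_len(x$m_trained) - 1L,
    dev_accuracy = x$dev_accuracies,
    selected = x$seed0 + seq_len(x$m_trained) - 1L == x$best_seed)
}

#' One-row summary of a seed search
#'
#' @param x a `brute_result`.
#' @param ... unused.
#' @return A one-row tibble: `best_seed`, `dev_accuracy`, `m_trained`.
#' @exportS3Method generics::glance
glance.brute_result <- function(x, ...) {
  tibble::tibble(best_seed = x$best_seed, dev_accuracy = x$dev_accuracy,
                 m_trained = x$m_trained)
}
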