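#' Gini impurity of a class-count vector
#'
#' `1 - sum((c_k / n)^2)`: 0 for a pure node, at most `1 - 1/K` for `K`
#' classes.
#'
#' @param counts nonnegative class counts with positive sum.
#' @return Impurity in `[0, 1 - 1/K]`.
#' @export
gini <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0) {
    abort("counts must be nonnegative with positive sum",
          class = "eegseek_validation_error")
  }
  1 - sum((counts / sum(counts))^2)
}

#' Tree learner hyperparameters
#'
#' @param k_features candidate features per split; default `ceiling(sqrt(d))`
#'   at fit time when `NULL`.
#' @param min_samples_split minimum rows to attempt a split (>= 2).
#' @param max_depth optional depth cap; `NULL` = unlimited.
#' @param seed integer RNG seed; the fit is a pure function of data and
#'   parameters including this seed.
#' @return A `tree_params` list.
#' @export
tree_params <- function(k_features = NULL, min_samples_split = 2L,
                        max_depth = NULL, seed = 0L) {
  if (min_samples_split < 2L) {
    abort("min_samples_split must be >= 2",
          class = "eegseek_validation_error")
  }
  structure(list(k_features = k_features,
                 min_samples_split = as.integer(min_samples_split),
                 max_depth = max_depth, seed = as.integer(seed)),
            class = "tree_params")
}

#' Fit one extremely randomized tree
#'
#' Recursive construction with the extra-randomized split rule: at each
#' node, `k_features` distinct non-constant features are drawn uniformly,
#' one cut-point per candidate is drawn uniformly in that feature's open
#' (min, max) interval over the node's rows, candidates are scored by Gini
#' impurity decrease, and the best wins (ties keep the earliest draw).
#' Nodes become leaves when pure, smaller than `min_samples_split`, at the
#' depth cap, or when all features are constant.
#'
#' @param X numeric matrix `[n x d]` (or a `feature_matrix`).
#' @param y integer labels in 0..3 (ignored if `X` is a `feature_matrix`).
#' @param params a [tree_params()].
#' @param n_classes number of classes, default 4.
#' @return An `extra_tree` fitted tree.
#' @export
fit_tree <- function(X, y = NULL, params = tree_params(), n_classes = 4L) {
  if (inherits(X, "feature_matrix")) {
    y <- X$labels
    X <- X$values
  }
  X <- as.matrix(X)
  if (nrow(X) < 1L) {
    abort("empty training set", class = "eegseek_validation_error")
  }
  y <- as.integer(y)
  if (length(y) != nrow(X) || any(y < 0L) || any(y >= n_classes)) {
    abort(sprintf("labels must be integers in 0..%d, one per row",
                  n_classes - 1L),
          class = "eegseek_validation_error")
  }
  k <- params$k_features
  if (is.null(k)) k <- as.integer(ceiling(sqrt(ncol(X))))
  k <- max(1L, min(as.integer(k), ncol(X)))
  md <- if (is.null(params$max_depth)) -1L else as.integer(params$max_depth)
  fit <- .et_fit_cpp(X, y, as.integer(n_classes), k,
                     params$min_samples_split, md, params$seed)
  structure(c(fit, list(n_classes = as.integer(n_classes),
                        n_features = ncol(X), params = params)),
            class = "extra_tree")
}

#' @export
print.extra_tree <- function(x, ...) {
  cat(sprintf("<extra_tree> %d nodes (%d leaves), %d features, seed %d\n",
              length(x$feature), sum(x$feature < 0L), x$n_features,
              x$params$seed))
  invisible(x)
}

#' Predict class labels from a fitted tree
#'
#' Rows are routed left when feature value < threshold; the label is the
#' argmax of the leaf's class counts (ties to the lowest class index) and
#' probabilities are the normalized leaf counts.
#'
#' @param object an `extra_tree`.
#' @param newdata numeric matrix or `feature_matrix` of matching width.
#' @param type `"label"` (default) or `"prob"`.
#' @param ... unused.
#' @return Integer labels, or a probability matrix with rows summing to 1.
#' @export
predict.extra_tree <- function(object, newdata, type = c("label", "prob"),
                               ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    abort("feature width does not match the fitted tree",
          class = "eegseek_validation_error")
  }
  out <- .et_predict_cpp(object$feature, object$threshold, object$left,
                         object$right, object$counts, newdata)
  if (type == "label") as.integer(out$labels) else out$prob
}
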