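# Common spatial patterns: spatial filters maximizing the variance ratio
# between two trial classes via the generalized eigenproblem
# C_i w = lambda (C_i + C_j) w on trace-normalized class covariances.

trial_cov <- function(X) {
  C <- X %*% t(X)
  C / sum(diag(C))
}

class_cov <- function(ds, trials) {
  covs <- lapply(trials, function(t) trial_cov(ds$data[t, , ]))
  Reduce(`+`, covs) / length(covs)
}

# Symmetric solve of C_i w = lambda (C_i + C_j) w via whitening of the
# composite; eigenvalues fall in [0, 1]. Singular composites get one
# ridge-regularized retry (epsilon = 1e-9 * trace / n on the diagonal).
csp_eig <- function(Ci, Cj, ridge = 1e-9) {
  n <- nrow(Ci)
  Cc <- Ci + Cj
  solve_once <- function(Cc) {
    ec <- eigen(Cc, symmetric = TRUE)
    if (min(ec$values) < .Machine$double.eps * max(ec$values)) return(NULL)
    Wh <- ec$vectors %*% diag(1 / sqrt(ec$values), n) %*% t(ec$vectors)
    es <- eigen(Wh %*% Ci %*% Wh, symmetric = TRUE)
    list(eigenvalues = pmin(pmax(es$values, 0), 1),
         filters = Wh %*% es$vectors)
  }
  res <- solve_once(Cc)
  if (is.null(res)) {
    res <- solve_once(Cc + diag(ridge * sum(diag(Cc)) / n, n))
  }
  if (is.null(res)) {
    abort("composite covariance is singular even after ridge regularization",
          class = "eegseek_numeric_error")
  }
  res
}

new_filter_bank <- function(eig, contrast, n_keep) {
  structure(list(filters = eig$filters, eigenvalues = eig$eigenvalues,
                 contrast = contrast, n_keep = as.integer(n_keep)),
            class = "spatial_filter_bank")
}

#' @export
print.spatial_filter_bank <- function(x, ...) {
  cat(sprintf("<spatial_filter_bank> contrast %s; top eigenvalue %.3f; keep %d\n",
              paste(x$contrast, collapse = " vs "),
              x$eigenvalues[1], x$n_keep))
  invisible(x)
}

#' Fit common spatial pattern filter banks
#'
#' For `scheme = "pairwise"` fits one bank per unordered class pair (6
#' contrasts for 4 classes, fixed order (0,1),(0,2),(0,3),(1,2),(1,3),(2,3));
#' for `scheme = "one_vs_all"` one bank per class against the pooled rest
#' (4 contrasts). Per contrast, trial covariances `X X^T / trace` are
#' averaged per class and `C_i w = lambda (C_i + C_j) w` is solved; the
#' `n_keep` retained filters are taken half from each end of the descending
#' eigenvalue spectrum.
#'
#' @param train an `eeg_epochs` object (training trials only).
#' @param scheme `"pairwise"` or `"one_vs_all"`.
#' @param n_keep even number of filters retained per contrast.
#' @return List of `spatial_filter_bank` objects, one per contrast.
#' @export
csp_fit <- function(train, scheme = c("pairwise", "one_vs_all"),
                    n_keep = 4L) {
  validate_epochs(train)
  scheme <- match.arg(scheme)
  n_keep <- as.integer(n_keep)
  if (n_keep < 2L || n_keep %% 2L != 0L || n_keep > dim(train$data)[2]) {
    abort("n_keep must be an even number between 2 and n_channels",
          class = "eegseek_validation_error")
  }
  classes <- 0:3
  trials_of <- lapply(classes, function(c) which(train$labels == c))
  if (scheme == "pairwise") {
    pairs <- utils::combn(classes, 2, simplify = FALSE)
    lapply(pairs, function(p) {
      check_min_trials(trials_of[[p[1] + 1L]], p[1])
      check_min_trials(trials_of[[p[2] + 1L]], p[2])
      Ci <- class_cov(train, trials_of[[p[1] + 1L]])
      Cj <- class_cov(train, trials_of[[p[2] + 1L]])
      new_filter_bank(csp_eig(Ci, Cj), p, n_keep)
    })
  } else {
    lapply(classes, function(c) {
      rest <- which(train$labels != c)
      check_min_trials(trials_of[[c + 1L]], c)
      check_min_trials(rest, "rest")
      Ci <- class_cov(train, trials_of[[c + 1L]])
      Cj <- class_cov(train, rest)
      new_filter_bank(csp_eig(Ci, Cj), c, n_keep)
    })
  }
}

check_min_trials <- function(idx, what) {
  if (length(idx) < 2L) {
    abort(sprintf("need at least 2 trials for class contrast '%s'", what),
          class = "eegseek_validation_error")
  }
}

retained_filters <- function(bank) {
  n <- ncol(bank$filters)
  k <- bank$n_keep %/% 2L
  bank$filters[, c(seq_len(k), n - k + seq_len(k) - 0L), drop = FALSE]
}

#' Log-variance CSP features
#'
#' Projects every trial through the retained filters of each bank and emits
#' `log(var(w^T X))` per filter (population variance, floored at `1e-12`),
#' concatenated across contrasts in the banks' fixed order.
#'
#' @param ds an `eeg_epochs` object.
#' @param banks filter banks from [csp_fit()] (fitted on training data only).
#' @param provenance `"csp_pair"` or `"csp_ova"`.
#' @return A `feature_matrix`.
#' @export
csp_features <- function(ds, banks, provenance = "csp_pair") {
  validate_epochs(ds)
  floor_var <- 1e-12
  nt <- n_trials(ds)
  cols <- lapply(seq_along(banks), function(b) {
    W <- retained_filters(banks[[b]])
    out <- matrix(0, nt, ncol(W))
    for (t in seq_len(nt)) {
      P <- t(W) %*% ds$data[t, , ]
      v <- rowMeans(P^2) - rowMeans(P)^2
      out[t, ] <- log(pmax(v, floor_var))
    }
    colnames(out) <- sprintf("c%s_f%d",
                             paste(banks[[b]]$contrast, collapse = ""),
                             seq_len(ncol(W)))
    out
  })
  values <- do.call(cbind, cols)
  feature_matrix(values, ds$labels, ds$subjects, provenance,
                 colnames(values))
}
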