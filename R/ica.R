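# FastICA in channel space (logcosh contrast, symmetric decorrelation).
# All components are retained; the run is deterministic via a fixed
# internal seed for the orthonormal initialization.

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                     nrow(W)) %*% t(e$vectors) %*% W
}

#' Fit an ICA unmixing matrix on training trials
#'
#' Training trials are concatenated along time into one channels-by-time
#' matrix, centered per channel, whitened by the eigendecomposition of the
#' channel covariance, and unmixed by symmetric FastICA with the logcosh
#' nonlinearity. All components are kept. Non-convergence within `max_iter`
#' is flagged in the result (`converged = FALSE`); the last iterate is
#' still usable.
#'
#' @param train an `eeg_epochs` object (training trials only).
#' @param max_iter iteration cap, default 200.
#' @param tol convergence tolerance on the unmixing update, default 1e-6.
#' @return An `ica_unmixing` object with the channel-space unmixing matrix
#'   (`unmixing`, components x channels), channel means, and a convergence
#'   flag.
#' @export
ica_fit <- function(train, max_iter = 200L, tol = 1e-6) {
  validate_epochs(train)
  d <- dim(train$data)
  X <- matrix(aperm(train$data, c(2, 3, 1)), nrow = d[2])  # ch x time
  mu <- rowMeans(X)
  Xc <- X - mu
  N <- ncol(Xc)
  C <- Xc %*% t(Xc) / N
  ec <- eigen(C, symmetric = TRUE)
  K <- diag(1 / sqrt(pmax(ec$values, 1e-18)), d[2]) %*% t(ec$vectors)
  Z <- K %*% Xc

  W <- with_substream(8641L, "ica_init", {
    sym_decorrelate(matrix(rnorm(d[2] * d[2]), d[2], d[2]))
  })
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- (G %*% t(Z)) / N - diag(rowMeans(1 - G^2), d[2]) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(unmixing = W %*% K, center = mu,
                 converged = converged, iterations = iter,
                 n_channels = d[2]),
            class = "ica_unmixing")
}

#' Unmix epochs and summarize independent components
#'
#' Applies a fitted unmixing matrix to each trial and reduces every
#' component time series to its mean, standard deviation and energy (the
#' same statistics as the wavelet bands), or returns the raw unmixed time
#' series flattened when `summarize = FALSE`.
#'
#' @param fit an `ica_unmixing` from [ica_fit()].
#' @param ds an `eeg_epochs` object.
#' @param summarize emit summary statistics (default) or raw coefficients.
#' @return A `feature_matrix` with provenance `"ica"`; the convergence flag
#'   is carried as attribute `"ica_converged"`.
#' @export
ica_features <- function(fit, ds, summarize = TRUE) {
  if (!inherits(fit, "ica_unmixing")) {
    abort("ICA must be fitted before it is applied",
          class = "eegseek_state_error")
  }
  validate_epochs(ds)
  d <- dim(ds$data)
  if (d[2] != fit$n_channels) {
    abort("channel count does not match the fitted unmixing",
          class = "eegseek_validation_error")
  }
  nt <- d[1]
  rows <- lapply(seq_len(nt), function(t) {
    Y <- fit$unmixing %*% (ds$data[t, , ] - fit$center)
    if (summarize) {
      as.vector(t(cbind(rowMeans(Y), apply(Y, 1, sd), rowSums(Y^2))))
    } else as.vector(t(Y))
  })
  values <- do.call(rbind, rows)
  nm <- if (summarize) {
    as.vector(t(outer(sprintf("ic%02d", seq_len(d[2])),
                      c("mean", "sd", "energy"), paste, sep = "_")))
  } else sprintf("ic_%05d", seq_len(ncol(values)))
  fm <- feature_matrix(values, ds$labels, ds$subjects, "ica", nm)
  attr(fm, "ica_converged") <- fit$converged
  fm
}
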