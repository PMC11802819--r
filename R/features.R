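# The six feature pipelines: raw flattening, ICA, PCA, pairwise and
# one-vs-all CSP, CAR + DWT, and their concatenation. Every pipeline is
# split into a fit step (train rows only) and an apply step so nothing is
# ever estimated on development or test trials.

#' Common average reference
#'
#' Subtracts the instantaneous across-channel mean from every channel, per
#' trial and time sample, removing signal common to all sensors.
#'
#' @param ds an `eeg_epochs` object with at least 2 channels.
#' @return An `eeg_epochs` of identical shape whose across-channel mean is
#'   zero at every sample.
#' @export
car_reference <- function(ds) {
  validate_epochs(ds)
  if (dim(ds$data)[2] < 2L) {
    abort("common average reference requires at least 2 channels",
          class = "eegseek_validation_error")
  }
  m <- apply(ds$data, c(1, 3), mean)           # trials x samples
  out <- ds$data - aperm(
    array(m, dim = c(dim(ds$data)[1], dim(ds$data)[3], dim(ds$data)[2])),
    c(1, 3, 2))
  epoch_dataset(out, ds$labels, ds$subjects, ds$sfreq, ds$channel_names)
}

#' Flatten epochs to a raw feature matrix
#'
#' The "raw" pipeline: each trial's channels-by-samples block is flattened
#' row-wise (channel-major) into one feature row.
#'
#' @param ds an `eeg_epochs` object.
#' @return A `feature_matrix` with provenance `"raw"`.
#' @export
flatten_epochs <- function(ds) {
  validate_epochs(ds)
  d <- dim(ds$data)
  # column order: channel-major (all samples of channel 1, then channel 2 ...)
  values <- matrix(aperm(ds$data, c(1, 3, 2)), nrow = d[1])
  nm <- as.vector(t(outer(ds$channel_names, seq_len(d[3]),
                          function(ch, s) sprintf("%s_t%03d", ch, s))))
  feature_matrix(values, ds$labels, ds$subjects, "raw", nm)
}

# ---------------------------------------------------------------------------
# PCA (trial-flattened space, all components)

#' Fit a PCA projection on training features
#'
#' Principal components of the (centered, unscaled) training matrix, all
#' components retained, so the projection is a rotation: no dimensionality
#' is discarded and transformed training columns are uncorrelated.
#'
#' @param train a `feature_matrix` (typically provenance `"raw"`).
#' @return A `pca_projection` object.
#' @export
pca_fit <- function(train) {
  validate_feature_matrix(train)
  pc <- prcomp(train$values, center = TRUE, scale. = FALSE)
  structure(list(rotation = pc$rotation, center = pc$center,
                 n_features = ncol(train$values)),
            class = "pca_projection")
}

#' Apply a fitted PCA projection
#'
#' @param fit a `pca_projection` from [pca_fit()].
#' @param fm a `feature_matrix` with the same feature width.
#' @return A `feature_matrix` with provenance `"pca"`.
#' @export
pca_apply <- function(fit, fm) {
  if (!inherits(fit, "pca_projection")) {
    abort("PCA must be fitted before it is applied",
          class = "eegseek_state_error")
  }
  if (ncol(fm$values) != fit$n_features) {
    abort("feature width does not match the fitted projection",
          class = "eegseek_validation_error")
  }
  scores <- sweep(fm$values, 2, fit$center) %*% fit$rotation
  feature_matrix(scores, fm$labels, fm$subjects, "pca",
                 colnames(fit$rotation))
}

# ---------------------------------------------------------------------------
# Normalization (the fixed preprocessing step before every model)

#' Fit a per-feature z-score normalizer on training rows
#'
#' Location is the column mean, scale the population standard deviation.
#' Columns with scale below `tol` are flagged constant and map to zero.
#'
#' @param train a `feature_matrix`.
#' @param tol scale below which a feature counts as constant.
#' @return A `normalizer` object.
#' @export
normalize_fit <- function(train, tol = 1e-12) {
  validate_feature_matrix(train)
  mu <- colMeans(train$values)
  sigma <- sqrt(colMeans(sweep(train$values, 2, mu)^2))
  structure(list(mean = mu, sd = sigma, constant = sigma < tol,
                 n_features = ncol(train$values)),
            class = "normalizer")
}

#' Apply a fitted normalizer
#'
#' @param nz a `normalizer` from [normalize_fit()].
#' @param fm a `feature_matrix` of matching width.
#' @return A `feature_matrix` with z-scored columns (constant columns 0).
#' @export
normalize_apply <- function(nz, fm) {
  if (!inherits(nz, "normalizer")) {
    abort("normalizer must be fitted before it is applied",
          class = "eegseek_state_error")
  }
  if (ncol(fm$values) != nz$n_features) {
    abort("feature width does not match the fitted normalizer",
          class = "eegseek_validation_error")
  }
  sdv <- ifelse(nz$constant, 1, nz$sd)
  z <- sweep(sweep(fm$values, 2, nz$mean), 2, sdv, `/`)
  z[, nz$constant] <- 0
  feature_matrix(z, fm$labels, fm$subjects, fm$provenance, fm$feature_names)
}
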