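# Orthonormal discrete wavelet transform (periodized) for Daubechies
# filters. Analysis lowpass h in natural order; highpass g[m] = (-1)^m
# h[L-1-m]. With periodic wrapping and even length at each level the
# transform is orthogonal, so band energies sum to signal energy.

wavelet_filter <- function(wavelet = c("db4", "haar", "db1", "db2")) {
  wavelet <- match.arg(wavelet)
  h <- switch(wavelet,
    haar = ,
    db1 = c(1, 1) / sqrt(2),
    db2 = c(0.482962913144690, 0.836516303737469,
            0.224143868041857, -0.129409522550921),
    db4 = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997))
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  list(h = h, g = g)
}

# One periodized analysis step over the columns of X (each column one
# signal): returns approximation and detail coefficient matrices of
# ceiling(n/2) rows (odd n is padded by repeating the last sample, which
# sacrifices exact orthonormality for that level).
dwt_step <- function(X, filt) {
  n <- nrow(X)
  if (n %% 2L == 1L) {
    X <- rbind(X, X[n, , drop = FALSE])
    n <- n + 1L
  }
  L <- length(filt$h)
  rows <- seq(1L, n - 1L, by = 2L)
  A <- 0; D <- 0
  for (m in seq_len(L)) {
    shifted <- X[(rows + m - 2L) %% n + 1L, , drop = FALSE]
    A <- A + filt$h[m] * shifted
    D <- D + filt$g[m] * shifted
  }
  list(approx = A, detail = D)
}

# Multilevel decomposition of every column of X; list of coefficient
# matrices coarsest first.
dwt_decompose_mat <- function(X, wavelet, level) {
  filt <- wavelet_filter(wavelet)
  details <- vector("list", level)
  A <- X
  for (l in seq_len(level)) {
    st <- dwt_step(A, filt)
    details[[l]] <- st$detail
    A <- st$approx
  }
  out <- c(list(A), rev(details))
  names(out) <- c(sprintf("a%d", level), sprintf("d%d", level:1))
  out
}

#' Multilevel discrete wavelet decomposition
#'
#' Periodized orthonormal DWT of a single time series. Bands are returned
#' coarsest first: the level-`level` approximation, then details from level
#' `level` down to 1. For even dyadic lengths and these orthonormal filters
#' the band energies sum to the signal energy (Parseval).
#'
#' @param x numeric vector.
#' @param wavelet `"haar"`/`"db1"`, `"db2"` or `"db4"`.
#' @param level decomposition depth; requires `length(x) >= 2^level`.
#' @return Named list of coefficient vectors: `a<level>`, `d<level>`, ...,
#'   `d1`.
#' @export
dwt_decompose <- function(x, wavelet = "db4", level = 1L) {
  level <- as.integer(level)
  if (level < 1L || length(x) < 2^level) {
    abort("decomposition level too deep for the signal length",
          class = "eegseek_validation_error")
  }
  lapply(dwt_decompose_mat(matrix(x, ncol = 1L), wavelet, level), drop)
}

default_dwt_level <- function(n_samples) {
  max(1L, min(5L, as.integer(floor(log2(n_samples))) - 1L))
}

#' Wavelet-band summary features per trial and channel
#'
#' Decomposes every trial/channel time series with a multilevel DWT and
#' summarizes each band (approximation plus each detail level) by its mean,
#' standard deviation and energy (sum of squared coefficients), in the fixed
#' order channel-major, band coarsest-first, statistics (mean, sd, energy).
#' Raw-coefficient output is available via `summarize = FALSE`.
#'
#' @param ds an `eeg_epochs` object (typically after [car_reference()]).
#' @param wavelet wavelet name, default `"db4"`.
#' @param level decomposition depth; default
#'   `min(5, floor(log2(n_samples)) - 1)`.
#' @param summarize emit the three band statistics (default) or raw
#'   concatenated coefficients.
#' @param provenance provenance tag for the result, default `"car_dwt"`.
#' @return A `feature_matrix`.
#' @export
dwt_features <- function(ds, wavelet = "db4", level = NULL,
                         summarize = TRUE, provenance = "car_dwt") {
  validate_epochs(ds)
  ns <- dim(ds$data)[3]
  if (is.null(level)) level <- default_dwt_level(ns)
  if (ns < 2^level) {
    abort("decomposition level too deep for the epoch length",
          class = "eegseek_validation_error")
  }
  nch <- dim(ds$data)[2]
  nt <- n_trials(ds)
  band_names <- c(sprintf("a%d", level), sprintf("d%d", level:1))
  # one matrix decomposition over all trial/channel series at once;
  # columns ordered channel-fastest within trial
  sig <- matrix(aperm(ds$data, c(3, 2, 1)), nrow = ns)
  bands <- dwt_decompose_mat(sig, wavelet, level)
  per_band <- lapply(bands, function(B) {
    if (!summarize) return(B)
    n <- nrow(B)
    mu <- colMeans(B)
    en <- colSums(B^2)
    s <- if (n > 1L) sqrt(pmax(en - n * mu^2, 0) / (n - 1L)) else 0 * mu
    rbind(mu, s, en)
  })
  # assemble rows: trial-major; per channel, bands coarsest-first with the
  # three statistics (or raw coefficients) contiguous
  blocks <- do.call(rbind, per_band)       # (bands*stats) x (nch*nt)
  values <- matrix(0, nt, nch * nrow(blocks))
  for (ch in seq_len(nch)) {
    cols <- (seq_len(nt) - 1L) * nch + ch
    values[, (ch - 1L) * nrow(blocks) + seq_len(nrow(blocks))] <-
      t(blocks[, cols, drop = FALSE])
  }
  feature_names <- if (summarize) {
    as.vector(t(outer(ds$channel_names, band_names, function(ch, b) {
      paste(ch, b, sep = "_")
    }))) |>
      (\(cb) as.vector(t(outer(cb, c("mean", "sd", "energy"), paste,
                               sep = "_"))))()
  } else sprintf("dwtcoef_%04d", seq_len(ncol(values)))
  feature_matrix(values, ds$labels, ds$subjects, provenance, feature_names)
}
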