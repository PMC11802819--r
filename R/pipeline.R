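# Pipeline dispatcher: fits each feature extractor on training trials only
# and applies it to train, dev and test, so the bench loop cannot leak.

#' Feature pipeline names
#' @return Character vector of the seven method names.
#' @export
pipeline_methods <- function() {
  c("raw", "ica", "pca", "csp_pair", "csp_ova", "car_dwt", "all")
}

#' Run one feature pipeline over a split
#'
#' Fits the pipeline's trainable parts (PCA rotation, ICA unmixing, CSP
#' filter banks) on the training trials only, then produces feature
#' matrices for train, development and test. `"car_dwt"` and `"raw"` are
#' stateless per-trial maps. `"all"` concatenates the six other pipelines
#' column-wise in fixed order.
#'
#' @param ds an `eeg_epochs` object.
#' @param method one of [pipeline_methods()].
#' @param split a `split_spec`.
#' @param n_keep CSP filters retained per contrast.
#' @param wavelet,level DWT settings (see [dwt_features()]).
#' @return List with `train`, `dev`, `test` (feature matrices) and `fits`
#'   (the fitted transformers, for audit).
#' @export
featurize_split <- function(ds, method, split, n_keep = 4L,
                            wavelet = "db4", level = NULL) {
  method <- match.arg(method, pipeline_methods())
  parts <- list(train = subset_trials(ds, split$train),
                dev = subset_trials(ds, split$dev),
                test = subset_trials(ds, split$test))
  fits <- list()
  out <- switch(
    method,
    raw = lapply(parts, flatten_epochs),
    pca = {
      flat <- lapply(parts, flatten_epochs)
      fits$pca <- pca_fit(flat$train)
      lapply(flat, function(fm) pca_apply(fits$pca, fm))
    },
    ica = {
      fits$ica <- ica_fit(parts$train)
      lapply(parts, function(p) ica_features(fits$ica, p))
    },
    csp_pair = {
      fits$csp <- csp_fit(parts$train, "pairwise", n_keep)
      lapply(parts, function(p) csp_features(p, fits$csp, "csp_pair"))
    },
    csp_ova = {
      fits$csp <- csp_fit(parts$train, "one_vs_all", n_keep)
      lapply(parts, function(p) csp_features(p, fits$csp, "csp_ova"))
    },
    car_dwt = lapply(parts, function(p) {
      dwt_features(car_reference(p), wavelet = wavelet, level = level)
    }),
    all = {
      sub <- lapply(setdiff(pipeline_methods(), "all"), function(m) {
        featurize_split(ds, m, split, n_keep = n_keep, wavelet = wavelet,
                        level = level)
      })
      names(sub) <- setdiff(pipeline_methods(), "all")
      fits <- lapply(sub, `[[`, "fits")
      list(train = concat_features(lapply(sub, function(s) s$train)),
           dev = concat_features(lapply(sub, function(s) s$dev)),
           test = concat_features(lapply(sub, function(s) s$test)))
    })
  list(train = out$train, dev = out$dev, test = out$test, fits = fits)
}
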