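make_epochs <- function(trials, labels = NULL, subjects = NULL, sfreq = 8) {
  data <- array(0, dim = c(length(trials), nrow(trials[[1]]),
                           ncol(trials[[1]])))
  for (i in seq_along(trials)) data[i, , ] <- trials[[i]]
  epoch_dataset(data,
                labels %||% rep(0L, length(trials)),
                subjects %||% rep(1L, length(trials)), sfreq)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("common average reference removes the across-channel mean", {
  # hand-computed 2x2 example: per-sample channel means are 2 and 4
  ds <- make_epochs(list(rbind(c(1, 3), c(3, 5))))
  out <- car_reference(ds)
  expect_equal(out$data[1, , ], rbind(c(-1, -1), c(1, 1)))

  # equal channels cancel completely; zero-mean input is a fixed point
  eq <- make_epochs(list(rbind(c(2, 7), c(2, 7))))
  expect_true(all(car_reference(eq)$data == 0))
  expect_equal(car_reference(out)$data, out$data)

  # channel mean is ~0 at every sample of a generated dataset
  g <- car_reference(generate_epochs(small_cfg()))
  expect_lt(max(abs(apply(g$data, c(1, 3), mean))), 1e-12)

  one <- make_epochs(list(matrix(1:4, nrow = 1)))
  expect_error(car_reference(one), class = "eegseek_validation_error")
})

test_that("Haar level-1 analysis matches the hand-computed example", {
  d <- dwt_decompose(c(1, 2, 3, 4), "haar", 1L)
  expect_equal(d$a1, c(2.1213, 4.9497), tolerance = 1e-4)
  expect_equal(d$d1, c(-0.7071, -0.7071), tolerance = 1e-4)
  expect_equal(sum(d$d1^2), 1.0, tolerance = 1e-10)

  flat <- dwt_decompose(c(1, 1, 1, 1), "haar", 1L)
  expect_equal(flat$d1, c(0, 0))
})

test_that("band energies conserve signal energy for orthonormal wavelets", {
  set.seed(77)
  for (wavelet in c("haar", "db2", "db4")) {
    for (n in c(32L, 64L, 256L)) {
      x <- rnorm(n)
      bands <- dwt_decompose(x, wavelet, 3L)
      expect_equal(sum(vapply(bands, function(b) sum(b^2), numeric(1))),
                   sum(x^2), tolerance = 1e-8)
    }
  }
  expect_error(dwt_decompose(rnorm(8), "haar", 4L),
               class = "eegseek_validation_error")
})

test_that("wavelet features emit mean/sd/energy per band in fixed order", {
  ds <- generate_epochs(small_cfg())
  fm <- dwt_features(ds, wavelet = "haar", level = 2L)
  nch <- dim(ds$data)[2]
  expect_equal(ncol(fm$values), nch * 3L * 3L)    # 3 bands x 3 stats
  expect_identical(fm$provenance, "car_dwt")
  # spot-check the first channel's coarse band statistics on trial 1
  bands <- dwt_decompose(ds$data[1, 1, ], "haar", 2L)
  expect_equal(fm$values[1, 1:3],
               c(mean(bands$a2), sd(bands$a2), sum(bands$a2^2)),
               ignore_attr = TRUE)
  expect_error(dwt_features(ds, level = 10L),
               class = "eegseek_validation_error")
})

test_that("PCA keeps all components and reproduces the 2-D eigenvalue example", {
  # 4-point cloud with sample covariance exactly [[2,1],[1,2]]
  Z <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1)) * sqrt(3) / 2
  X <- Z %*% chol(matrix(c(2, 1, 1, 2), 2))
  fm <- feature_matrix(X, rep(0:1, 2), rep(1L, 4), "raw")
  fit <- pca_fit(fm)
  scores <- pca_apply(fit, fm)
  expect_equal(apply(scores$values, 2, var), c(3, 1), ignore_attr = TRUE)
  # orthogonal invariance: total variance preserved, columns uncorrelated
  expect_equal(sum(apply(scores$values, 2, var)), sum(apply(X, 2, var)))
  expect_lt(abs(cov(scores$values)[1, 2]), 1e-12)
  expect_identical(scores$provenance, "pca")
  expect_equal(ncol(scores$values), ncol(X))

  expect_error(pca_apply(list(), fm), class = "eegseek_state_error")
  wide <- feature_matrix(cbind(X, X), rep(0:1, 2), rep(1L, 4), "raw")
  expect_error(pca_apply(fit, wide), class = "eegseek_validation_error")
})

test_that("ICA recovers planted independent sources", {
  cfg <- small_cfg(n_channels = 4L, subject_variability = 0, snr = 1e6,
                   n_subjects = 1L, seed = 3L)
  ds <- generate_epochs(cfg, keep_sources = TRUE)
  fit <- ica_fit(ds)
  expect_true(fit$converged)
  S <- attr(ds, "sources")
  # each recovered component matches one distinct true source
  Y <- fit$unmixing %*% (ds$data[1, , ] - fit$center)
  cc <- abs(cor(t(Y), t(S[1, , ])))
  expect_true(all(apply(cc, 1, max) > 0.9))
  expect_equal(anyDuplicated(apply(cc, 1, which.max)), 0L)

  # determinism: the internal seed is fixed
  fit2 <- ica_fit(ds)
  expect_identical(fit$unmixing, fit2$unmixing)

  fm <- ica_features(fit, ds)
  expect_identical(fm$provenance, "ica")
  expect_equal(ncol(fm$values), 4L * 3L)
  expect_true(attr(fm, "ica_converged"))
})

test_that("an ICA run stopped at the iteration cap is flagged, not fatal", {
  ds <- generate_epochs(small_cfg(n_channels = 4L, seed = 8L))
  fit <- ica_fit(ds, max_iter = 1L)
  expect_false(fit$converged)
  fm <- ica_features(fit, ds)
  expect_false(attr(fm, "ica_converged"))
  expect_true(all(is.finite(fm$values)))
})

test_that("normalization matches the worked z-score example and guards constants", {
  fm <- feature_matrix(cbind(c(2, 4, 6), c(5, 5, 5)), c(0L, 1L, 2L),
                       rep(1L, 3), "raw")
  nz <- normalize_fit(fm)
  out <- normalize_apply(nz, fm)
  expect_equal(out$values[, 1], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(out$values[, 2], c(0, 0, 0))
  expect_true(nz$constant[2])

  # re-application reproduces the fitted moments on the training rows
  mu <- colMeans(out$values)
  expect_equal(mu, c(0, 0), ignore_attr = TRUE)
  expect_equal(sqrt(mean((out$values[, 1] - mu[1])^2)), 1)

  wide <- feature_matrix(cbind(fm$values, 1:3), fm$labels, fm$subjects, "raw")
  expect_error(normalize_apply(nz, wide), class = "eegseek_validation_error")
})

test_that("the combined pipeline concatenates widths and rows in fixed order", {
  ds <- generate_epochs(small_cfg())
  sp <- split_subject_dependent(ds, 1L, seed = 2L)
  fs <- featurize_split(ds, "all", sp)
  parts <- lapply(setdiff(pipeline_methods(), "all"), function(m) {
    featurize_split(ds, m, sp)$train
  })
  expect_equal(ncol(fs$train$values),
               sum(vapply(parts, function(p) ncol(p$values), integer(1))))
  expect_equal(fs$train$values[1, ],
               unlist(lapply(parts, function(p) p$values[1, ])),
               ignore_attr = TRUE)
  expect_identical(fs$train$provenance, "all")
  # provenance prefixes appear in declared order
  prefixes <- unique(sub("\\..*$", "", fs$train$feature_names))
  expect_identical(prefixes, setdiff(pipeline_methods(), "all"))

  empty <- feature_matrix(matrix(numeric(0), 0, 2), integer(0), integer(0),
                          "raw")
  expect_error(concat_features(list(parts[[1]], empty)),
               class = "eegseek_validation_error")
})
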