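# Multi-subject synthetic EEG with planted class structure. The generative
# model is fixed and documented: a shared random mixing matrix perturbed per
# subject, per-class source-variance profiles, band-limited source noise,
# and sensor noise at a configurable SNR.

#' Configuration for the synthetic EEG generator
#'
#' Defaults emulate the inner-speech recording regime this package targets:
#' 10 subjects, four classes, 45-60 trials per class per subject.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_channels number of sensors (>= 2).
#' @param sfreq sampling rate in Hz.
#' @param epoch_seconds epoch duration in seconds.
#' @param trials_per_class_range inclusive integer range for the per-subject,
#'   per-class trial count, drawn uniformly and independently per cell.
#' @param n_sources number of latent sources; defaults to `n_channels`.
#' @param class_power_contrast variance multiplier (>= 1) applied to each
#'   class's designated source subset; 1 means no class signal at all.
#' @param subject_variability standard deviation of the per-subject
#'   perturbation added to the shared mixing matrix (0 = identical subjects).
#' @param snr ratio of mean signal power to mean sensor-noise power (> 0).
#' @param seed master RNG seed; the generator is a pure function of the
#'   whole configuration including this seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 10L, n_channels = 16L, sfreq = 256,
                         epoch_seconds = 1.0,
                         trials_per_class_range = c(45L, 60L),
                         n_sources = n_channels,
                         class_power_contrast = 3.0,
                         subject_variability = 0.3,
                         snr = 2.0, seed = 1L) {
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects),
         n_channels = as.integer(n_channels),
         sfreq = as.numeric(sfreq),
         epoch_seconds = as.numeric(epoch_seconds),
         trials_per_class_range = as.integer(trials_per_class_range),
         n_sources = as.integer(n_sources),
         class_power_contrast = as.numeric(class_power_contrast),
         subject_variability = as.numeric(subject_variability),
         snr = as.numeric(snr),
         seed = as.integer(seed)),
    class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  bad <- function(msg) abort(msg, class = "eegseek_validation_error")
  if (cfg$n_subjects < 1L) bad("n_subjects must be >= 1")
  if (cfg$n_channels < 2L) bad("n_channels must be >= 2")
  if (cfg$sfreq <= 0) bad("sfreq must be positive")
  if (cfg$epoch_seconds <= 0) bad("epoch_seconds must be positive")
  r <- cfg$trials_per_class_range
  if (length(r) != 2L || r[1] > r[2] || r[1] < 1L) {
    bad("trials_per_class_range must be an inclusive range [low, high], low >= 1")
  }
  if (cfg$n_sources < 1L) bad("n_sources must be >= 1")
  if (cfg$class_power_contrast < 1) bad("class_power_contrast must be >= 1")
  if (cfg$subject_variability < 0) bad("subject_variability must be >= 0")
  if (cfg$snr <= 0) bad("snr must be positive")
  invisible(cfg)
}

# Deterministic substream seed: master seed combined with a name hash so the
# counts / mixing / sources / noise draws come from independent streams and
# changing one phase's consumption does not shift the others.
substream_seed <- function(master, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1987654321
  as.integer((as.numeric(master) * 2654435761 + h) %% 2147483647)
}

with_substream <- function(master, name, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master, name))
  force(code)
}

# Source subset designated to each class code 0..3: consecutive blocks of
# size max(1, n_sources %/% 4); blocks are disjoint whenever n_sources >= 4.
class_source_sets <- function(n_sources) {
  s <- max(1L, n_sources %/% 4L)
  lapply(0:3, function(c) ((c * s + seq_len(s) - 1L) %% n_sources) + 1L)
}

# Shared derivation of the planted quantities (counts, mixing matrices,
# class variance profiles) so generate_epochs and planted_truth agree.
synth_plan <- function(cfg) {
  validate_synth_config(cfg)
  r <- cfg$trials_per_class_range
  counts <- with_substream(cfg$seed, "counts", {
    pool <- seq.int(r[1], r[2])            # sample via indices: a length-1
    draw <- pool[sample.int(length(pool),  # pool must stay a fixed value
                            cfg$n_subjects * 4L, replace = TRUE)]
    matrix(draw, nrow = cfg$n_subjects, ncol = 4L)
  })
  mix <- with_substream(cfg$seed, "mixing", {
    A0 <- matrix(rnorm(cfg$n_channels * cfg$n_sources),
                 cfg$n_channels, cfg$n_sources)
    A <- lapply(seq_len(cfg$n_subjects), function(j) {
      A0 + cfg$subject_variability *
        matrix(rnorm(cfg$n_channels * cfg$n_sources),
               cfg$n_channels, cfg$n_sources)
    })
    list(A0 = A0, A = A)
  })
  sets <- class_source_sets(cfg$n_sources)
  v <- matrix(1.0, nrow = 4L, ncol = cfg$n_sources)
  for (c in 1:4) v[c, sets[[c]]] <- cfg$class_power_contrast
  list(counts = counts, A0 = mix$A0, A = mix$A, v = v, class_sources = sets)
}

#' Planted ground truth of the synthetic generator
#'
#' Returns exactly the per-class source-variance profiles and per-subject
#' mixing matrices that [generate_epochs()] uses for the same configuration,
#' for recovery tests against known structure.
#'
#' @param cfg a `synth_config`.
#' @return A list with `v` (4 x n_sources variance matrix, rows = class
#'   codes 0..3), `A` (list of per-subject mixing matrices), `A0` (shared
#'   base mixing matrix), `class_sources` (per-class source index sets) and
#'   `counts` (subjects x 4 trial-count matrix).
#' @export
planted_truth <- function(cfg) {
  synth_plan(cfg)
}

#' Generate a synthetic multi-subject epoch dataset
#'
#' Fixed generative model: (i) a base mixing matrix `A0` (channels x
#' sources) with standard-normal entries; (ii) per subject j a perturbed
#' copy `A_j = A0 + subject_variability * E_j`; (iii) per class a source
#' variance profile equal to `class_power_contrast` on that class's source
#' subset and 1 elsewhere; (iv) per trial, sources are white noise
#' band-limited to 1-40 Hz (4th-order Butterworth, zero-phase), scaled by
#' the square root of the class profile, mixed through `A_j`, plus white
#' sensor noise scaled so that mean signal power / mean noise power equals
#' `snr` per trial. Bit-identical output for identical configurations.
#'
#' @param cfg a `synth_config`.
#' @param keep_sources if `TRUE`, attach the per-trial source time series as
#'   attribute `"sources"` (for recovery tests).
#' @return An `eeg_epochs` dataset; trials ordered by subject, then class,
#'   then repetition.
#' @export
generate_epochs <- function(cfg, keep_sources = FALSE) {
  plan <- synth_plan(cfg)
  n_samples <- as.integer(round(cfg$sfreq * cfg$epoch_seconds))
  stopifnot(n_samples >= 8L)
  total <- sum(plan$counts)

  labels <- integer(total); subjects <- integer(total)
  t0 <- 0L
  for (j in seq_len(cfg$n_subjects)) {
    for (c in 1:4) {
      k <- plan$counts[j, c]
      labels[t0 + seq_len(k)] <- c - 1L
      subjects[t0 + seq_len(k)] <- j
      t0 <- t0 + k
    }
  }

  # 1-40 Hz band-limit; if sfreq is too low for the 40 Hz edge, high-pass at
  # 1 Hz only. Zero-phase via forward-backward matrix filter.
  ny <- cfg$sfreq / 2
  bl <- if (ny > 41) signal::butter(4, c(1, 40) / ny, type = "pass")
        else signal::butter(4, 1 / ny, type = "high")

  src_white <- with_substream(cfg$seed, "sources", {
    matrix(rnorm(n_samples * cfg$n_sources * total), nrow = n_samples)
  })
  src <- .filtfilt_mat_cpp(as.numeric(bl$b), as.numeric(bl$a), src_white)
  sens_noise <- with_substream(cfg$seed, "noise", {
    matrix(rnorm(total * cfg$n_channels * n_samples),
           nrow = cfg$n_channels)
  })

  data <- array(0, dim = c(total, cfg$n_channels, n_samples))
  sources_out <- if (keep_sources) {
    array(0, dim = c(total, cfg$n_sources, n_samples))
  } else NULL
  sqrtv <- sqrt(plan$v)
  for (t in seq_len(total)) {
    cols <- (t - 1L) * cfg$n_sources + seq_len(cfg$n_sources)
    S <- t(src[, cols, drop = FALSE]) * sqrtv[labels[t] + 1L, ]
    sig <- plan$A[[subjects[t]]] %*% S
    ps <- mean(sig^2)
    nz <- sens_noise[, (t - 1L) * n_samples + seq_len(n_samples),
                     drop = FALSE] * sqrt(ps / cfg$snr)
    data[t, , ] <- sig + nz
    if (keep_sources) sources_out[t, , ] <- S
  }
  ds <- epoch_dataset(data, labels, subjects, cfg$sfreq)
  if (keep_sources) attr(ds, "sources") <- sources_out
  ds
}
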