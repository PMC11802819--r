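#' Fixed four-class inner-speech label mapping
#'
#' Class codes are fixed integers 0..3 mapped to the Spanish direction words
#' of the inner-speech paradigm. The Spanish words are authoritative; no
#' English gloss is stored.
#'
#' @return Named integer vector mapping word to code.
#' @export
#' @examples
#' inner_speech_classes()
inner_speech_classes <- function() {
  c(arriba = 0L, abajo = 1L, derecha = 2L, izquierda = 3L)
}

#' Construct an epoched EEG dataset
#'
#' The canonical in-memory container for epoched multichannel EEG: a 3-D
#' numeric array with trials first, per-trial class labels (integer codes
#' 0..3, see [inner_speech_classes()]) and subject identifiers, the sampling
#' rate, and channel names.
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]`.
#' @param labels integer vector, one label in 0..3 per trial.
#' @param subjects integer vector, one subject id (>= 1) per trial.
#' @param sfreq sampling rate in Hz, > 0.
#' @param channel_names character vector of length `n_channels`; defaults to
#'   `ch01`, `ch02`, ...
#' @return An object of class `eeg_epochs`.
#' @export
epoch_dataset <- function(data, labels, subjects, sfreq,
                          channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array [trials x channels x samples]",
          class = "eegseek_validation_error")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(dim(data)[2]))
  }
  ds <- structure(
    list(data = data,
         labels = as.integer(labels),
         subjects = as.integer(subjects),
         sfreq = as.numeric(sfreq),
         channel_names = as.character(channel_names)),
    class = "eeg_epochs")
  validate_epochs(ds)
  ds
}

#' Validate an epoched dataset
#'
#' Checks the container invariants: finite data, matching lengths, labels in
#' 0..3, positive sampling rate, unique channel names. Errors name the
#' offending field.
#'
#' @param ds an `eeg_epochs` object.
#' @return `ds`, invisibly.
#' @export
validate_epochs <- function(ds) {
  d <- dim(ds$data)
  if (length(d) != 3L) {
    abort("data: must have 3 dimensions", class = "eegseek_validation_error")
  }
  if (!all(is.finite(ds$data))) {
    abort("data: contains non-finite values",
          class = "eegseek_validation_error")
  }
  if (length(ds$labels) != d[1] || length(ds$subjects) != d[1]) {
    abort("labels/subjects: length must equal the number of trials",
          class = "eegseek_validation_error")
  }
  if (anyNA(ds$labels) || !all(ds$labels %in% 0:3)) {
    abort("labels: every label must be an integer in {0,1,2,3}",
          class = "eegseek_validation_error")
  }
  if (anyNA(ds$subjects) || any(ds$subjects < 1L)) {
    abort("subjects: subject ids must be integers >= 1",
          class = "eegseek_validation_error")
  }
  if (length(ds$sfreq) != 1L || !is.finite(ds$sfreq) || ds$sfreq <= 0) {
    abort("sfreq: sampling rate must be a single positive number",
          class = "eegseek_validation_error")
  }
  if (length(ds$channel_names) != d[2]) {
    abort("channel_names: length must equal the number of channels",
          class = "eegseek_validation_error")
  }
  if (anyDuplicated(ds$channel_names)) {
    abort("channel_names: must be unique",
          class = "eegseek_validation_error")
  }
  invisible(ds)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  cat(sprintf("  subjects: %s\n",
              paste(sort(unique(x$subjects)), collapse = ", ")))
  cat(sprintf("  class codes: %s\n",
              paste(sort(unique(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Number of trials in a dataset
#' @param ds an `eeg_epochs` object.
#' @return Integer trial count.
#' @export
n_trials <- function(ds) dim(ds$data)[1]

#' Subset trials of a dataset
#'
#' @param ds an `eeg_epochs` object.
#' @param idx integer trial indices (1-based).
#' @return An `eeg_epochs` with the selected trials, order preserved.
#' @export
subset_trials <- function(ds, idx) {
  idx <- as.integer(idx)
  if (length(idx) == 0L || any(idx < 1L) || any(idx > n_trials(ds))) {
    abort("trial indices out of range", class = "eegseek_validation_error")
  }
  epoch_dataset(ds$data[idx, , , drop = FALSE], ds$labels[idx],
                ds$subjects[idx], ds$sfreq, ds$channel_names)
}

#' Per-subject, per-class trial counts
#'
#' Tabulates trials by (subject, label) over the full cross of subjects and
#' the four class codes, so a class absent for a subject appears with count
#' zero. Counts always sum to the number of trials.
#'
#' @param ds an `eeg_epochs` object.
#' @return A tibble with columns `subject`, `label`, `count`, sorted by
#'   subject then label.
#' @export
class_counts <- function(ds) {
  validate_epochs(ds)
  grid <- expand.grid(label = 0:3,
                      subject = sort(unique(ds$subjects)),
                      KEEP.OUT.ATTRS = FALSE)
  tab <- table(factor(ds$subjects, levels = sort(unique(ds$subjects))),
               factor(ds$labels, levels = 0:3))
  tibble::tibble(
    subject = as.integer(grid$subject),
    label = as.integer(grid$label),
    count = as.integer(tab[cbind(as.character(grid$subject),
                                 as.character(grid$label))])
  ) |> dplyr::arrange(.data$subject, .data$label)
}

#' Write per-subject class counts to CSV
#'
#' @param ds an `eeg_epochs` object.
#' @param path output CSV path (columns `subject,label,count`).
#' @return `path`, invisibly.
#' @export
write_class_counts <- function(ds, path) {
  write.csv(as.data.frame(class_counts(ds)), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
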