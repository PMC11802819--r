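# Leakage-free splitting protocols. Subject-dependent: stratified
# train/dev/test within one subject's trials. Subject-independent: test
# subjects are entirely absent from train and dev.

new_split_spec <- function(train, dev, test, mode, detail, seed) {
  sp <- structure(list(train = as.integer(train), dev = as.integer(dev),
                       test = as.integer(test), mode = mode,
                       detail = detail, seed = as.integer(seed)),
                  class = "split_spec")
  if (anyDuplicated(c(sp$train, sp$dev, sp$test))) {
    abort("train/dev/test indices must be pairwise disjoint",
          class = "eegseek_validation_error")
  }
  sp
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %s: %d train / %d dev / %d test trials\n",
              x$mode, length(x$train), length(x$dev), length(x$test)))
  invisible(x)
}

stratified_take <- function(labels, idx, frac) {
  take <- integer(0)
  for (c in sort(unique(labels[idx]))) {
    pool <- idx[labels[idx] == c]
    k <- as.integer(round(frac * length(pool)))
    take <- c(take, pool[seq_len(k)])
  }
  take
}

#' Subject-dependent stratified split
#'
#' Restricts to one subject's trials and splits them into test
#' (`test_frac`, stratified per class so train and test class proportions
#' agree within one trial), development (`dev_frac` of the remaining
#' training trials, stratified), and train. Deterministic in all arguments.
#'
#' @param ds an `eeg_epochs` object.
#' @param subject subject id present in `ds` with >= 2 trials per class.
#' @param test_frac fraction of the subject's trials per class for test.
#' @param dev_frac fraction of the remaining training trials for the
#'   development split.
#' @param seed protocol seed.
#' @return A `split_spec`.
#' @export
split_subject_dependent <- function(ds, subject, test_frac = 0.2,
                                    dev_frac = 0.2, seed = 1L) {
  validate_epochs(ds)
  idx <- which(ds$subjects == subject)
  if (length(idx) == 0L) {
    abort(sprintf("subject %s not present", subject),
          class = "eegseek_validation_error")
  }
  counts <- table(factor(ds$labels[idx], levels = 0:3))
  if (any(counts < 2L)) {
    abort("every class needs at least 2 trials for this subject",
          class = "eegseek_validation_error")
  }
  idx <- with_substream(seed, "split_sd", sample(idx))
  test <- stratified_take(ds$labels, idx, test_frac)
  rest <- setdiff(idx, test)
  dev <- stratified_take(ds$labels, rest, dev_frac)
  train <- setdiff(rest, dev)
  new_split_spec(train, dev, test, "subject_dependent",
                 list(subject = subject, test_frac = test_frac,
                      dev_frac = dev_frac), seed)
}

#' Subject-independent split
#'
#' Test = every trial of the held-out subjects; no test subject appears in
#' train or dev. The development split is a stratified fraction of the
#' remaining (training-subject) trials.
#'
#' @param ds an `eeg_epochs` object.
#' @param test_subjects nonempty proper subset of the subject ids.
#' @param dev_frac fraction of training-subject trials for the development
#'   split, stratified by class.
#' @param seed protocol seed.
#' @return A `split_spec`.
#' @export
split_subject_independent <- function(ds, test_subjects, dev_frac = 0.2,
                                      seed = 1L) {
  validate_epochs(ds)
  all_subj <- sort(unique(ds$subjects))
  test_subjects <- unique(as.integer(test_subjects))
  if (length(test_subjects) == 0L || !all(test_subjects %in% all_subj)) {
    abort("test_subjects must be a nonempty subset of the dataset's subjects",
          class = "eegseek_validation_error")
  }
  if (length(setdiff(all_subj, test_subjects)) == 0L) {
    abort("test_subjects must leave at least one training subject",
          class = "eegseek_validation_error")
  }
  test <- which(ds$subjects %in% test_subjects)
  rest <- which(!ds$subjects %in% test_subjects)
  rest <- with_substream(seed, "split_si", sample(rest))
  dev <- stratified_take(ds$labels, rest, dev_frac)
  train <- setdiff(rest, dev)
  new_split_spec(train, dev, test, "subject_independent",
                 list(test_subjects = test_subjects, dev_frac = dev_frac),
                 seed)
}

#' Classification accuracy
#'
#' Fraction of predictions equal to the truth.
#'
#' @param pred,truth equal-length label vectors.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 1L) {
    abort("pred and truth must have equal positive length",
          class = "eegseek_validation_error")
  }
  mean(pred == truth)
}

#' Write a split to JSON
#'
#' @param split a `split_spec`.
#' @param path output path. Indices are recorded 1-based
#'   (`"index_base": 1`).
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(mode = split$mode, index_base = 1L, seed = split$seed,
         detail = split$detail, train = split$train, dev = split$dev,
         test = split$test),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a split written by [write_split()]
#' @param path JSON path.
#' @return A `split_spec`.
#' @export
read_split <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  off <- if (!is.null(s$index_base)) 1L - as.integer(s$index_base) else 0L
  new_split_spec(s$train + off, s$dev + off, s$test + off, s$mode,
                 as.list(s$detail), s$seed)
}
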