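#' Save an epoched dataset to an HDF5 container
#'
#' One portable HDF5 file with datasets `/data` (trials x channels x
#' samples), `/labels`, `/subjects`, and root attributes `sfreq` and
#' `channel_names`. [load_epochs()] reads the same layout back
#' field-identically at stored precision.
#'
#' @param ds a valid `eeg_epochs` object.
#' @param path output file path; overwritten if present.
#' @return `path`, invisibly.
#' @export
save_epochs <- function(ds, path) {
  validate_epochs(ds)
  if (file.exists(path)) file.remove(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (isFALSE(ok)) {
    abort(sprintf("cannot create file '%s'", path), class = "eegseek_io_error")
  }
  rhdf5::h5write(ds$data, path, "data")
  rhdf5::h5write(ds$labels, path, "labels")
  rhdf5::h5write(ds$subjects, path, "subjects")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(ds$sfreq, fid, "sfreq")
  rhdf5::h5writeAttribute(ds$channel_names, fid, "channel_names")
  invisible(path)
}

#' Load an epoched dataset from an HDF5 container
#'
#' Reads the layout written by [save_epochs()] and validates all container
#' invariants (including the fixed 0..3 label codes).
#'
#' @param path path to an HDF5 epoch container.
#' @return An `eeg_epochs` object.
#' @export
load_epochs <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: '%s'", path), class = "eegseek_io_error")
  }
  have <- rhdf5::h5ls(path)$name
  for (field in c("data", "labels", "subjects")) {
    if (!field %in% have) {
      abort(sprintf("container missing dataset '%s'", field),
            class = "eegseek_format_error")
    }
  }
  fid <- rhdf5::H5Fopen(path)
  attrs <- tryCatch(rhdf5::h5readAttributes(fid, "/"),
                    finally = rhdf5::H5Fclose(fid))
  if (is.null(attrs$sfreq)) {
    abort("container missing attribute 'sfreq'",
          class = "eegseek_format_error")
  }
  data <- rhdf5::h5read(path, "data")
  channel_names <- attrs$channel_names
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(dim(data)[2]))
  }
  epoch_dataset(data,
                as.integer(rhdf5::h5read(path, "labels")),
                as.integer(rhdf5::h5read(path, "subjects")),
                as.numeric(attrs$sfreq),
                as.character(channel_names))
}
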