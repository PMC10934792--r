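#' Epoched multichannel EEG trials
#'
#' An `epoch_set` is the universal data container of the package: a set of
#' fixed-length trials recorded on the same channels, each labelled with an
#' integer class, together with the sampling metadata needed to interpret the
#' sample axis in seconds.
#'
#' @param data numeric 3-d array, dimensions `[trial, channel, sample]`, in
#'   microvolts. All values must be finite.
#' @param labels integer vector, one class label per trial. Two distinct
#'   values are required whenever the set is used for fitting.
#' @param sfreq sampling rate in Hz (positive scalar).
#' @param channel_names character vector of unique channel identifiers, one
#'   per channel; defaults to `"ch01"`, `"ch02"`, ...
#' @param t0 time in seconds of the first sample relative to task onset.
#'   Negative values mean a pre-onset baseline is present.
#'
#' @return An object of class `epoch_set`: a list with elements `data`,
#'   `labels`, `sfreq`, `channel_names`, `t0`.
#' @export
epoch_set <- function(data, labels, sfreq, channel_names = NULL, t0 = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trial, channel, sample]", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(dim(data)[2L]))
  x <- structure(
    list(data = data, labels = as.integer(labels), sfreq = as.numeric(sfreq),
         channel_names = as.character(channel_names), t0 = as.numeric(t0)),
    class = "epoch_set")
  validate_epoch_set(x)
  x
}

#' Validate an epoch_set
#'
#' Checks the structural invariants of the container and fails with an error
#' naming the offending field.
#'
#' @param x an `epoch_set`.
#' @param require_two_classes if `TRUE`, additionally require exactly two
#'   distinct label values (the fitting precondition).
#' @return `x`, invisibly.
#' @export
validate_epoch_set <- function(x, require_two_classes = FALSE) {
  if (!inherits(x, "epoch_set")) stop("not an epoch_set", call. = FALSE)
  d <- dim(x$data)
  if (length(d) != 3L)
    stop("field `data`: must have 3 dimensions [trial, channel, sample]",
         call. = FALSE)
  if (!all(is.finite(x$data)))
    stop("field `data`: non-finite values present", call. = FALSE)
  if (length(x$labels) != d[1L])
    stop("field `labels`: length (", length(x$labels),
         ") must equal trial count (", d[1L], ")", call. = FALSE)
  if (require_two_classes && length(unique(x$labels)) != 2L)
    stop("field `labels`: exactly 2 distinct classes required, found ",
         length(unique(x$labels)), call. = FALSE)
  if (length(x$channel_names) != d[2L])
    stop("field `channel_names`: length must equal channel count", call. = FALSE)
  if (anyDuplicated(x$channel_names))
    stop("field `channel_names`: names must be unique", call. = FALSE)
  if (!is.finite(x$sfreq) || x$sfreq <= 0)
    stop("field `sfreq`: must be a positive number", call. = FALSE)
  if (!is.finite(x$t0))
    stop("field `t0`: must be finite", call. = FALSE)
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$sfreq))
  cat(sprintf("  t0 = %g s; span [%g, %g) s\n", x$t0, x$t0, x$t0 + d[3L] / x$sfreq))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s x %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of trials, channels, samples
#' @param x an `epoch_set`.
#' @return integer count.
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' @rdname n_trials
#' @export
n_channels <- function(x) dim(x$data)[2L]

#' @rdname n_trials
#' @export
n_samples <- function(x) dim(x$data)[3L]

#' Subset an epoch_set by trial and/or channel
#'
#' @param x an `epoch_set`.
#' @param trials integer or logical index on the trial axis (default: all).
#' @param channels integer or logical index on the channel axis (default: all).
#' @return a new `epoch_set`.
#' @export
subset_epochs <- function(x, trials = NULL, channels = NULL) {
  if (is.null(trials)) trials <- seq_len(n_trials(x))
  if (is.null(channels)) channels <- seq_len(n_channels(x))
  epoch_set(x$data[trials, channels, , drop = FALSE],
            labels = x$labels[trials], sfreq = x$sfreq,
            channel_names = x$channel_names[channels], t0 = x$t0)
}

#' Time axis of an epoch_set
#' @param x an `epoch_set`.
#' @return numeric vector of sample times in seconds relative to task onset.
#' @export
epoch_times <- function(x) x$t0 + (seq_len(n_samples(x)) - 1L) / x$sfreq

FIXTURE_VERSION <- 1L

#' Write an epoch_set to a portable fixture directory
#'
#' The fixture format is deliberately simple and platform-independent:
#' `meta.json` (shape, sampling metadata, byte order, format version),
#' `data.f32` (little-endian 32-bit floats, row-major `[trial, channel,
#' sample]`, i.e. the sample index varies fastest), and `labels.csv` (one
#' integer per line). Writing then reading reproduces the set exactly up to
#' 32-bit float representation of the data.
#'
#' @param epochs an `epoch_set`.
#' @param path directory to create/write into.
#' @return invisibly, a manifest: named character vector of written file paths.
#' @export
write_fixture <- function(epochs, path) {
  validate_epoch_set(epochs)
  if (!dir.exists(path))
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path, call. = FALSE)
  d <- dim(epochs$data)
  meta <- list(
    version = FIXTURE_VERSION,
    shape = as.integer(d),
    sfreq = epochs$sfreq,
    t0 = epochs$t0,
    channel_names = as.list(epochs$channel_names),
    dtype = "float32",
    byte_order = "little",
    order = "row-major [trial, channel, sample]")
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # row-major [trial][channel][sample]: sample varies fastest
  flat <- as.vector(aperm(epochs$data, c(3L, 2L, 1L)))
  con <- file(file.path(path, "data.f32"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(flat, con, size = 4L, endian = "little")
  writeLines(as.character(epochs$labels), file.path(path, "labels.csv"))
  invisible(c(meta = file.path(path, "meta.json"),
              data = file.path(path, "data.f32"),
              labels = file.path(path, "labels.csv")))
}

#' Read an epoch_set from a fixture directory
#'
#' @param path directory written by [write_fixture()].
#' @return an `epoch_set`.
#' @export
read_fixture <- function(path) {
  files <- file.path(path, c("meta.json", "data.f32", "labels.csv"))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("fixture file missing: ", paste(basename(missing), collapse = ", "),
         " [error: missing_file]", call. = FALSE)
  meta <- jsonlite::read_json(files[1L], simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape <= 0L))
    stop("meta.json: invalid shape [error: bad_meta]", call. = FALSE)
  n_expected <- prod(shape)
  n_bytes <- file.info(files[2L])$size
  if (n_bytes != 4 * n_expected)
    stop("data.f32: ", n_bytes, " bytes but shape implies ", 4 * n_expected,
         " [error: shape_mismatch]", call. = FALSE)
  con <- file(files[2L], "rb")
  on.exit(close(con), add = TRUE)
  flat <- readBin(con, what = "numeric", n = n_expected, size = 4L,
                  endian = "little")
  if (length(flat) != n_expected)
    stop("data.f32: short read [error: shape_mismatch]", call. = FALSE)
  if (!all(is.finite(flat)))
    stop("data.f32: non-finite values [error: nonfinite]", call. = FALSE)
  lab_lines <- readLines(files[3L])
  lab_lines <- lab_lines[nzchar(trimws(lab_lines))]
  if (!all(grepl("^\\s*-?[0-9]+\\s*$", lab_lines)))
    stop("labels.csv: non-integer line [error: label_parse]", call. = FALSE)
  labels <- as.integer(lab_lines)
  if (length(labels) != shape[1L])
    stop("labels.csv: ", length(labels), " labels but ", shape[1L],
         " trials [error: shape_mismatch]", call. = FALSE)
  data <- aperm(array(flat, dim = rev(shape)), c(3L, 2L, 1L))
  epoch_set(data, labels = labels, sfreq = meta$sfreq,
            channel_names = unlist(meta$channel_names), t0 = meta$t0)
}
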