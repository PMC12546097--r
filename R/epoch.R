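#' Construct an EEG epoch
#'
#' An epoch is one task segment of multichannel EEG: a channels-by-samples
#' matrix in microvolts together with its sample rate, channel labels and a
#' task label (`"BSL"`, `"WR"` or `"TL"`).
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling frequency in Hz.
#' @param channel_names Character vector, one label per row of `data`.
#' @param task Task label, one of `"BSL"`, `"WR"`, `"TL"`.
#' @return An object of class `eeg_epoch`.
#' @export
epoch <- function(data, fs, channel_names, task = c("BSL", "WR", "TL")) {
  task <- match.arg(task)
  if (!is.matrix(data) || !is.numeric(data))
    stop("epoch data must be a numeric channels x samples matrix")
  if (anyNA(data) || any(!is.finite(data)))
    stop("epoch data contains NA or non-finite samples")
  if (length(channel_names) != nrow(data))
    stop("channel_names length must equal the number of data rows")
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (ncol(data) < fs)
    stop("epoch must be at least 1 s long (samples >= fs)")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = as.character(channel_names),
                 task = task),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> task=%s, %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$task, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Epoch duration in seconds
#' @param x An `eeg_epoch`.
#' @return Duration in seconds.
#' @export
epoch_duration <- function(x) ncol(x$data) / x$fs

#' Write an epoch to a flat binary file with a JSON sidecar
#'
#' Samples are stored as little-endian float32 in channel-major order
#' (`<path>.f32`); the sidecar (`<path>.json`) records channel names, sample
#' rate, task label and dimensions so the file is self-describing.
#'
#' @param x An `eeg_epoch`.
#' @param path Output path stem (without extension).
#' @return Invisibly, the two file paths written.
#' @seealso [read_epoch()]
#' @export
write_epoch <- function(x, path) {
  stopifnot(inherits(x, "eeg_epoch"))
  bin <- paste0(path, ".f32")
  sidecar <- paste0(path, ".json")
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(x$data)), con, size = 4, endian = "little")
  meta <- list(format = "float32-le", order = "channel-major",
               n_channels = nrow(x$data), n_samples = ncol(x$data),
               fs = x$fs, task = x$task, channel_names = x$channel_names)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(bin, sidecar))
}

#' Read an epoch written by [write_epoch()]
#'
#' @param path Path stem used at write time.
#' @return An `eeg_epoch` (float32 quantization applies to the samples).
#' @export
read_epoch <- function(path) {
  bin <- paste0(path, ".f32")
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("sidecar not found: %s", sidecar))
  if (!file.exists(bin))
    stop(sprintf("binary payload not found: %s", bin))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(bin, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "numeric", n = n + 1, size = 4, endian = "little")
  if (length(vals) != n)
    stop(sprintf("truncated or oversized payload in %s: expected %d samples, got %d",
                 bin, n, length(vals)))
  data <- matrix(vals, nrow = meta$n_channels, ncol = meta$n_samples, byrow = TRUE)
  epoch(data, fs = as.numeric(meta$fs), channel_names = meta$channel_names,
        task = meta$task)
}
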