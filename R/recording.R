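#' EEG recording container
#'
#' A `Recording` is a channels x samples numeric matrix of microvolt values
#' with a sampling rate and ordered channel names. Row order follows the
#' montage; time runs along columns.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz, positive scalar.
#' @param channels character vector of channel names, one per row.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channels = rownames(data)) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  if (length(channels) != nrow(data))
    stop("length(channels) must equal nrow(data)")
  rownames(data) <- channels
  structure(list(data = data, fs = fs, channels = as.character(channels)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

rec_duration <- function(rec) ncol(rec$data) / rec$fs

rec_channel_idx <- function(rec, channels) {
  idx <- match(channels, rec$channels)
  if (anyNA(idx))
    stop("unknown channel(s): ", paste(channels[is.na(idx)], collapse = ", "))
  idx
}

#' Write a recording to the documented CSV dialect
#'
#' The dialect is: line 1 `fs,<Hz>`; line 2 `channels,<name1>,...`; then one
#' row per sample with the channel values in montage order.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @param digits significant digits kept in the text representation.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path, digits = 8) {
  writeLines(c(paste0("fs,", format(rec$fs, digits = 15)),
               paste(c("channels", rec$channels), collapse = ",")), path)
  m <- signif(t(rec$data), digits)
  data.table::fwrite(data.table::as.data.table(m), path, col.names = FALSE,
                     append = TRUE)
  invisible(path)
}

#' Read a recording from the documented CSV dialect
#' @param path file written by [write_recording_csv()].
#' @return An `eeg_recording`.
#' @export
read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  if (length(hdr) < 2L || !startsWith(hdr[1], "fs,") ||
      !startsWith(hdr[2], "channels,"))
    stop("not a recording CSV: expected `fs,` and `channels,` header lines in ",
         path)
  fs <- as.numeric(sub("^fs,", "", hdr[1]))
  channels <- strsplit(hdr[2], ",", fixed = TRUE)[[1]][-1]
  m <- as.matrix(data.table::fread(path, skip = 2L, header = FALSE))
  if (ncol(m) != length(channels))
    stop("column count does not match channel header in ", path)
  recording(t(unname(m)), fs = fs, channels = channels)
}

REC_BIN_MAGIC <- "EEGATT01"

#' Write a recording in the compact binary dialect
#'
#' Layout: 8-byte magic, fs (double), n_channels (int32), channel names
#' (length-prefixed UTF-8), n_samples (int32), then column-major doubles
#' (sample-by-sample across channels).
#'
#' @inheritParams write_recording_csv
#' @return `path`, invisibly.
#' @export
write_recording_bin <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(REC_BIN_MAGIC, con, nchars = 8L, eos = NULL)
  writeBin(as.double(rec$fs), con, size = 8, endian = "little")
  writeBin(as.integer(nrow(rec$data)), con, size = 4, endian = "little")
  for (ch in rec$channels) {
    raw <- charToRaw(enc2utf8(ch))
    writeBin(as.integer(length(raw)), con, size = 4, endian = "little")
    writeBin(raw, con)
  }
  writeBin(as.integer(ncol(rec$data)), con, size = 4, endian = "little")
  writeBin(as.double(rec$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a recording from the compact binary dialect
#' @param path file written by [write_recording_bin()].
#' @return An `eeg_recording`.
#' @export
read_recording_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchars = 8L, useBytes = TRUE)
  if (!identical(magic, REC_BIN_MAGIC))
    stop("not a recording binary file: ", path)
  fs <- readBin(con, "double", 1, size = 8, endian = "little")
  nch <- readBin(con, "integer", 1, size = 4, endian = "little")
  channels <- character(nch)
  for (i in seq_len(nch)) {
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    channels[i] <- rawToChar(readBin(con, "raw", len))
  }
  ns <- readBin(con, "integer", 1, size = 4, endian = "little")
  x <- readBin(con, "double", nch * ns, size = 8, endian = "little")
  recording(matrix(x, nrow = nch, ncol = ns), fs = fs, channels = channels)
}
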