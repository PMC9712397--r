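#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (8th-order Butterworth at 80% of
#' the new Nyquist) and keeps every q-th sample. The original rate must be an
#' integer multiple of the target; equal rates bypass the filter exactly.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs new sampling rate in Hz.
#' @return The downsampled `eeg_recording`.
#' @export
downsample <- function(rec, target_fs) {
  if (target_fs <= 0) stop("target_fs must be > 0")
  if (rec$fs == target_fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop(sprintf("fs (%g) must be an integer multiple of target_fs (%g)",
                 rec$fs, target_fs))
  q <- round(q)
  bf <- signal::butter(8, 0.8 / q, type = "low")
  data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  keep <- seq(1L, ncol(data), by = q)
  recording(data[, keep, drop = FALSE], fs = target_fs,
            channels = rec$channels)
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass; the default
#' 0.5--45 Hz band removes drift and high-frequency muscle activity while
#' keeping all analysis bands intact.
#'
#' @param rec an `eeg_recording`.
#' @param lo low cut-off, Hz.
#' @param hi high cut-off, Hz (must be below Nyquist).
#' @return The filtered `eeg_recording`.
#' @export
bandpass <- function(rec, lo = 0.5, hi = 45) {
  if (!(lo > 0 && lo < hi && hi < rec$fs / 2))
    stop(sprintf("invalid band [%g, %g] Hz for fs = %g", lo, hi, rec$fs))
  bf <- signal::butter(4, c(lo, hi) / (rec$fs / 2), type = "pass")
  data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  recording(data, fs = rec$fs, channels = rec$channels)
}

#' Remove ocular (blink) artifacts by frontal-proxy regression
#'
#' Builds a blink proxy — the low-passed (default 5 Hz) mean of the frontal
#' channels — and regresses it out of every channel by least squares. This is
#' an automated stand-in for component-based artifact rejection: blinks are
#' frontal-dominant and low-frequency, so projecting them out of each channel
#' removes most blink energy while leaving in-band oscillatory activity
#' essentially untouched.
#'
#' @param rec an `eeg_recording`.
#' @param proxy_channels frontal channels forming the proxy.
#' @param lp_hz proxy low-pass corner, Hz.
#' @return Cleaned `eeg_recording`. If the proxy has (numerically) zero
#'   variance the input is returned unchanged with a warning.
#' @export
remove_ocular <- function(rec, proxy_channels = frontal_proxy_channels(),
                          lp_hz = 5) {
  idx <- rec_channel_idx(rec, proxy_channels)
  bf <- signal::butter(4, lp_hz / (rec$fs / 2), type = "low")
  lp <- function(x) signal::filtfilt(bf, x)
  proxy_all <- lp(colMeans(rec$data[idx, , drop = FALSE]))
  if (sum((proxy_all - mean(proxy_all))^2) < 1e-12) {
    warning("ocular proxy has zero variance; recording returned unchanged")
    return(rec)
  }
  center <- function(x) x - mean(x)
  p_all <- center(proxy_all)
  data <- rec$data
  for (ci in seq_len(nrow(data))) {
    # a proxy channel is regressed against the other proxies only, so its
    # own noise never inflates the fitted coefficient
    p0 <- if (ci %in% idx && length(idx) > 1) {
      others <- setdiff(idx, ci)
      center(lp(colMeans(rec$data[others, , drop = FALSE])))
    } else p_all
    den <- sum(p0^2)
    if (den < 1e-12) next
    beta <- sum(data[ci, ] * p0) / den
    data[ci, ] <- data[ci, ] - beta * p0
  }
  recording(data, fs = rec$fs, channels = rec$channels)
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so the
#' channel mean is zero at all times. Idempotent.
#'
#' @param rec an `eeg_recording` with at least 2 channels.
#' @return The re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$data) < 2) stop("average reference needs >= 2 channels")
  data <- sweep(rec$data, 2, colMeans(rec$data))
  recording(data, fs = rec$fs, channels = rec$channels)
}

#' Labeled 2-s epoch
#'
#' @param data channels x samples matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param label `"attention"` or `"distraction"`.
#' @param debate_id debate identifier.
#' @param anchor event anchor time on the EEG clock, seconds.
#' @param channels channel names.
#' @return An `eeg_epoch` object.
#' @export
epoch <- function(data, fs, label, debate_id, anchor,
                  channels = rownames(data)) {
  stopifnot(label %in% c("attention", "distraction"))
  structure(list(data = data, fs = fs, label = label,
                 debate_id = debate_id, anchor = anchor,
                 channels = channels %||% paste0("ch", seq_len(nrow(data)))),
            class = "eeg_epoch")
}

#' Extract fixed-length labeled epochs around fused events
#'
#' Each event contributes the window `[anchor - pre_s, anchor - pre_s +
#' length_s)`, mapped to samples as `floor(t * fs)` (0-based, half-open), so
#' every epoch has exactly `round(length_s * fs)` samples. The 1-s pre-anchor
#' default absorbs the rater's reaction time: the marked instant trails the
#' neural event. Events whose window leaves the recording are skipped and
#' counted.
#'
#' @param rec a preprocessed `eeg_recording`.
#' @param events data.frame of fused events (needs `label`, `anchor`;
#'   `debate_id` optional).
#' @param pre_s seconds before the anchor at which the window starts.
#' @param length_s window length in seconds.
#' @param debate_id fallback debate id if `events` lacks the column.
#' @return List of `eeg_epoch` objects; attribute `n_skipped` counts
#'   out-of-bounds events.
#' @export
extract_epochs <- function(rec, events, pre_s = 1.0, length_s = 2.0,
                           debate_id = NA) {
  n <- ncol(rec$data)
  len <- round(length_s * rec$fs)
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(events))) {
    t0 <- events$anchor[i] - pre_s
    s0 <- floor(t0 * rec$fs)               # 0-based first sample
    if (t0 < 0 || s0 + len > n) { skipped <- skipped + 1L; next }
    cols <- (s0 + 1L):(s0 + len)
    did <- if ("debate_id" %in% names(events)) events$debate_id[i] else debate_id
    out[[length(out) + 1L]] <-
      epoch(rec$data[, cols, drop = FALSE], fs = rec$fs,
            label = events$label[i], debate_id = did,
            anchor = events$anchor[i], channels = rec$channels)
  }
  if (skipped > 0L)
    message(sprintf("extract_epochs: skipped %d event(s) outside the recording",
                    skipped))
  attr(out, "n_skipped") <- skipped
  out
}

#' Run the standard preprocessing chain
#'
#' Downsample (512 to 256 Hz by default), band-pass 0.5--45 Hz, regress out
#' the ocular proxy, re-reference to the common average — in that order.
#'
#' @param rec raw `eeg_recording`.
#' @param target_fs post-downsampling rate, Hz.
#' @param lo,hi band-pass edges, Hz.
#' @param ocular apply the ocular-regression stage?
#' @return Preprocessed `eeg_recording`.
#' @export
preprocess_recording <- function(rec, target_fs = 256, lo = 0.5, hi = 45,
                                 ocular = TRUE) {
  rec <- downsample(rec, target_fs)
  rec <- bandpass(rec, lo, hi)
  if (ocular) rec <- remove_ocular(rec)
  rereference_average(rec)
}

#' Serialize epochs to a directory with an index CSV
#'
#' One recording-dialect CSV per epoch plus `index.csv` (epoch_id, label,
#' debate_id, anchor, file) — the contract consumed by the spectral and
#' decoding stages.
#'
#' @param epochs list of `eeg_epoch` objects.
#' @param dir output directory.
#' @return The index data.frame, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(epochs), function(i) {
    ep <- epochs[[i]]
    f <- sprintf("epoch%05d.csv", i)
    write_recording_csv(recording(ep$data, ep$fs, ep$channels),
                        file.path(dir, f))
    data.frame(epoch_id = i, label = ep$label, debate_id = ep$debate_id,
               anchor = ep$anchor, file = f, stringsAsFactors = FALSE)
  })
  index <- do.call(rbind, rows)
  utils::write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(index)
}

#' Read epochs written by [write_epochs()]
#' @param dir directory containing `index.csv` and epoch files.
#' @return List of `eeg_epoch` objects in index order.
#' @export
read_epochs <- function(dir) {
  index <- utils::read.csv(file.path(dir, "index.csv"),
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(index)), function(i) {
    rec <- read_recording_csv(file.path(dir, index$file[i]))
    epoch(rec$data, rec$fs, index$label[i], index$debate_id[i],
          index$anchor[i], rec$channels)
  })
}
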