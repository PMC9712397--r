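#' Detect blink times in frontal EEG
#'
#' Blinks dominate the low-frequency content of the frontal channels, so they
#' are found by low-pass filtering the mean frontal signal and picking peaks
#' above a robust adaptive threshold (median + k * MAD), enforcing a minimum
#' 0.5-s separation. Returns at most `max_events` earliest peak times.
#'
#' @param recording an `eeg_recording`, at least 10 s long.
#' @param channels frontal channel subset (default Fp1/Fp2/AF3/AF4).
#' @param max_events maximum number of blink times to return.
#' @param lp_hz low-pass corner frequency in Hz (default 5).
#' @param k threshold in MADs above the median (default 6).
#' @return Numeric vector of blink peak times in seconds, strictly
#'   increasing; empty if no peak clears the threshold.
#' @export
detect_blinks <- function(recording, channels = frontal_proxy_channels(),
                          max_events = Inf, lp_hz = 5, k = 6) {
  if (rec_duration(recording) < 10)
    stop("detect_blinks: recording must be at least 10 s long")
  idx <- rec_channel_idx(recording, channels)
  fs <- recording$fs
  proxy <- colMeans(recording$data[idx, , drop = FALSE])
  bf <- signal::butter(4, lp_hz / (fs / 2), type = "low")
  sm <- signal::filtfilt(bf, proxy)
  thr <- stats::median(sm) + k * stats::mad(sm)
  above <- sm > thr
  if (!any(above)) return(numeric(0))
  # local maxima above threshold, then greedy 0.5-s separation
  n <- length(sm)
  is_peak <- above & c(FALSE, diff(sm) > 0) & c(diff(sm) < 0, FALSE)
  cand <- which(is_peak)
  if (length(cand) == 0L) return(numeric(0))
  cand <- cand[order(cand)]
  min_gap <- round(0.5 * fs)
  keep <- integer(0)
  last <- -Inf
  for (p in cand) {
    if (p - last >= min_gap) { keep <- c(keep, p); last <- p }
    else if (sm[p] > sm[keep[length(keep)]]) { keep[length(keep)] <- p; last <- p }
  }
  # refine each peak to sub-sample precision with the centroid of the bump
  # above half height (robust for broad, smoothed blink transients)
  half_win <- round(0.4 * fs)
  times <- vapply(keep, function(p) {
    a <- max(1L, p - half_win); b <- min(n, p + half_win)
    seg <- sm[a:b] - (stats::median(sm))
    lvl <- 0.5 * (sm[p] - stats::median(sm))
    use <- seg >= lvl
    if (sum(use) >= 3) {
      w <- seg[use] - lvl
      (a - 1 + sum((which(use) - 1) * w) / sum(w)) / fs
    } else (p - 1) / fs
  }, numeric(1))
  utils::head(times, n = if (is.finite(max_events)) max_events else length(times))
}

#' Estimate the EEG-to-video clock offset from matched blink times
#'
#' With both clocks observing the same physical blinks, the offset is the
#' median of the pairwise differences (EEG minus video); the median makes the
#' estimate robust to a single poorly-localized pair.
#'
#' @param eeg_blinks sorted blink times on the EEG clock (seconds).
#' @param video_blinks sorted blink times on the video clock, same count.
#' @return list(offset_s, residual_mad_s, n); `offset_s` is EEG minus video.
#' @export
estimate_offset <- function(eeg_blinks, video_blinks) {
  if (length(eeg_blinks) != length(video_blinks))
    stop(sprintf("blink count mismatch: %d EEG vs %d video",
                 length(eeg_blinks), length(video_blinks)))
  if (length(eeg_blinks) < 2)
    stop("need at least 2 matched blinks to estimate an offset")
  d <- sort(eeg_blinks) - sort(video_blinks)
  list(offset_s = stats::median(d),
       residual_mad_s = stats::mad(d, constant = 1),
       n = length(d))
}

#' Shift annotation tracks onto the EEG clock
#'
#' Adds `offset` to every interval boundary (video-clock annotations plus the
#' EEG-minus-video offset land on the EEG clock). Intervals whose shifted
#' start would be negative are clipped at 0 with a warning.
#'
#' @param tracks list of [rater_track()] objects (or a single track).
#' @param offset seconds to add.
#' @param warn_clip warn when an interval is clipped at 0?
#' @return Shifted tracks in the same shape as the input.
#' @export
apply_offset <- function(tracks, offset, warn_clip = TRUE) {
  single <- inherits(tracks, "rater_track")
  if (single) tracks <- list(tracks)
  out <- lapply(tracks, function(tr) {
    iv <- tr$intervals
    if (nrow(iv)) {
      iv$start <- iv$start + offset
      iv$stop <- iv$stop + offset
      clip <- iv$start < 0
      if (any(clip)) {
        if (warn_clip)
          warning(sprintf("%s: %d interval(s) clipped at t = 0 after shift",
                          tr$rater_id, sum(clip)))
        iv$start[clip] <- 0
        iv <- iv[iv$stop > 0, , drop = FALSE]
      }
    }
    rater_track(tr$rater_id, iv)
  })
  if (single) out[[1]] else out
}
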