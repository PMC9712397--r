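#' Configuration for the synthetic debate-EEG generator
#'
#' The generator emulates naturalistic debate sessions: 32-channel EEG at
#' 512 Hz with 1/f background activity, band-limited oscillations whose
#' amplitudes over designated scalp regions shift with the attentional state
#' (alpha up over left frontal sites, theta up over left parietal sites,
#' delta down over central sites during attention), frontal-dominant blink
#' transients, an unknown EEG-to-video clock offset, and several imperfect
#' human raters who annotate attention/distraction intervals from video.
#'
#' @param n_debates number of debates to simulate.
#' @param debate_length_s debate duration in seconds (default 600: a 10-minute
#'   debate).
#' @param fs sampling rate in Hz (default 512).
#' @param n_channels number of channels; fixed at 32 (Biosemi montage).
#' @param effect_alpha_leftfrontal attention-minus-distraction alpha envelope
#'   change (microvolts) over Fp1/AF3/F3/F7.
#' @param effect_theta_leftparietal attention-minus-distraction theta envelope
#'   change (microvolts) over P3/P7/CP5.
#' @param effect_delta_central attention-minus-distraction delta envelope
#'   change (microvolts) over Cz/C3/C4; negative: delta drops with attention.
#' @param noise_sd broadband background noise standard deviation (microvolts).
#' @param n_raters number of simulated raters (default 3).
#' @param rater_boundary_jitter_sd Gaussian jitter of rater interval
#'   boundaries, seconds.
#' @param rater_miss_prob probability that a rater misses an interval.
#' @param clock_offset_s EEG-minus-video clock offset in seconds (annotations
#'   are logged on the video clock).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @param effect_groups named list of channel vectors (`alpha`, `theta`,
#'   `delta`) carrying the respective effects; defaults to the canonical
#'   left-frontal / left-parietal / central groups. Override to plant the
#'   same effects on a different scalp topography (e.g. for transfer
#'   experiments).
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_debates = 12,
                         debate_length_s = 600,
                         fs = 512,
                         n_channels = 32,
                         effect_alpha_leftfrontal = 2,
                         effect_theta_leftparietal = 3,
                         effect_delta_central = -4,
                         noise_sd = 10,
                         n_raters = 3,
                         rater_boundary_jitter_sd = 0.3,
                         rater_miss_prob = 0.1,
                         clock_offset_s = 0.25,
                         seed = 1L,
                         effect_groups = NULL) {
  if (is.null(effect_groups)) {
    g <- effect_channel_groups()
    effect_groups <- list(alpha = g$left_frontal, theta = g$left_parietal,
                          delta = g$central)
  }
  cfg <- list(n_debates = n_debates, debate_length_s = debate_length_s,
              fs = fs, n_channels = n_channels,
              effect_alpha_leftfrontal = effect_alpha_leftfrontal,
              effect_theta_leftparietal = effect_theta_leftparietal,
              effect_delta_central = effect_delta_central,
              noise_sd = noise_sd, n_raters = n_raters,
              rater_boundary_jitter_sd = rater_boundary_jitter_sd,
              rater_miss_prob = rater_miss_prob,
              clock_offset_s = clock_offset_s, seed = as.integer(seed),
              effect_groups = effect_groups)
  if (!all(c("alpha", "theta", "delta") %in% names(cfg$effect_groups)))
    stop("invalid config: effect_groups needs alpha, theta and delta entries")
  bad_ch <- setdiff(unlist(cfg$effect_groups), biosemi32_montage()$channel)
  if (length(bad_ch))
    stop("invalid config: unknown effect channel(s): ",
         paste(bad_ch, collapse = ", "))
  if (cfg$fs <= 0) stop("invalid config: fs must be > 0")
  if (cfg$debate_length_s <= 0)
    stop("invalid config: debate_length_s must be > 0")
  if (cfg$n_channels != 32L)
    stop("invalid config: n_channels is fixed at 32 (Biosemi montage)")
  if (cfg$n_debates < 1) stop("invalid config: n_debates must be >= 1")
  if (cfg$n_raters < 1) stop("invalid config: n_raters must be >= 1")
  if (cfg$rater_miss_prob < 0 || cfg$rater_miss_prob > 1)
    stop("invalid config: rater_miss_prob must be in [0, 1]")
  if (cfg$noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  class(cfg) <- "synth_config"
  cfg
}

# Baseline (state-independent) band envelope amplitudes, microvolts.
BAND_BASE_AMP <- c(delta = 6, theta = 4, alpha = 4, beta = 3)

# Canonical band edges in Hz used by the generator's oscillators.
BAND_EDGES <- list(delta = c(0.5, 4), theta = c(4, 8),
                   alpha = c(8, 13), beta = c(13, 28))

# State-interval process: alternating labeled intervals separated by short
# unlabeled gaps. Distraction is the more frequent state; less experienced
# debaters drift more.
DISTRACTION_PROB <- c(less = 0.68, more = 0.55)

debate_metadata <- function(debate_index) {
  list(difficulty = if (debate_index %% 2L == 1L) "easy" else "hard",
       experience = if (((debate_index - 1L) %% 12L) < 5L) "more" else "less")
}

generate_state_intervals <- function(length_s, p_distraction) {
  t <- 2                                    # settle-in before first label
  out <- list()
  while (t < length_s - 4) {
    dur <- stats::rlnorm(1, meanlog = log(12), sdlog = 0.4)
    dur <- min(dur, length_s - t - 1)
    if (dur < 3) break
    lab <- if (stats::runif(1) < p_distraction) "distraction" else "attention"
    out[[length(out) + 1L]] <- data.frame(start = t, stop = t + dur,
                                          label = lab,
                                          stringsAsFactors = FALSE)
    t <- t + dur + stats::runif(1, 0.5, 2)  # unlabeled gap between states
  }
  if (length(out) == 0L)
    return(data.frame(start = numeric(0), stop = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Ground truth for one synthetic debate
#'
#' Draws the hidden state timeline (non-overlapping attention/distraction
#' intervals with short unlabeled gaps), spontaneous blink times, and the
#' debate's difficulty/experience metadata. Deterministic given
#' (config, debate_index).
#'
#' @param config a [synth_config()].
#' @param debate_index 1-based debate number.
#' @return A `synth_truth` list: `intervals` (data.frame start/stop/label),
#'   `blink_times`, `difficulty`, `experience`, `clock_offset_s`,
#'   `debate_length_s`.
#' @export
generate_truth <- function(config, debate_index) {
  stopifnot(inherits(config, "synth_config"))
  meta <- debate_metadata(debate_index)
  with_seed(derive_seed(config$seed, debate_index, 11L), {
    iv <- generate_state_intervals(config$debate_length_s,
                                   DISTRACTION_PROB[[meta$experience]])
    # spontaneous blinks roughly every 2-6 s, avoiding the calibration window
    bt <- numeric(0)
    t <- 12
    while (t < config$debate_length_s - 1) {
      bt <- c(bt, t)
      t <- t + stats::runif(1, 2, 6)
    }
    structure(list(intervals = iv, blink_times = bt,
                   difficulty = meta$difficulty, experience = meta$experience,
                   clock_offset_s = config$clock_offset_s,
                   debate_length_s = config$debate_length_s),
              class = "synth_truth")
  })
}

# 0/1 attention indicator sampled on the recording's time grid
attention_indicator <- function(truth, n, fs) {
  att <- numeric(n)
  iv <- truth$intervals
  if (nrow(iv) == 0L) return(att)
  for (i in which(iv$label == "attention")) {
    a <- floor(iv$start[i] * fs) + 1L
    b <- min(n, floor(iv$stop[i] * fs))
    if (a <= b) att[a:b] <- 1
  }
  att
}

#' Generate one synthetic EEG recording
#'
#' Builds a 32 x (fs * debate_length) microvolt matrix: 1/f-plus-white
#' background noise, band-limited oscillators in the delta/theta/alpha/beta
#' bands on every channel, state-dependent amplitude modulation of the
#' designated channel groups, and blink transients at the ground-truth blink
#' times.
#'
#' @param config a [synth_config()].
#' @param debate_index 1-based debate number (selects the RNG stream and
#'   metadata).
#' @param truth optional precomputed [generate_truth()] result (so the two
#'   debaters of one debate can share a timeline).
#' @param debater 1 or 2; the two debaters of a debate share the truth but
#'   have independent noise.
#' @return list(recording = eeg_recording, truth = synth_truth).
#' @export
generate_recording <- function(config, debate_index, truth = NULL,
                               debater = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(truth)) truth <- generate_truth(config, debate_index)
  fs <- config$fs
  n <- round(config$debate_length_s * fs)
  channels <- biosemi32_montage()$channel
  groups <- config$effect_groups
  effects <- list(alpha = list(e = config$effect_alpha_leftfrontal,
                               chans = groups$alpha),
                  theta = list(e = config$effect_theta_leftparietal,
                               chans = groups$theta),
                  delta = list(e = config$effect_delta_central,
                               chans = groups$delta))
  att <- attention_indicator(truth, n, fs)

  data <- with_seed(derive_seed(config$seed, debate_index, 23L, debater), {
    m <- matrix(0, nrow = length(channels), ncol = n)
    for (ci in seq_along(channels)) {
      bg <- sqrt(0.8) * pink_noise(n) + sqrt(0.2) * stats::rnorm(n)
      m[ci, ] <- config$noise_sd * bg
      for (band in names(BAND_EDGES)) {
        edges <- BAND_EDGES[[band]]
        nb <- bandlimited_noise(n, fs, edges[1], edges[2])
        env <- BAND_BASE_AMP[[band]]
        eff <- effects[[band]]
        if (!is.null(eff) && channels[ci] %in% eff$chans)
          env <- env + eff$e * att
        m[ci, ] <- m[ci, ] + env * nb
      }
    }
    tpl <- blink_template(fs, dur_s = 0.4, amp = 100)
    add_transient(m, fs, truth$blink_times, tpl, blink_weights(channels))
  })
  list(recording = recording(data, fs = fs, channels = channels),
       truth = truth)
}

#' Simulate noisy raters from ground truth
#'
#' Each rater reproduces the true intervals with Gaussian boundary jitter,
#' drops intervals with probability `rater_miss_prob`, and (as part of the
#' same noise model) may split long intervals in two, reflecting differing
#' levels of labelling detail. Raters never flip a label between the two
#' classes: rater error is omission and timing, not inversion. With zero
#' jitter and zero miss probability every track equals the truth exactly.
#'
#' @param truth a [generate_truth()] result.
#' @param config a [synth_config()].
#' @return List of `rater_track` objects (see [rater_track()]).
#' @export
simulate_raters <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_raters < 1) stop("n_raters must be >= 1")
  jit <- config$rater_boundary_jitter_sd
  miss <- config$rater_miss_prob
  noiseless <- (jit == 0 && miss == 0)
  lapply(seq_len(config$n_raters), function(r) {
    iv <- truth$intervals
    id <- paste0("rater", r)
    if (noiseless || nrow(iv) == 0L)
      return(rater_track(id, iv))
    # per-rater granularity: later raters split long intervals more often
    split_prob <- 0.4 * (r - 1) / max(1, config$n_raters - 1)
    out <- with_seed(derive_seed(config$seed, 37L, r), {
      rows <- list()
      for (i in seq_len(nrow(iv))) {
        if (stats::runif(1) < miss) next
        s <- iv$start[i] + stats::rnorm(1, 0, jit)
        e <- iv$stop[i] + stats::rnorm(1, 0, jit)
        s <- max(0, s)
        if (e - s < 0.1) e <- s + 0.1
        dur <- e - s
        if (dur > 15 && stats::runif(1) < split_prob) {
          mid <- s + dur * stats::runif(1, 0.35, 0.65)
          rows[[length(rows) + 1L]] <-
            data.frame(start = c(s, mid + 0.4), stop = c(mid - 0.4, e),
                       label = iv$label[i], stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <-
            data.frame(start = s, stop = e, label = iv$label[i],
                       stringsAsFactors = FALSE)
        }
      }
      if (length(rows) == 0L)
        data.frame(start = numeric(0), stop = numeric(0),
                   label = character(0), stringsAsFactors = FALSE)
      else do.call(rbind, rows)
    })
    rater_track(id, out)
  })
}

#' Insert the five calibration blinks and return video-side times
#'
#' Emulates the synchronization protocol in which a debater slowly blinks
#' five times at the start of the session; the same blinks are visible in the
#' video and in the frontal EEG, so matching them yields the clock offset.
#' Video-side times are EEG-side times minus the configured clock offset.
#'
#' @param recording an `eeg_recording` (at least 10 s long).
#' @param truth the debate's `synth_truth`.
#' @param config a [synth_config()].
#' @return list(recording, eeg_blinks, video_blinks) with exactly 5 blink
#'   times each.
#' @export
generate_calibration_blinks <- function(recording, truth, config) {
  stopifnot(inherits(config, "synth_config"))
  if (abs(config$clock_offset_s) >= 10)
    stop("clock offset magnitude must be < 10 s")
  if (rec_duration(recording) < 10)
    stop("recording too short for 5 separated calibration blinks (need >= 10 s)")
  eeg_times <- 2 + 1.5 * (0:4)
  tpl <- blink_template(recording$fs, dur_s = 0.45, amp = 160)
  w <- blink_weights(recording$channels)
  data <- add_transient(recording$data, recording$fs, eeg_times, tpl, w)
  list(recording = recording(data, recording$fs, recording$channels),
       eeg_blinks = eeg_times,
       video_blinks = eeg_times - config$clock_offset_s)
}

#' Simulate one full debate in memory
#'
#' Convenience wrapper chaining [generate_truth()], [generate_recording()]
#' for both debaters, [generate_calibration_blinks()] and
#' [simulate_raters()]; rater tracks are returned on the video clock (truth
#' minus the clock offset), as a video-based annotation tool would log them.
#'
#' @param config a [synth_config()].
#' @param debate_index 1-based debate number.
#' @param both_debaters simulate the second debater's recording too?
#' @return list(truth, recording_a, recording_b (or NULL), tracks,
#'   eeg_blinks, video_blinks).
#' @export
synth_debate <- function(config, debate_index, both_debaters = FALSE) {
  truth <- generate_truth(config, debate_index)
  a <- generate_recording(config, debate_index, truth, debater = 1L)
  cal <- generate_calibration_blinks(a$recording, truth, config)
  rec_b <- NULL
  if (both_debaters) {
    b <- generate_recording(config, debate_index, truth, debater = 2L)
    rec_b <- generate_calibration_blinks(b$recording, truth, config)$recording
  }
  tracks <- simulate_raters(truth, config)
  tracks <- apply_offset(tracks, -config$clock_offset_s, warn_clip = FALSE)
  list(truth = truth, recording_a = cal$recording, recording_b = rec_b,
       tracks = tracks, eeg_blinks = cal$eeg_blinks,
       video_blinks = cal$video_blinks)
}

#' Generate and write a full synthetic dataset
#'
#' Writes, for each debate, two debater recordings (shared timeline,
#' independent noise), per-rater annotation CSVs on the video clock, a
#' video-blink CSV, and a manifest. Debates split evenly into easy/hard;
#' experience tags follow a 10:14 more:less ratio. The manifest records the
#' true clock offset for testing but the pipeline never reads that column.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @param format `"bin"` (compact binary) or `"csv"` for recordings.
#' @return The manifest data.frame, invisibly; written as `manifest.csv`.
#' @export
generate_dataset <- function(config, dir, format = c("bin", "csv")) {
  stopifnot(inherits(config, "synth_config"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  ext <- if (format == "bin") ".eeg" else ".csv"
  writer <- if (format == "bin") write_recording_bin else write_recording_csv
  rows <- list()
  for (d in seq_len(config$n_debates)) {
    deb <- synth_debate(config, d, both_debaters = TRUE)
    base <- sprintf("debate%02d", d)
    rec_paths <- c(paste0(base, "_a", ext), paste0(base, "_b", ext))
    writer(deb$recording_a, file.path(dir, rec_paths[1]))
    writer(deb$recording_b, file.path(dir, rec_paths[2]))
    ann_paths <- vapply(seq_along(deb$tracks), function(r) {
      p <- sprintf("%s_rater%d.csv", base, r)
      write_rater_csv(deb$tracks[[r]], file.path(dir, p))
      p
    }, character(1))
    blink_path <- paste0(base, "_video_blinks.csv")
    utils::write.csv(data.frame(blink_time_s = deb$video_blinks),
                     file.path(dir, blink_path), row.names = FALSE)
    rows[[d]] <- data.frame(
      debate_id = d, difficulty = deb$truth$difficulty,
      experience = deb$truth$experience,
      recording_a = rec_paths[1], recording_b = rec_paths[2],
      annotations = paste(ann_paths, collapse = ";"),
      video_blinks = blink_path,
      clock_offset_s = config$clock_offset_s,
      n_true_attention = sum(deb$truth$intervals$label == "attention"),
      n_true_distraction = sum(deb$truth$intervals$label == "distraction"),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
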