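#' Rater annotation track
#'
#' One rater's labeled time intervals, as exported by behavioral event-logging
#' software (e.g. BORIS): each row marks the start and stop (seconds, may be
#' millisecond-precise) of an observed attention or distraction episode.
#'
#' @param rater_id identifier string.
#' @param intervals data.frame with columns `start`, `stop` (seconds) and
#'   `label` in `{"attention", "distraction"}`.
#' @return A `rater_track` object, intervals sorted by start.
#' @export
rater_track <- function(rater_id, intervals) {
  stopifnot(is.data.frame(intervals),
            all(c("start", "stop", "label") %in% names(intervals)))
  if (nrow(intervals) > 0L) {
    if (any(intervals$stop <= intervals$start))
      stop("rater_track: every interval needs start < stop")
    bad <- setdiff(unique(intervals$label), c("attention", "distraction"))
    if (length(bad))
      stop("rater_track: unknown label(s): ", paste(bad, collapse = ", "))
    intervals <- intervals[order(intervals$start), , drop = FALSE]
    rownames(intervals) <- NULL
  }
  structure(list(rater_id = as.character(rater_id),
                 intervals = intervals[, c("start", "stop", "label")]),
            class = "rater_track")
}

#' @export
print.rater_track <- function(x, ...) {
  cat(sprintf("<rater_track> %s: %d intervals\n", x$rater_id,
              nrow(x$intervals)))
  invisible(x)
}

#' Write a rater track to the annotation CSV dialect
#'
#' Columns: `rater_id`, `behavior`, `start_s`, `stop_s` (the BORIS-style
#' export layout this package reads back).
#'
#' @param track a [rater_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rater_csv <- function(track, path) {
  df <- data.frame(rater_id = track$rater_id,
                   behavior = track$intervals$label,
                   start_s = track$intervals$start,
                   stop_s = track$intervals$stop,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Parse a rater annotation CSV
#'
#' Reads the `rater_id, behavior, start_s, stop_s` dialect. Malformed rows
#' (stop <= start, unknown behavior label, non-numeric times) are rejected
#' individually; the warning lists their line numbers so logs can be fixed at
#' the source.
#'
#' @param path CSV file path.
#' @return A [rater_track()] with intervals sorted by start. The attribute
#'   `rejected` holds a data.frame of rejected line numbers and reasons.
#' @export
parse_rater_csv <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rater_id", "behavior", "start_s", "stop_s")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns ", paste(need, collapse = ", "),
         ": ", path)
  start <- suppressWarnings(as.numeric(df$start_s))
  stop_ <- suppressWarnings(as.numeric(df$stop_s))
  line <- seq_len(nrow(df)) + 1L          # +1 for the header line
  reasons <- character(nrow(df))
  reasons[is.na(start) | is.na(stop_)] <- "non-numeric time"
  ok_time <- !is.na(start) & !is.na(stop_)
  reasons[ok_time & stop_ <= start] <- "stop <= start"
  bad_label <- !(df$behavior %in% c("attention", "distraction"))
  reasons[reasons == "" & bad_label] <- "unknown behavior label"
  bad <- reasons != ""
  if (any(bad))
    warning(sprintf("rejected %d malformed row(s) in %s: %s", sum(bad), path,
                    paste(sprintf("line %d (%s)", line[bad], reasons[bad]),
                          collapse = "; ")))
  keep <- !bad
  iv <- data.frame(start = start[keep], stop = stop_[keep],
                   label = df$behavior[keep], stringsAsFactors = FALSE)
  id <- if (nrow(df) > 0L) df$rater_id[1] else "unknown"
  tr <- rater_track(id, iv)
  attr(tr, "rejected") <- data.frame(line = line[bad], reason = reasons[bad],
                                     stringsAsFactors = FALSE)
  tr
}

#' Fuse rater tracks into majority-backed events
#'
#' The time axis is discretized at `fs_vote`; at each tick a label wins when
#' at least half the raters (ceiling(n/2)) mark it. Ticks where both labels
#' reach a majority, or neither does, contribute nothing: no majority, no
#' instance. Maximal runs of a winning label at least `min_event_s` long
#' become fused events; the event's anchor time is its onset.
#'
#' @param tracks list of [rater_track()] objects.
#' @param fs_vote voting grid rate, Hz (default 100, i.e. 10-ms ticks).
#' @param min_event_s minimum event duration in seconds (default 0.2;
#'   suppresses boundary-jitter slivers).
#' @return data.frame of fused events: `label`, `anchor` (onset, s),
#'   `start`, `stop`, `n_supporting_raters` (minimum tick-wise support over
#'   the run).
#' @export
fuse_majority <- function(tracks, fs_vote = 100, min_event_s = 0.2) {
  if (length(tracks) == 0L) stop("fuse_majority: need at least one track")
  if (fs_vote <= 0) stop("fuse_majority: fs_vote must be > 0")
  n_raters <- length(tracks)
  need <- ceiling(n_raters / 2)
  tmax <- max(0, vapply(tracks, function(tr)
    if (nrow(tr$intervals)) max(tr$intervals$stop) else 0, numeric(1)))
  n_ticks <- ceiling(tmax * fs_vote) + 1L
  empty <- data.frame(label = character(0), anchor = numeric(0),
                      start = numeric(0), stop = numeric(0),
                      n_supporting_raters = integer(0),
                      stringsAsFactors = FALSE)
  if (n_ticks <= 1L) return(empty)

  votes <- list(attention = integer(n_ticks), distraction = integer(n_ticks))
  for (tr in tracks) {
    iv <- tr$intervals
    for (lab in names(votes)) {
      marked <- logical(n_ticks)
      rows <- which(iv$label == lab)
      for (i in rows) {
        a <- floor(iv$start[i] * fs_vote) + 1L
        b <- min(n_ticks, ceiling(iv$stop[i] * fs_vote))
        if (a <= b) marked[a:b] <- TRUE    # a rater votes once per tick
      }
      votes[[lab]] <- votes[[lab]] + marked
    }
  }
  maj_att <- votes$attention >= need
  maj_dis <- votes$distraction >= need
  winner <- ifelse(maj_att & !maj_dis, "attention",
                   ifelse(maj_dis & !maj_att, "distraction", NA_character_))

  events <- list()
  r <- rle(ifelse(is.na(winner), "none", winner))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    lab <- r$values[j]
    if (lab == "none") next
    t0 <- (starts[j] - 1L) / fs_vote
    t1 <- ends[j] / fs_vote
    if (t1 - t0 < min_event_s) next
    sup <- min(votes[[lab]][starts[j]:ends[j]])
    events[[length(events) + 1L]] <-
      data.frame(label = lab, anchor = t0, start = t0, stop = t1,
                 n_supporting_raters = sup, stringsAsFactors = FALSE)
  }
  if (length(events) == 0L) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Instance-count summary over debates
#'
#' Tallies fused attention/distraction instances per debate and per
#' difficulty condition, with grand totals and per-debate mean and range —
#' the standard per-debate summary table for this kind of dataset.
#'
#' @param events data.frame with columns `label`, `debate_id`, `difficulty`
#'   (and optionally `experience`); typically fused events joined to
#'   manifest metadata.
#' @return list with `per_debate` (one row per debate), `per_difficulty`,
#'   `totals` (named vector), and `per_debate_stats` (mean/min/max of
#'   per-debate instance counts by label).
#' @export
count_instances <- function(events) {
  need <- c("label", "debate_id", "difficulty")
  if (nrow(events) > 0L && !all(need %in% names(events)))
    stop("events need columns ", paste(need, collapse = ", "))
  count2 <- function(df) c(attention = sum(df$label == "attention"),
                           distraction = sum(df$label == "distraction"))
  if (nrow(events) == 0L) {
    return(list(per_debate = data.frame(debate_id = integer(0),
                                        difficulty = character(0),
                                        n_attention = integer(0),
                                        n_distraction = integer(0)),
                per_difficulty = data.frame(difficulty = character(0),
                                            n_attention = integer(0),
                                            n_distraction = integer(0)),
                totals = c(attention = 0L, distraction = 0L),
                per_debate_stats = NULL))
  }
  per_debate <- do.call(rbind, lapply(split(events, events$debate_id),
    function(df) {
      k <- count2(df)
      data.frame(debate_id = df$debate_id[1], difficulty = df$difficulty[1],
                 n_attention = k[["attention"]],
                 n_distraction = k[["distraction"]],
                 stringsAsFactors = FALSE)
    }))
  rownames(per_debate) <- NULL
  per_difficulty <- do.call(rbind, lapply(split(events, events$difficulty),
    function(df) {
      k <- count2(df)
      data.frame(difficulty = df$difficulty[1],
                 n_attention = k[["attention"]],
                 n_distraction = k[["distraction"]],
                 stringsAsFactors = FALSE)
    }))
  rownames(per_difficulty) <- NULL
  totals <- count2(events)
  stats_for <- function(col) c(mean = mean(col), min = min(col),
                               max = max(col))
  list(per_debate = per_debate, per_difficulty = per_difficulty,
       totals = totals,
       per_debate_stats = rbind(attention = stats_for(per_debate$n_attention),
                                distraction = stats_for(per_debate$n_distraction)))
}
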