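pipeline_defaults <- function() {
  list(
    mode = "synth",               # "synth" or "manifest"
    manifest = NULL,              # manifest.csv path in manifest mode
    synth = unclass(synth_config()),
    target_fs = 256,
    bandpass_lo = 0.5, bandpass_hi = 45,
    ocular = TRUE,
    fs_vote = 100, min_event_s = 0.2,
    pre_s = 1.0, epoch_length_s = 2.0,
    bands = c("raw", "delta", "theta", "alpha", "beta"),
    q = 0.05, t_screen = 4,
    decode_bands = c("delta", "theta", "alpha", "beta"),
    decode_models = "rf",
    k = 10, ratios = c(0.6, 0.2, 0.2),
    cap = 200000,
    seed = 1L)
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML config (or takes a list), fills every omitted key with its
#' default (synth mode, 256 Hz, 0.5--45 Hz, FDR level 0.05, k = 10, 60:20:20
#' split, majority cap 200,000), rejects unknown keys, and reports all type
#' and range errors at once. Idempotent: normalizing a normalized config is
#' the identity.
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return The normalized config list (class `pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config))
    config <- yaml::read_yaml(config) %||% list()
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  stopifnot(is.list(config))
  def <- pipeline_defaults()
  errs <- character(0)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    errs <- c(errs, paste("unknown config key(s):",
                          paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(def, config[setdiff(names(config), unknown)])
  # modifyList drops NULL-valued entries; keep the manifest slot explicit
  if (!"manifest" %in% names(cfg)) cfg["manifest"] <- list(NULL)
  cfg <- cfg[names(def)]
  if (is.list(cfg$synth)) {
    syn_unknown <- setdiff(names(cfg$synth), names(def$synth))
    if (length(syn_unknown))
      errs <- c(errs, paste("unknown synth key(s):",
                            paste(syn_unknown, collapse = ", ")))
    cfg$synth <- utils::modifyList(def$synth,
                                   cfg$synth[setdiff(names(cfg$synth),
                                                     syn_unknown)])
  } else errs <- c(errs, "`synth` must be a list")
  if (!cfg$mode %in% c("synth", "manifest"))
    errs <- c(errs, "`mode` must be 'synth' or 'manifest'")
  if (cfg$mode == "manifest" && is.null(cfg$manifest))
    errs <- c(errs, "manifest mode needs a `manifest` path")
  if (!is.numeric(cfg$q) || cfg$q <= 0 || cfg$q >= 1)
    errs <- c(errs, "`q` must be in (0, 1)")
  if (!is.numeric(cfg$k) || cfg$k < 2)
    errs <- c(errs, "`k` must be >= 2")
  if (length(cfg$ratios) != 3 || abs(sum(cfg$ratios) - 1) > 1e-9)
    errs <- c(errs, "`ratios` must be three proportions summing to 1")
  if (!is.numeric(cfg$target_fs) || cfg$target_fs <= 0)
    errs <- c(errs, "`target_fs` must be > 0")
  if (!is.numeric(cfg$cap) || cfg$cap < 1)
    errs <- c(errs, "`cap` must be >= 1")
  bad_m <- setdiff(cfg$decode_models, c("rf", "svm-rbf", "mlp", "lstm",
                                        "cnn1d"))
  if (length(bad_m))
    errs <- c(errs, paste("unknown decode model(s):",
                          paste(bad_m, collapse = ", ")))
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

plog <- function(run, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  message(line)
  cat(line, "\n", file = file.path(run, "run.log"), append = TRUE)
}

stage_path <- function(run, stage) file.path(run, paste0(stage, ".rds"))

# resumable stage: reuse the cached result if present, else compute + cache
run_stage <- function(run, stage, resume, fun) {
  p <- stage_path(run, stage)
  if (resume && file.exists(p)) {
    plog(run, "stage %-11s resumed from cache", stage)
    return(readRDS(p))
  }
  t0 <- Sys.time()
  out <- fun()
  saveRDS(out, p)
  plog(run, "stage %-11s done in %.1f s", stage,
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}

hash_outputs <- function(run) {
  files <- list.files(run, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) return(invisible(NULL))
  h <- tools::md5sum(files)
  utils::write.csv(data.frame(file = basename(names(h)), md5 = unname(h)),
                   file.path(run, "hashes.csv"), row.names = FALSE)
  invisible(h)
}

# gather epochs + fused events for one debate (synth mode, in memory)
process_synth_debate <- function(cfg, scfg, d) {
  deb <- synth_debate(scfg, d)
  # calibration blinks sit in the first ~10 s; detect on a short crop
  head_rec <- recording(deb$recording_a$data[, seq_len(12 * scfg$fs),
                                             drop = FALSE],
                        scfg$fs, deb$recording_a$channels)
  eeg_blinks <- detect_blinks(head_rec, max_events = 5)
  off <- estimate_offset(eeg_blinks, deb$video_blinks)$offset_s
  tracks <- apply_offset(deb$tracks, off, warn_clip = FALSE)
  events <- fuse_majority(tracks, fs_vote = cfg$fs_vote,
                          min_event_s = cfg$min_event_s)
  rec <- preprocess_recording(deb$recording_a, target_fs = cfg$target_fs,
                              lo = cfg$bandpass_lo, hi = cfg$bandpass_hi,
                              ocular = cfg$ocular)
  eps <- extract_epochs(rec, events, pre_s = cfg$pre_s,
                        length_s = cfg$epoch_length_s, debate_id = d)
  meta <- debate_metadata(d)
  if (nrow(events)) {
    events$debate_id <- d
    events$difficulty <- meta$difficulty
    events$experience <- meta$experience
  }
  list(epochs = eps, events = events, offset = off,
       true_offset = scfg$clock_offset_s)
}

process_manifest_debate <- function(cfg, man, i) {
  dir <- dirname(cfg$manifest)
  read_rec <- function(p) {
    fp <- file.path(dir, p)
    if (grepl("\\.csv$", p)) read_recording_csv(fp) else read_recording_bin(fp)
  }
  rec_raw <- read_rec(man$recording_a[i])
  tracks <- lapply(strsplit(man$annotations[i], ";")[[1]], function(p)
    parse_rater_csv(file.path(dir, p)))
  vb <- utils::read.csv(file.path(dir, man$video_blinks[i]))$blink_time_s
  eeg_blinks <- detect_blinks(rec_raw, max_events = length(vb))
  off <- estimate_offset(eeg_blinks, vb)$offset_s
  tracks <- apply_offset(tracks, off, warn_clip = FALSE)
  events <- fuse_majority(tracks, fs_vote = cfg$fs_vote,
                          min_event_s = cfg$min_event_s)
  rec <- preprocess_recording(rec_raw, target_fs = cfg$target_fs,
                              lo = cfg$bandpass_lo, hi = cfg$bandpass_hi,
                              ocular = cfg$ocular)
  eps <- extract_epochs(rec, events, pre_s = cfg$pre_s,
                        length_s = cfg$epoch_length_s,
                        debate_id = man$debate_id[i])
  if (nrow(events)) {
    events$debate_id <- man$debate_id[i]
    events$difficulty <- man$difficulty[i]
    events$experience <- man$experience[i]
  }
  list(epochs = eps, events = events, offset = off,
       true_offset = man$clock_offset_s[i])
}

#' Generate a synthetic study in memory
#'
#' Runs the front half of the pipeline — synthesis, blink synchronization,
#' annotation fusion, preprocessing, epoch extraction — debate by debate
#' without writing recordings to disk, and returns the labeled epochs with
#' their fused events and the per-debate sync table. This is the standard
#' entry point for statistical and decoding experiments on synthetic data.
#'
#' @param config a [synth_config()].
#' @param pipeline optional pipeline settings (see [validate_config()]);
#'   the synth settings inside it are ignored in favour of `config`.
#' @return list(epochs, events, sync) where `events` carries debate id,
#'   difficulty and experience metadata and `sync` compares estimated and
#'   true clock offsets per debate.
#' @export
synth_epochs <- function(config = synth_config(), pipeline = list()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- validate_config(pipeline)
  gathered <- lapply(seq_len(config$n_debates), function(d)
    process_synth_debate(cfg, config, d))
  list(epochs = do.call(c, lapply(gathered, `[[`, "epochs")),
       events = do.call(rbind, lapply(gathered, `[[`, "events")),
       sync = data.frame(
         debate = seq_along(gathered),
         offset_est = vapply(gathered, `[[`, numeric(1), "offset"),
         offset_true = vapply(gathered, `[[`, numeric(1), "true_offset")))
}

#' Run the full decoding pipeline
#'
#' Orchestrates the complete framework with one config: synthetic generation
#' (or manifest-driven loading), blink synchronization, annotation fusion,
#' preprocessing and epoching, wavelet band features, channel statistics
#' with FDR topographies, and band-wise classification. Every stage's result
#' is cached in the run directory (making reruns resumable per stage) and
#' the tabular outputs are written as CSV with an md5 hash manifest.
#'
#' @param config a YAML path or config list (see [validate_config()]).
#' @param out_dir run directory (created).
#' @param resume reuse cached stage results found in `out_dir`?
#' @return list(config, counts, chi_square, stat_maps, thresholds,
#'   topography, reports, comparison, sync) — also cached in `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir, resume = FALSE) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plog(out_dir, "run started (mode=%s, seed=%d)", cfg$mode, cfg$seed)

  gathered <- run_stage(out_dir, "ingest", resume, function() {
    if (cfg$mode == "synth") {
      scfg <- do.call(synth_config, cfg$synth)
      lapply(seq_len(scfg$n_debates), function(d)
        process_synth_debate(cfg, scfg, d))
    } else {
      man <- utils::read.csv(cfg$manifest, stringsAsFactors = FALSE)
      lapply(seq_len(nrow(man)), function(i)
        process_manifest_debate(cfg, man, i))
    }
  })
  epochs <- do.call(c, lapply(gathered, `[[`, "epochs"))
  events <- do.call(rbind, lapply(gathered, `[[`, "events"))
  sync_tab <- data.frame(
    debate = seq_along(gathered),
    offset_est = vapply(gathered, `[[`, numeric(1), "offset"),
    offset_true = vapply(gathered, `[[`, numeric(1), "true_offset"))
  utils::write.csv(sync_tab, file.path(out_dir, "sync.csv"),
                   row.names = FALSE)
  plog(out_dir, "%d epochs from %d debates (%d attention / %d distraction)",
       length(epochs), length(gathered),
       sum(events$label == "attention"), sum(events$label == "distraction"))

  counts <- run_stage(out_dir, "counts", resume, function()
    count_instances(events))
  utils::write.csv(counts$per_debate, file.path(out_dir, "counts.csv"),
                   row.names = FALSE)

  chi <- run_stage(out_dir, "chisq", resume, function() {
    tab <- table(factor(events$label, c("attention", "distraction")),
                 factor(events$experience, c("less", "more")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NULL
    else chi_square_2x2(tab)
  })

  feats <- run_stage(out_dir, "spectral", resume, function()
    epoch_features(epochs, bands = cfg$bands))
  fm <- do.call(cbind, lapply(names(feats$features), function(b) {
    m <- feats$features[[b]]
    colnames(m) <- paste(b, colnames(m), sep = "_")
    m
  }))
  utils::write.csv(cbind(data.frame(label = feats$labels,
                                    debate_id = feats$debate_id), fm),
                   file.path(out_dir, "features.csv"), row.names = FALSE)

  stat_maps <- run_stage(out_dir, "stats", resume, function()
    channel_stat_maps(feats$features, feats$labels, q = cfg$q,
                      t_screen = cfg$t_screen))
  topo <- topography_mask(stat_maps)
  utils::write.csv(as.data.frame(stat_maps),
                   file.path(out_dir, "stat_maps.csv"), row.names = FALSE)
  utils::write.csv(topo, file.path(out_dir, "topography.csv"),
                   row.names = FALSE)

  reports <- run_stage(out_dir, "decode", resume, function() {
    out <- list()
    for (band in cfg$decode_bands) {
      ws <- make_windows(epochs, band)
      cap <- min(cfg$cap, min(table(ws$labels)))
      ws <- balance_subsample(ws, cap = cap, seed = derive_seed(cfg$seed, 5L))
      for (model in cfg$decode_models) {
        rep <- if (model %in% c("lstm", "cnn1d"))
          train_eval_split(ws, model, ratios = cfg$ratios, seed = cfg$seed)
        else
          train_eval_kfold(ws, model, k = cfg$k, seed = cfg$seed)
        out[[paste(band, model, sep = "_")]] <- rep
        plog(out_dir, "decode %s / %s: accuracy %.3f", band, model,
             rep$accuracy)
      }
    }
    out
  })
  comparison <- if (length(reports)) band_comparison(reports) else
    data.frame(band = character(0), model = character(0),
               protocol = character(0), accuracy = numeric(0),
               seed = integer(0), n_eval = integer(0), best = logical(0))
  utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  hash_outputs(out_dir)
  plog(out_dir, "run complete")
  res <- list(config = cfg, counts = counts, chi_square = chi,
              stat_maps = stat_maps,
              thresholds = attr(stat_maps, "thresholds"),
              topography = topo, reports = reports,
              comparison = comparison, sync = sync_tab)
  saveRDS(res, file.path(out_dir, "result.rds"))
  invisible(res)
}
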