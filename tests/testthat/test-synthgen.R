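test_that("identical config and seed give bit-identical output", {
  cfg <- tiny_config(seed = 42)
  a <- generate_recording(cfg, 1)
  b <- generate_recording(cfg, 1)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$intervals, b$truth$intervals)
  expect_identical(simulate_raters(a$truth, cfg), simulate_raters(b$truth, cfg))
  # different debate index or debater draws a different stream
  c1 <- generate_recording(cfg, 2)
  expect_false(identical(a$recording$data, c1$recording$data))
  d2 <- generate_recording(cfg, 1, a$truth, debater = 2L)
  expect_false(identical(a$recording$data, d2$recording$data))
})

test_that("config validation rejects impossible settings", {
  expect_error(synth_config(fs = 0), "fs")
  expect_error(synth_config(debate_length_s = -5), "debate_length_s")
  expect_error(synth_config(n_channels = 16), "fixed at 32")
  expect_error(synth_config(rater_miss_prob = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(effect_groups = list(alpha = "Nope1",
                                                 theta = "P3",
                                                 delta = "Cz")),
               "unknown effect channel")
})

test_that("a planted alpha effect raises band amplitude on its channels (FFT oracle)", {
  cfg <- tiny_config(seed = 3, debate_length_s = 120,
                     effect_alpha_leftfrontal = 2,
                     effect_theta_leftparietal = 0,
                     effect_delta_central = 0)
  out <- generate_recording(cfg, 1)
  rec <- out$recording
  iv <- out$truth$intervals
  f3 <- rec$data[match("F3", rec$channels), ]
  amp_in <- function(rows) {
    vapply(which(rows), function(i) {
      a <- floor(iv$start[i] * rec$fs) + 1
      b <- floor(iv$stop[i] * rec$fs)
      fft_band_amplitude(f3[a:b], rec$fs, 8, 13)
    }, numeric(1))
  }
  amp_att <- amp_in(iv$label == "attention")
  amp_dis <- amp_in(iv$label == "distraction")
  expect_gt(mean(amp_att), mean(amp_dis))
})

test_that("null effects leave attention and distraction exchangeable", {
  # with zero planted effects the two-sample t on band amplitude should
  # behave like a null test: p-values not systematically small across seeds
  ps <- vapply(1:8, function(s) {
    cfg <- tiny_config(seed = s, debate_length_s = 120,
                       effect_alpha_leftfrontal = 0,
                       effect_theta_leftparietal = 0,
                       effect_delta_central = 0)
    out <- generate_recording(cfg, 1)
    iv <- out$truth$intervals
    f3 <- out$recording$data[match("F3", out$recording$channels), ]
    amp <- function(i) {
      a <- floor(iv$start[i] * 512) + 1; b <- floor(iv$stop[i] * 512)
      fft_band_amplitude(f3[a:b], 512, 8, 13)
    }
    x <- vapply(which(iv$label == "attention"), amp, numeric(1))
    y <- vapply(which(iv$label == "distraction"), amp, numeric(1))
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    t.test(x, y)$p.value
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 4)
  expect_lte(sum(ps < 0.05), 2)          # about the nominal false-positive rate
  expect_gt(mean(ps), 0.2)               # not collapsed toward zero
})

test_that("planted effect strength moves the group t statistic monotonically", {
  tvals <- vapply(c(0, 2, 4), function(eff) {
    mean(vapply(1:2, function(s) {
      cfg <- tiny_config(seed = s, debate_length_s = 120,
                         effect_theta_leftparietal = eff,
                         effect_alpha_leftfrontal = 0,
                         effect_delta_central = 0)
      out <- generate_recording(cfg, 1)
      iv <- out$truth$intervals
      p3 <- out$recording$data[match("P3", out$recording$channels), ]
      amp <- function(i) {
        a <- floor(iv$start[i] * 512) + 1; b <- floor(iv$stop[i] * 512)
        fft_band_amplitude(p3[a:b], 512, 4, 8)
      }
      x <- vapply(which(iv$label == "attention"), amp, numeric(1))
      y <- vapply(which(iv$label == "distraction"), amp, numeric(1))
      abs(t.test(x, y)$statistic)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(tvals) > 0))
})

test_that("noiseless raters reproduce truth; total misses empty the tracks", {
  cfg0 <- tiny_config(seed = 6, rater_boundary_jitter_sd = 0,
                      rater_miss_prob = 0)
  truth <- generate_truth(cfg0, 1)
  for (tr in simulate_raters(truth, cfg0))
    expect_equal(tr$intervals, truth$intervals)
  cfg1 <- tiny_config(seed = 6, rater_miss_prob = 1)
  for (tr in simulate_raters(generate_truth(cfg1, 1), cfg1))
    expect_equal(nrow(tr$intervals), 0)
})

test_that("majority fusion recovers most true events from noisy raters", {
  hits <- 0; total <- 0
  for (s in 1:3) {
    cfg <- tiny_config(seed = s, debate_length_s = 120)
    truth <- generate_truth(cfg, 1)
    ev <- fuse_majority(simulate_raters(truth, cfg))
    for (i in seq_len(nrow(truth$intervals))) {
      iv <- truth$intervals[i, ]
      total <- total + 1
      # matched if a fused event of the same label overlaps the true one
      hit <- any(ev$label == iv$label & ev$start < iv$stop + 0.5 &
                   ev$stop > iv$start - 0.5)
      hits <- hits + hit
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("calibration blinks: exactly five, video clock lags by the offset", {
  cfg <- tiny_config(seed = 8, clock_offset_s = 0.25)
  out <- generate_recording(cfg, 1)
  cal <- generate_calibration_blinks(out$recording, out$truth, cfg)
  expect_length(cal$eeg_blinks, 5)
  expect_equal(cal$video_blinks, cal$eeg_blinks - 0.25)
  expect_true(all(diff(cal$eeg_blinks) >= 0.5))
  cfg0 <- tiny_config(seed = 8, clock_offset_s = 0)
  cal0 <- generate_calibration_blinks(out$recording, out$truth, cfg0)
  expect_equal(cal0$video_blinks, cal0$eeg_blinks)
  short <- recording(out$recording$data[, 1:(5 * 512)], 512,
                     out$recording$channels)
  expect_error(generate_calibration_blinks(short, out$truth, cfg),
               "too short")
})

test_that("dataset writer produces a complete, even, reproducible manifest", {
  cfg <- tiny_config(n_debates = 4, debate_length_s = 30, seed = 12)
  dir1 <- file.path(tempdir(), "ds1"); dir2 <- file.path(tempdir(), "ds2")
  man <- generate_dataset(cfg, dir1)
  expect_equal(nrow(man), 4)
  recs <- c(man$recording_a, man$recording_b)
  expect_length(recs, 8)                       # two debaters per debate
  expect_true(all(file.exists(file.path(dir1, recs))))
  expect_equal(sort(as.character(man$difficulty)), c("easy", "easy", "hard", "hard"))
  generate_dataset(cfg, dir2)
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  expect_identical(tools::md5sum(file.path(dir1, man$recording_a[1]))[[1]],
                   tools::md5sum(file.path(dir2, man$recording_a[1]))[[1]])
  unlink(c(dir1, dir2), recursive = TRUE)
})
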