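test_that("rater CSV round-trips and rejects malformed rows with line numbers", {
  iv <- data.frame(start = c(5.25, 1.001, 12), stop = c(7.5, 3.75, 20),
                   label = c("attention", "distraction", "attention"))
  tr <- rater_track("rater1", iv)
  expect_equal(tr$intervals$start, sort(iv$start))   # sorted on construction
  path <- tempfile(fileext = ".csv")
  write_rater_csv(tr, path)
  back <- parse_rater_csv(path)
  expect_equal(back$intervals, tr$intervals)
  expect_equal(back$rater_id, "rater1")

  # malformed rows: reversed interval, unknown label, non-numeric time
  bad <- data.frame(rater_id = "r2",
                    behavior = c("attention", "bored", "attention",
                                 "distraction"),
                    start_s = c(1, 2, 5, "x"),
                    stop_s = c(0.5, 3, 6, 9))
  path2 <- tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE)
  expect_warning(tr2 <- parse_rater_csv(path2), "line 2.*line 3.*line 5")
  expect_equal(nrow(tr2$intervals), 1)
  expect_equal(attr(tr2, "rejected")$line, c(2L, 3L, 5L))
  expect_error(parse_rater_csv("no/such/file.csv"), "not found")
})

test_that("unanimous raters fuse to the common intervals", {
  iv <- data.frame(start = c(10, 30), stop = c(12, 35),
                   label = c("attention", "distraction"))
  tracks <- lapply(1:3, function(r) rater_track(paste0("r", r), iv))
  ev <- fuse_majority(tracks)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$label, c("attention", "distraction"))
  expect_equal(ev$start, c(10, 30), tolerance = 0.011)
  expect_equal(ev$n_supporting_raters, c(3L, 3L))
  expect_equal(ev$anchor, ev$start)
})

test_that("two of three raters suffice; direct conflicts produce no event", {
  att <- data.frame(start = 10, stop = 12, label = "attention")
  dis <- data.frame(start = 10, stop = 12, label = "distraction")
  none <- data.frame(start = numeric(0), stop = numeric(0),
                     label = character(0))
  # A and B mark attention, C silent -> retained with 2 supporters
  ev <- fuse_majority(list(rater_track("a", att), rater_track("b", att),
                           rater_track("c", none)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_supporting_raters, 2L)
  # A says attention, B says distraction, C silent -> no event
  # (with 3 raters neither label reaches the 2-vote majority)
  ev2 <- fuse_majority(list(rater_track("a", att), rater_track("b", dis),
                            rater_track("c", none)))
  expect_equal(nrow(ev2), 0)
  # with 2 raters each label reaches 1 = ceil(2/2): both majorities -> none
  ev3 <- fuse_majority(list(rater_track("a", att), rater_track("b", dis)))
  expect_equal(nrow(ev3), 0)
  expect_error(fuse_majority(list()), "at least one")
})

test_that("fusion agrees with a tick-wise vote oracle on a toy timeline", {
  # 10 ticks at 1 Hz; rater intervals chosen to exercise partial overlaps
  t1 <- rater_track("r1", data.frame(start = 0, stop = 6, label = "attention"))
  t2 <- rater_track("r2", data.frame(start = 2, stop = 8, label = "attention"))
  t3 <- rater_track("r3", data.frame(start = c(0, 7), stop = c(1, 10),
                                     label = c("distraction", "distraction")))
  tracks <- list(t1, t2, t3)
  ev <- fuse_majority(tracks, fs_vote = 1, min_event_s = 1)
  # oracle: per-tick votes (ticks are [k, k+1) intervals)
  votes_at <- function(t, lab) sum(vapply(tracks, function(tr)
    any(tr$intervals$label == lab & tr$intervals$start <= t &
          tr$intervals$stop > t), logical(1)))
  for (i in seq_len(nrow(ev))) {
    ticks <- seq(ev$start[i], ev$stop[i] - 1)
    expect_true(all(vapply(ticks, function(t)
      votes_at(t, ev$label[i]) >= 2, logical(1))))
  }
  # attention should win on [2, 6) only (both r1 and r2 cover it)
  expect_true(any(ev$label == "attention" & ev$start <= 2 & ev$stop >= 6))
})

test_that("fusion is permutation-invariant and monotone in agreeing raters", {
  cfg <- tiny_config(seed = 5)
  truth <- generate_truth(cfg, 1)
  tracks <- simulate_raters(truth, cfg)
  ev <- fuse_majority(tracks)
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    expect_equal(fuse_majority(tracks[perm]), ev)
  }
  # an extra rater that repeats rater 1 can only preserve/extend events
  ev2 <- fuse_majority(c(tracks, list(rater_track("extra",
                                                  tracks[[1]]$intervals))))
  for (i in seq_len(nrow(ev))) {
    overlap <- ev2$label == ev$label[i] & ev2$start <= ev$anchor[i] &
      ev2$stop > ev$anchor[i]
    expect_true(any(overlap) ||
                  ev$n_supporting_raters[i] >= 2)  # still majority-backed
  }
  expect_true(all(ev$n_supporting_raters >= 2))
})

test_that("instance counting reproduces per-condition totals and ground truth", {
  # per-difficulty segment counts summing to the dataset totals
  mk <- function(n, lab, diff) if (n == 0) NULL else
    data.frame(label = rep(lab, n), debate_id = paste0(diff, "x"),
               difficulty = diff)
  events <- rbind(mk(46, "attention", "easy"), mk(142, "distraction", "easy"),
                  mk(138, "attention", "hard"), mk(160, "distraction", "hard"))
  cnt <- count_instances(events)
  expect_equal(unname(cnt$totals["distraction"]), 302)
  expect_equal(unname(cnt$totals["attention"]), 184)
  expect_equal(cnt$per_difficulty$n_attention,
               c(46, 138)[order(c("easy", "hard"))])
  # empty input -> all-zero table
  cnt0 <- count_instances(events[0, ])
  expect_equal(unname(cnt0$totals), c(0L, 0L))
  # noiseless raters: fused counts equal ground-truth interval counts
  cfg <- tiny_config(seed = 2, rater_boundary_jitter_sd = 0,
                     rater_miss_prob = 0)
  truth <- generate_truth(cfg, 1)
  ev <- fuse_majority(simulate_raters(truth, cfg))
  expect_equal(sum(ev$label == "attention"),
               sum(truth$intervals$label == "attention"))
  expect_equal(sum(ev$label == "distraction"),
               sum(truth$intervals$label == "distraction"))
})
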