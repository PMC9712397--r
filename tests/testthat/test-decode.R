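# toy epochs with a mean shift on two channels; band "raw" keeps the test
# independent of the wavelet stage
toy_epochs <- function(n = 60, shift = 1.5, fs = 64, n_ch = 8, seed = 1,
                       len = 128) {
  ch <- paste0("ch", seq_len(n_ch))
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      lab <- if (i %% 2 == 0) "attention" else "distraction"
      m <- matrix(rnorm(n_ch * len), n_ch)
      if (lab == "attention") m[1:2, ] <- m[1:2, ] + shift
      epoch(m, fs, lab, debate_id = 1, anchor = i, channels = ch)
    })
  })
}

test_that("windowing cuts epochs into label-inheriting non-overlapping pieces", {
  eps <- toy_epochs(n = 1)
  ws <- make_windows(eps, "raw")
  expect_equal(dim(ws$x), c(4, 32, 8))          # 128 / 32 windows
  expect_equal(unique(ws$labels), eps[[1]]$label)
  expect_equal(ws$epoch_id, rep(1L, 4))
  # windows tile the epoch without overlap
  expect_equal(t(ws$x[1, , ]), eps[[1]]$data[, 1:32])
  expect_equal(t(ws$x[2, , ]), eps[[1]]$data[, 33:64])
  expect_equal(dim(make_windows(list(), "raw")$x)[1], 0)
  # 512-sample epochs at 256 Hz yield the canonical 16 windows
  ep512 <- epoch(matrix(rnorm(32 * 512), 32), 256, "attention", 1, 10,
                 biosemi32_montage()$channel)
  expect_equal(dim(make_windows(list(ep512), "raw")$x)[1], 16)
})

test_that("majority-class subsampling balances classes reproducibly", {
  eps <- c(toy_epochs(n = 25, seed = 2),
           toy_epochs(n = 50, seed = 3))     # imbalance across labels
  ws <- make_windows(eps, "raw")
  tab <- table(ws$labels)
  maj <- max(tab); mino <- min(tab)
  bal <- balance_subsample(ws, seed = 4)
  expect_equal(as.integer(table(bal$labels)), c(mino, mino))
  bal2 <- balance_subsample(ws, seed = 4)
  expect_identical(bal$x, bal2$x)
  cap <- mino + 4
  capped <- balance_subsample(ws, cap = cap, seed = 4)
  expect_equal(max(as.integer(table(capped$labels))), cap)
  expect_error(balance_subsample(ws, cap = maj + 1), "exceeds")
})

test_that("no epoch's windows straddle folds or partitions (leakage guard)", {
  eps <- toy_epochs(n = 40)
  ws <- make_windows(eps, "raw")
  folds <- eegattend:::epoch_folds(ws, k = 5, seed = 1)
  expect_true(all(tapply(folds, ws$epoch_id,
                         function(f) length(unique(f))) == 1))
  parts <- eegattend:::split_partitions(ws, c(0.6, 0.2, 0.2), seed = 1)
  expect_true(all(tapply(parts, ws$epoch_id,
                         function(p) length(unique(p))) == 1))
  expect_setequal(unique(parts), c("train", "val", "test"))
})

test_that("classical models separate a constructed two-class problem under CV", {
  ws <- balance_subsample(make_windows(toy_epochs(n = 60), "raw"), seed = 1)
  for (model in c("rf", "svm-rbf", "mlp")) {
    rep <- train_eval_kfold(ws, model, k = 5, seed = 2)
    expect_gte(rep$accuracy, 0.95)
    expect_equal(sum(rep$confusion), rep$n_eval)
    expect_equal(sum(diag(rep$confusion)) / sum(rep$confusion),
                 rep$accuracy)
  }
  # identical seed, identical report for the random forest
  r1 <- train_eval_kfold(ws, "rf", k = 5, seed = 7)
  r2 <- train_eval_kfold(ws, "rf", k = 5, seed = 7)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$confusion, r2$confusion)
  expect_error(train_eval_kfold(ws, "rf", k = 100, seed = 1), "exceeds")
})

test_that("label permutation collapses accuracy to chance", {
  ws <- balance_subsample(make_windows(toy_epochs(n = 60), "raw"), seed = 1)
  # permute labels at the epoch level, keeping windows grouped
  eps_ids <- unique(ws$epoch_id)
  lab_of <- ws$labels[match(eps_ids, ws$epoch_id)]
  with_seed(11, {
    perm <- sample(lab_of)
  })
  ws$labels <- perm[match(ws$epoch_id, eps_ids)]
  rep <- train_eval_kfold(ws, "rf", k = 5, seed = 2)
  # windows within an epoch are correlated, so the chance CI uses the epoch
  # as the independent unit (here 4 windows per epoch)
  n_epochs <- length(eps_ids)
  half_width <- 1.96 * sqrt(0.25 / n_epochs)
  expect_lt(abs(rep$accuracy - 0.5), half_width + 0.02)
})

test_that("sequence models beat chance on the constructed problem (60:20:20)", {
  ws <- balance_subsample(make_windows(toy_epochs(n = 80), "raw"), seed = 1)
  for (model in c("lstm", "cnn1d")) {
    rep <- train_eval_split(ws, model, seed = 3,
                            opts = list(hidden = 8, filters = 8,
                                        epochs = 25))
    expect_gte(rep$accuracy, 0.9)
    expect_equal(rep$protocol, "60:20:20")
  }
})

test_that("band comparison tabulates reports and flags ties for best", {
  ws <- balance_subsample(make_windows(toy_epochs(n = 40), "raw"), seed = 1)
  r1 <- train_eval_kfold(ws, "rf", k = 4, seed = 2)
  tab1 <- band_comparison(list(r1))
  expect_equal(nrow(tab1), 1)
  expect_true(tab1$best)
  r2 <- r1; r2$model <- "rf2"                 # tie at identical accuracy
  tab2 <- band_comparison(list(r1, r2))
  expect_equal(sum(tab2$best), 2)
  expect_error(band_comparison(list()), "at least one")
})

test_that("transfer evaluation: self-transfer is optimistic, schema must match", {
  ws <- balance_subsample(make_windows(toy_epochs(n = 60), "raw"), seed = 1)
  cv <- train_eval_kfold(ws, "rf", k = 5, seed = 2)
  self <- evaluate_transfer(ws, ws, "rf", seed = 2)
  expect_gte(self$accuracy, cv$accuracy)
  other <- make_windows(toy_epochs(n = 10, n_ch = 4), "raw")
  expect_error(evaluate_transfer(ws, other), "schema mismatch")
  wrong_band <- make_windows(toy_epochs(n = 10), "raw")
  wrong_band$band <- "theta"
  expect_error(evaluate_transfer(ws, wrong_band), "band mismatch")
})
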