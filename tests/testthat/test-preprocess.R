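test_that("downsampling halves the grid and preserves in-band tones", {
  t512 <- (0:5119) / 512
  tone <- sin(2 * pi * 10 * t512)
  rec <- recording(rbind(tone, tone), 512, c("Fp1", "Fp2"))
  ds <- downsample(rec, 256)
  expect_equal(ncol(ds$data), 2560)
  expect_equal(ds$fs, 256)
  # FFT oracle: the 10 Hz line survives within 1% amplitude
  amp <- function(x, fs, f) {
    n <- length(x); X <- abs(fft(x)) / n * 2
    X[round(f * n / fs) + 1]
  }
  expect_equal(amp(ds$data[1, ], 256, 10), amp(tone, 512, 10),
               tolerance = 0.01)
  # equal rates bypass exactly; non-integer factors are rejected
  expect_identical(downsample(rec, 512)$data, rec$data)
  expect_error(downsample(rec, 300), "integer multiple")
})

test_that("band-pass keeps 10 Hz, crushes 90 Hz by 40 dB, and maps zero to zero", {
  fs <- 256
  n <- fs * 8
  tt <- (0:(n - 1)) / fs
  mk_rec <- function(x) recording(rbind(x, x), fs, c("Fp1", "Fp2"))
  amp <- function(x, f) { X <- abs(fft(x)) / length(x) * 2; X[f * 8 + 1] }
  bp10 <- bandpass(mk_rec(sin(2 * pi * 10 * tt)))
  expect_equal(amp(bp10$data[1, ], 10), 1, tolerance = 0.05)
  bp90 <- bandpass(mk_rec(sin(2 * pi * 90 * tt)))
  expect_lt(amp(bp90$data[1, ], 90), 10^(-40 / 20))
  expect_equal(bandpass(mk_rec(numeric(n)))$data, mk_rec(numeric(n))$data)
  expect_error(bandpass(mk_rec(numeric(n)), lo = 50, hi = 40), "invalid band")
  expect_error(bandpass(mk_rec(numeric(n)), lo = 0.5, hi = 200),
               "invalid band")
})

test_that("ocular regression strips blinks but leaves oscillations alone", {
  fs <- 256
  dur <- 60                       # least-squares removes ~1 dof per channel,
                                  # a 1/sqrt(n) relative change, so use 60 s
  with_seed(31, {
    base <- matrix(rnorm(32 * fs * dur, sd = 2), 32)
  })
  ch <- biosemi32_montage()$channel
  tt <- (0:(fs * dur - 1)) / fs
  alpha_sig <- 4 * sin(2 * pi * 10 * tt)
  base[match("O1", ch), ] <- base[match("O1", ch), ] + alpha_sig
  clean_rec <- recording(base, fs, ch)
  # no blinks: output is essentially the input
  out0 <- remove_ocular(clean_rec)
  expect_lt(sqrt(sum((out0$data - clean_rec$data)^2) /
                   sum(clean_rec$data^2)), 0.01)
  # with blinks: frontal blink energy drops by >= 80%
  tpl <- eegattend:::blink_template(fs, 0.4, 120)
  w <- eegattend:::blink_weights(ch)
  times <- seq(2, 58, by = 2.5)
  dirty <- clean_rec
  dirty$data <- eegattend:::add_transient(dirty$data, fs, times, tpl, w)
  out <- remove_ocular(dirty)
  fp1 <- match("Fp1", ch)
  blink_energy <- function(m) {
    d <- m[fp1, ] - clean_rec$data[fp1, ]      # blink component only
    sum(d^2)
  }
  expect_lte(blink_energy(out$data) / blink_energy(dirty$data), 0.2)
  # 10 Hz content on O1 preserved within 5% (FFT oracle)
  amp10 <- function(m) {
    x <- m[match("O1", ch), ]
    X <- abs(fft(x)) / length(x) * 2
    X[10 * dur + 1]
  }
  expect_equal(amp10(out$data), amp10(clean_rec$data), tolerance = 0.05)
  # degenerate proxy: zero-variance frontal channels -> warning, no-op
  flat <- recording(matrix(0, 32, fs * 12), fs, ch)
  expect_warning(out_flat <- remove_ocular(flat), "zero variance")
  expect_equal(out_flat$data, flat$data)
})

test_that("average re-referencing zeroes the channel mean and is idempotent", {
  with_seed(7, {
    m <- matrix(rnorm(32 * 1000), 32)
  })
  rec <- recording(m, 256, biosemi32_montage()$channel)
  rr <- rereference_average(rec)
  expect_lt(max(abs(colMeans(rr$data))), 1e-10)
  expect_equal(rereference_average(rr)$data, rr$data, tolerance = 1e-12)
  # a constant offset on every channel vanishes entirely
  const <- recording(matrix(5, 4, 100), 256, c("Fp1", "Fp2", "F3", "F4"))
  expect_equal(unname(rereference_average(const)$data), matrix(0, 4, 100))
  expect_error(rereference_average(recording(matrix(1, 1, 10), 256, "Fp1")),
               ">= 2 channels")
})

test_that("epoch extraction uses floor-based half-open 2-s windows", {
  fs <- 256
  with_seed(13, {
    m <- matrix(rnorm(32 * fs * 40), 32)
  })
  rec <- recording(m, fs, biosemi32_montage()$channel)
  events <- data.frame(label = c("attention", "distraction", "attention"),
                       anchor = c(30.0, 5.5, 0.5))
  expect_message(eps <- extract_epochs(rec, events, debate_id = 7),
                 "skipped 1")
  expect_length(eps, 2)                      # anchor 0.5 underflows
  expect_equal(attr(eps, "n_skipped"), 1)
  # anchor 30 s -> 0-based samples [7424, 7936) -> columns 7425:7936
  expect_equal(unname(eps[[1]]$data), m[, 7425:7936])
  expect_equal(ncol(eps[[1]]$data), 512)
  expect_equal(eps[[1]]$label, "attention")
  expect_equal(eps[[1]]$debate_id, 7)
  # every epoch has exactly round(length_s * fs) samples
  for (ep in eps) expect_equal(ncol(ep$data), round(2 * fs))
})

test_that("epochs serialize to an index + files and read back identically", {
  fs <- 256
  ch <- biosemi32_montage()$channel
  eps <- lapply(1:3, function(i)
    epoch(matrix(rnorm(32 * 512), 32), fs,
          c("attention", "distraction", "attention")[i], i, i * 10, ch))
  dir <- file.path(tempdir(), "epochs_rt")
  idx <- write_epochs(eps, dir)
  expect_equal(nrow(idx), 3)
  back <- read_epochs(dir)
  for (i in 1:3) {
    expect_equal(unname(back[[i]]$data), unname(eps[[i]]$data),
                 tolerance = 1e-6)
    expect_equal(back[[i]]$label, eps[[i]]$label)
  }
  unlink(dir, recursive = TRUE)
})

test_that("the full chain is deterministic end to end", {
  cfg <- tiny_config(seed = 17)
  deb <- synth_debate(cfg, 1)
  r1 <- preprocess_recording(deb$recording_a)
  r2 <- preprocess_recording(deb$recording_a)
  expect_identical(r1$data, r2$data)
})
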