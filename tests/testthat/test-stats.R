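test_that("channel t-test matches the pooled closed form and screens at |t| >= 4", {
  # hand-computed pooled two-sample t for {1,2,3} vs {7,8,9}:
  # diff = -6, sp^2 = 1, se = sqrt(2/3), t = -6/sqrt(2/3)
  x <- matrix(c(1, 2, 3), ncol = 1)
  y <- matrix(c(7, 8, 9), ncol = 1)
  res <- channel_ttest(x, y)
  expect_equal(res$t, -6 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(res$t), df = 4), tolerance = 1e-10)
  expect_true(res$screened)
  # identical groups: t = 0, p = 1, not screened
  res0 <- channel_ttest(x, x)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_false(res0$screened)
  # screening flag fires exactly at the threshold
  set.seed(4)
  a <- matrix(rnorm(40, 0), ncol = 2)
  b <- matrix(rnorm(40, 1), ncol = 2)
  r <- channel_ttest(a, b)
  expect_equal(r$screened, abs(r$t) >= 4)
  expect_error(channel_ttest(a[1, , drop = FALSE], b), "at least 2")
})

test_that("BH step-up matches its brute-force definition across many p-vectors", {
  grid <- c(0.001, 0.005, 0.01, 0.02, 0.04, 0.05, 0.2, 0.5, 0.9, 1)
  with_seed(11, {
    for (rep in 1:100) {
      m <- sample(1:12, 1)
      p <- sample(grid, m, replace = TRUE)
      got <- fdr_bh(p, 0.05)
      want <- brute_bh(p, 0.05)
      expect_identical(got$mask, want$mask)
      expect_equal(got$threshold, want$threshold)
      # cross-check against the standard adjusted-p route
      expect_identical(got$mask, p.adjust(p, "BH") <= 0.05)
    }
  })
})

test_that("BH worked examples: realized thresholds and monotone behaviour", {
  r1 <- fdr_bh(rep(0.001, 10), 0.05)
  expect_true(all(r1$mask))
  expect_equal(r1$threshold, 0.001)
  r2 <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.2), 0.05)
  expect_identical(r2$mask, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(r2$threshold, 0.04)
  # appending a p = 1 entry re-runs the step-up with a larger m; the result
  # must track the brute-force oracle exactly (here the stricter per-rank
  # thresholds empty the significant set)
  p3 <- c(0.01, 0.02, 0.03, 0.04, 0.2, 1)
  r3 <- fdr_bh(p3, 0.05)
  expect_identical(r3$mask, brute_bh(p3, 0.05)$mask)
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("topography masking zeroes non-significant channels and joins coordinates", {
  mont <- biosemi32_montage()
  sm <- data.frame(band = "alpha", channel = mont$channel,
                   t = seq(-3, 3, length.out = 32),
                   p = runif(32),
                   screened = FALSE,
                   significant = rep(c(TRUE, FALSE), 16))
  topo <- topography_mask(sm)
  expect_equal(topo$t_display[!topo$significant], rep(0, 16))
  expect_equal(topo$t_display[topo$significant], sm$t[sm$significant])
  expect_equal(topo$x, mont$x)
  sm_bad <- sm; sm_bad$channel[1] <- "XX1"
  expect_error(topography_mask(sm_bad), "missing montage")
})

test_that("2x2 chi-square matches the hand-computed Pearson statistic with df 1", {
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$chisq, 0)
  r <- chi_square_2x2(matrix(c(20, 10, 10, 20), 2, 2))
  # E = 15 everywhere, sum((O-E)^2/E) = 4 * 25/15 = 20/3
  expect_equal(r$chisq, 20 / 3, tolerance = 1e-10)
  expect_equal(r$df, 1)
  expect_equal(r$p, pchisq(20 / 3, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
  expect_error(chi_square_2x2(matrix(1:6, 3, 2)), "2x2")
})

test_that("two-sample power is calibrated: null limit, monotonicity, Monte-Carlo", {
  expect_equal(power_twosample(1e-9, n = 20), 0.05, tolerance = 1e-3)
  pows <- sapply(c(5, 10, 20, 40, 80), function(n) power_twosample(0.5, n = n))
  expect_true(all(diff(pows) > 0))
  # Monte-Carlo oracle: 1e5 simulated pooled t-tests at d = 0.5, n = 64
  n <- 64; d <- 0.5; reps <- 1e5
  rej <- 0
  with_seed(42, {
    for (chunk in 1:10) {
      xa <- matrix(rnorm(n * (reps / 10), mean = d), n)
      xb <- matrix(rnorm(n * (reps / 10)), n)
      ma <- colMeans(xa); mb <- colMeans(xb)
      va <- colSums((xa - rep(ma, each = n))^2)
      vb <- colSums((xb - rep(mb, each = n))^2)
      sp <- sqrt((va + vb) / (2 * n - 2))
      tt <- (ma - mb) / (sp * sqrt(2 / n))
      rej <- rej + sum(abs(tt) > qt(0.975, 2 * n - 2))
    }
  })
  expect_equal(power_twosample(d, n = n), rej / reps, tolerance = 0.01)
  # inverse mode returns the minimal integer n reaching the requested power
  n_min <- power_twosample(0.8, power = 0.9)
  expect_gte(power_twosample(0.8, n = n_min), 0.9)
  expect_lt(power_twosample(0.8, n = n_min - 1), 0.9)
  expect_error(power_twosample(-1, n = 10), "d must be")
})
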