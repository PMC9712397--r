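# shared fixtures and reference constants for the test suite

# Reference db8/db4 low-pass (scaling) filter coefficients, minimum-phase
# convention h[0] = 0.0544..., cross-checked against the PyWavelets filter
# bank (which stores the reversed filter).
DB8_H_REF <- rev(c(
  -0.00011747678412476953, 0.0006754494064505693, -0.00039174037337694705,
  -0.004870352993451574, 0.008746094047405777, 0.013981027917398282,
  -0.044088253930794755, -0.017369301001807547, 0.12874742662047847,
  0.0004724845739132828, -0.2840155429615469, -0.015829105256349306,
  0.5853546836542067, 0.6756307362972898, 0.31287159091429995,
  0.05441584224310401))
DB4_H_REF <- rev(c(
  -0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
  -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
  0.7148465705529157, 0.2303778133088965))

# small, fast generator config for unit tests (short debates)
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_debates = 2, debate_length_s = 60, seed = seed), list(...))
  do.call(synth_config, args)
}

# a quiet recording (channels x samples of near-zero noise) for
# construction-oracle tests
quiet_recording <- function(fs = 256, dur_s = 20, noise_sd = 2,
                            seed = 1) {
  ch <- biosemi32_montage()$channel
  with_seed(seed, {
    recording(matrix(rnorm(32 * fs * dur_s, sd = noise_sd), nrow = 32),
              fs = fs, channels = ch)
  })
}

# brute-force periodized DWT analysis step, written independently of the
# package's polyphase implementation: explicit circular correlation then
# keep every second output.
brute_dwt_step <- function(x, h, g) {
  N <- length(x)
  conv_at <- function(flt, n0) {
    s <- 0
    for (m in seq_along(flt)) s <- s + flt[m] * x[((n0 + m - 2) %% N) + 1]
    s
  }
  ks <- seq(1, N, by = 2)
  list(a = vapply(ks, function(k) conv_at(h, k), numeric(1)),
       d = vapply(ks, function(k) conv_at(g, k), numeric(1)))
}

brute_dwt <- function(x, spec, levels) {
  d <- list(); a <- x
  for (lev in seq_len(levels)) {
    st <- brute_dwt_step(a, spec$h, spec$g)
    d[[lev]] <- st$d
    a <- st$a
  }
  list(d = d, a = a)
}

# brute-force Benjamini-Hochberg step-up, direct from the definition
brute_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  thr <- 0
  for (k in seq_len(m)) if (p[o[k]] <= k / m * q) thr <- max(thr, p[o[k]])
  list(mask = p <= thr & thr > 0, threshold = thr)
}

# FFT band-amplitude oracle: mean rectified amplitude of x restricted to
# [lo, hi] Hz, via direct spectral masking (independent of the DWT path)
fft_band_amplitude <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  freq <- pmin((seq_len(n) - 1) * fs / n, fs - (seq_len(n) - 1) * fs / n)
  X[freq < lo | freq > hi] <- 0 + 0i
  mean(abs(Re(stats::fft(X, inverse = TRUE)) / n))
}
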