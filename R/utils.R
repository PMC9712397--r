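# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All generator randomness flows through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation so that independent stages/debates draw
# from non-overlapping streams. Kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  codes <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in codes) s <- (s * 48271 + as.double(k) * 9973 + 1) %% 2147483647
  as.integer(s)
}

# spectral-shaping caches (keyed by length / band) to avoid rebuilding
# frequency grids for every channel of every recording
noise_env <- new.env(parent = emptyenv())

pink_scale <- function(n) {
  key <- paste0("p", n)
  v <- noise_env[[key]]
  if (is.null(v)) {
    f <- c(1, seq_len(n - 1))               # DC handled as lowest bin
    f <- pmin(f, n - f + 1)                 # mirror for negative frequencies
    v <- 1 / sqrt(f)
    noise_env[[key]] <- v
  }
  v
}

band_mask <- function(n, fs, lo, hi) {
  key <- paste0("b", n, "_", fs, "_", lo, "_", hi)
  v <- noise_env[[key]]
  if (is.null(v)) {
    freq <- (seq_len(n) - 1) * fs / n
    freq <- pmin(freq, fs - freq)           # two-sided spectrum
    v <- freq >= lo & freq <= hi
    noise_env[[key]] <- v
  }
  v
}

# Unit-variance 1/f-shaped ("pink-ish") noise of length n via FFT shaping.
pink_noise <- function(n) {
  W <- stats::fft(stats::rnorm(n)) * pink_scale(n)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# Unit-variance noise band-limited to [lo, hi] Hz at sampling rate fs,
# via hard FFT masking of white noise.
bandlimited_noise <- function(n, fs, lo, hi) {
  W <- stats::fft(stats::rnorm(n)) * band_mask(n, fs, lo, hi)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

# Raised-cosine blink transient: peak `amp`, duration `dur_s` seconds.
blink_template <- function(fs, dur_s = 0.4, amp = 1) {
  n <- max(3L, round(dur_s * fs))
  amp * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))
}

# Per-channel blink topography weights (frontal-dominant), by channel name.
blink_weights <- function(channels) {
  w <- c(Fp1 = 1, Fp2 = 1, AF3 = 0.6, AF4 = 0.6, F3 = 0.3, F4 = 0.3,
         F7 = 0.25, F8 = 0.25, Fz = 0.2, FC1 = 0.08, FC2 = 0.08)
  out <- w[channels]
  out[is.na(out)] <- 0
  unname(out)
}

# Sum transients (centered/peaked at the given times) into a length-n signal.
transient_signal <- function(n, fs, times, template) {
  sig <- numeric(n)
  half <- (length(template) - 1L) %/% 2L
  for (t_s in times) {
    i0 <- floor(t_s * fs) + 1L - half
    idx <- i0:(i0 + length(template) - 1L)
    keep <- idx >= 1L & idx <= n
    if (any(keep)) sig[idx[keep]] <- sig[idx[keep]] + template[keep]
  }
  sig
}

# Add transients at `times` to `data` (channels x samples), scaled per
# channel by `weights`; transient peaks land on the nominal times so that
# detected peak times line up with planted blink times.
add_transient <- function(data, fs, times, template, weights) {
  if (length(times) == 0L) return(data)
  sig <- transient_signal(ncol(data), fs, times, template)
  for (ci in which(weights != 0))
    data[ci, ] <- data[ci, ] + weights[ci] * sig
  data
}

`%||%` <- function(a, b) if (is.null(a)) b else a
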