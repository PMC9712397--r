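#' Daubechies analysis filters
#'
#' Computes the orthonormal Daubechies scaling (low-pass, `h`) and wavelet
#' (high-pass, `g`) filters with `p` vanishing moments (2p taps) by spectral
#' factorization: the roots of the binomial polynomial
#' `P(y) = sum_k C(p-1+k, k) y^k` are mapped to the z-plane and the
#' minimum-phase factor is kept, giving `h(z) = c (1+z)^p q(z)`. The filters
#' satisfy `sum(h) = sqrt(2)`, `sum(h^2) = 1`, and `g` is the quadrature
#' mirror of `h`.
#'
#' @param p number of vanishing moments: 8 for the default 16-tap filter,
#'   4 for the 8-tap variant.
#' @return list(h, g, p, taps).
#' @export
daubechies_filters <- function(p = 8) {
  if (p < 1 || p != round(p)) stop("p must be a positive integer")
  if (p == 1) {
    h <- rep(1 / sqrt(2), 2)
  } else {
    bino <- choose(p - 1 + 0:(p - 1), 0:(p - 1))
    yroots <- polyroot(bino)
    zroots <- complex(0)
    for (y in yroots) {
      # y = (2 - z - 1/z)/4  =>  z^2 - (2 - 4y) z + 1 = 0
      b <- 2 - 4 * y
      disc <- sqrt(b^2 - 4)
      z1 <- (b + disc) / 2
      z2 <- (b - disc) / 2
      zroots <- c(zroots, if (Mod(z1) < 1) z1 else z2)
    }
    # q(z) = prod (z - z_i); conjugate roots keep coefficients real
    q <- 1
    for (z in zroots) q <- convolve_poly(q, c(1, -z))
    hpoly <- q
    for (i in seq_len(p)) hpoly <- convolve_poly(hpoly, c(1, 1))
    h <- Re(hpoly)
  }
  h <- h * sqrt(2) / sum(h)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g, p = p, taps = L)
}

# polynomial multiplication (coefficient convolution), complex-safe
convolve_poly <- function(a, b) {
  out <- rep(0 + 0i, length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    ib <- seq_along(b) + i - 1L
    out[ib] <- out[ib] + a[i] * b
  }
  out
}

#' Wavelet transform specification
#'
#' @param family `"db8"` (16-tap, 8 vanishing moments, the default) or
#'   `"db4"` (8-tap). The dyadic scale base is 2 and the translation base 1.
#' @param mode boundary handling: `"periodic"` treats the signal as
#'   circular (exact orthogonality), `"symmetric"` runs the transform on a
#'   mirror-extended copy to soften the wrap-around discontinuity; both give
#'   exact reconstruction.
#' @return A `wavelet_spec` list with the filters attached.
#' @export
wavelet_spec <- function(family = c("db8", "db4"),
                         mode = c("periodic", "symmetric")) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  p <- if (family == "db8") 8 else 4
  flt <- daubechies_filters(p)
  structure(list(family = family, mode = mode, a0 = 2, b0 = 1,
                 h = flt$h, g = flt$g, taps = flt$taps),
            class = "wavelet_spec")
}

# column-index cache for the periodized polyphase filtering: for signal
# length N and filter length L, entry m holds ((2k + m - 1) mod N) + 1
dwt_env <- new.env(parent = emptyenv())
dwt_cols <- function(N, L) {
  key <- paste0(N, "_", L)
  v <- dwt_env[[key]]
  if (is.null(v)) {
    base <- seq(0L, N - 2L, by = 2L)
    v <- lapply(seq_len(L), function(m) ((base + m - 1L) %% N) + 1L)
    dwt_env[[key]] <- v
  }
  v
}

# one periodic analysis step on a channels x N matrix -> list(a, d), N/2 cols
dwt_step <- function(X, h, g) {
  N <- ncol(X)
  cols <- dwt_cols(N, length(h))
  A <- h[1] * X[, cols[[1]], drop = FALSE]
  D <- g[1] * X[, cols[[1]], drop = FALSE]
  for (m in 2:length(h)) {
    Xm <- X[, cols[[m]], drop = FALSE]
    A <- A + h[m] * Xm
    D <- D + g[m] * Xm
  }
  list(a = A, d = D)
}

# one periodic synthesis step: (A, D) with M columns -> channels x 2M matrix
idwt_step <- function(A, D, h, g) {
  N <- 2L * ncol(A)
  X <- matrix(0, nrow(A), N)
  cols <- dwt_cols(N, length(h))
  for (m in seq_along(h)) {
    pos <- cols[[m]]
    X[, pos] <- X[, pos] + h[m] * A + g[m] * D
  }
  X
}

# matrix decomposition: channels x samples in, matrices per level out
mdwt_decompose <- function(X, spec, levels) {
  n0 <- ncol(X)
  if (spec$mode == "symmetric") X <- cbind(X, X[, rev(seq_len(n0)),
                                               drop = FALSE])
  n <- ncol(X)
  if (n < spec$taps)
    stop(sprintf("signal of length %d is shorter than the %d-tap filter",
                 n, spec$taps))
  if (levels > floor(log2(n)))
    stop("levels exceeds floor(log2(signal length))")
  d <- vector("list", levels)
  a <- X
  for (lev in seq_len(levels)) {
    if (ncol(a) < spec$taps || ncol(a) %% 2L != 0L)
      stop(sprintf("level %d input (length %d) too short for the %d-tap filter",
                   lev, ncol(a), spec$taps))
    st <- dwt_step(a, spec$h, spec$g)
    d[[lev]] <- st$d
    a <- st$a
  }
  structure(list(d = d, a = a, n = n0, levels = levels, spec = spec),
            class = "mdwt_pyramid")
}

mdwt_reconstruct <- function(mpyr) {
  a <- mpyr$a
  for (lev in rev(seq_len(mpyr$levels)))
    a <- idwt_step(a, mpyr$d[[lev]], mpyr$spec$h, mpyr$spec$g)
  a[, seq_len(mpyr$n), drop = FALSE]
}

mband_component <- function(band, levels, fs) {
  if (grepl("^[AD][0-9]+$", band)) return(band)
  bm <- band_map(fs, levels)
  row <- bm[!is.na(bm$band) & bm$band == band, ]
  if (nrow(row) == 0L) stop("unknown band: ", band)
  row$component[1]
}

mband_reconstruct <- function(mpyr, band, fs) {
  comp <- mband_component(band, mpyr$levels, fs)
  kind <- substr(comp, 1, 1)
  lev <- as.integer(substr(comp, 2, nchar(comp)))
  if (lev > mpyr$levels) stop("component ", comp, " not present in pyramid")
  if (kind == "A" && lev != mpyr$levels)
    stop("approximation only available at the deepest level")
  z <- mpyr
  if (kind != "A") z$a <- mpyr$a * 0
  z$d <- lapply(seq_len(mpyr$levels), function(i)
    if (kind == "D" && i == lev) mpyr$d[[i]] else mpyr$d[[i]] * 0)
  mdwt_reconstruct(z)
}

#' Discrete wavelet decomposition
#'
#' Cascade of quadrature-mirror filtering and dyadic decimation: level-1
#' detail `D1` holds the top half-band, each further level halves the band,
#' and the final approximation `A_levels` holds the lowest band. With the
#' periodic convention the transform is orthonormal, so energy is conserved
#' exactly and reconstruction is exact.
#'
#' @param x numeric signal (even length at every level; length must be at
#'   least the filter length).
#' @param spec a [wavelet_spec()].
#' @param levels decomposition depth; at most `floor(log2(length(x)))`.
#' @return A `dwt_pyramid`: list(d = list(D1..Dlevels), a = A_levels,
#'   n, levels, spec).
#' @export
dwt_decompose <- function(x, spec = wavelet_spec(), levels) {
  mp <- mdwt_decompose(matrix(x, nrow = 1L), spec, levels)
  structure(list(d = lapply(mp$d, as.numeric), a = as.numeric(mp$a),
                 n = mp$n, levels = levels, spec = spec),
            class = "dwt_pyramid")
}

#' Invert a wavelet decomposition
#'
#' @param pyr a `dwt_pyramid` from [dwt_decompose()].
#' @return The reconstructed signal, length `pyr$n`.
#' @export
dwt_reconstruct <- function(pyr) {
  as.numeric(mdwt_reconstruct(as_mpyr(pyr)))
}

as_mpyr <- function(pyr) {
  structure(list(d = lapply(pyr$d, function(v) matrix(v, nrow = 1L)),
                 a = matrix(pyr$a, nrow = 1L), n = pyr$n,
                 levels = pyr$levels, spec = pyr$spec),
            class = "mdwt_pyramid")
}

#' Map canonical EEG bands to wavelet components
#'
#' Each detail level `Di` spans the dyad `[fs/2^(i+1), fs/2^i)` Hz and the
#' final approximation spans `[0, fs/2^(levels+1))`. With fs = 256 and 5
#' levels this yields A5 = delta (0--4 Hz), D5 = theta (4--8), D4 = alpha
#' (8--16), D3 = beta (16--32) and D2 = gamma (32--64); gamma is computed but
#' flagged excluded (movement-contaminated in unconstrained recordings) and
#' D1 is discarded. The dyadic edges approximate the nominal 13/28/45 Hz band
#' boundaries; the approximation is inherent to mapping five bands onto five
#' dyadic components.
#'
#' @param fs sampling rate, Hz (256 canonical; any rate with dyadic edges at
#'   4/8/16/32 Hz works, e.g. 512 with 6 levels).
#' @param levels decomposition depth.
#' @return data.frame: band, component (e.g. `"D4"`), f_lo, f_hi, status
#'   (`"used"`, `"excluded"`, `"discarded"`).
#' @export
band_map <- function(fs = 256, levels = as.integer(log2(fs) - 3)) {
  lev_for_edge <- function(edge) {
    i <- log2(fs) - log2(edge) - 1
    if (abs(i - round(i)) > 1e-9 || round(i) < 1)
      stop(sprintf("fs = %g has no dyadic level with lower edge %g Hz",
                   fs, edge))
    as.integer(round(i))
  }
  i_theta <- lev_for_edge(4)
  if (levels < i_theta)
    stop(sprintf("need %d levels at fs = %g so the final approximation is 0-4 Hz",
                 i_theta, fs))
  rows <- rbind(
    data.frame(band = "delta", component = paste0("A", i_theta),
               f_lo = 0, f_hi = 4, status = "used"),
    data.frame(band = "theta", component = paste0("D", i_theta),
               f_lo = 4, f_hi = 8, status = "used"),
    data.frame(band = "alpha", component = paste0("D", lev_for_edge(8)),
               f_lo = 8, f_hi = 16, status = "used"),
    data.frame(band = "beta", component = paste0("D", lev_for_edge(16)),
               f_lo = 16, f_hi = 32, status = "used"),
    data.frame(band = "gamma", component = paste0("D", lev_for_edge(32)),
               f_lo = 32, f_hi = 64, status = "excluded"))
  d1 <- data.frame(band = NA_character_, component = "D1",
                   f_lo = fs / 4, f_hi = fs / 2, status = "discarded")
  out <- rbind(rows, d1)
  rownames(out) <- NULL
  out
}

#' Reconstruct a single band's time signal
#'
#' Inverts the pyramid with every component except the requested band's
#' zeroed out, so the band reconstructions (plus the excluded/discarded
#' components) sum to the input signal exactly.
#'
#' @param pyr a `dwt_pyramid`.
#' @param band `"delta"`, `"theta"`, `"alpha"` or `"beta"` (or a raw
#'   component name like `"D4"`/`"A5"`).
#' @param fs sampling rate the pyramid's signal was sampled at, Hz.
#' @return Numeric band signal, same length as the decomposed signal.
#' @export
band_reconstruct <- function(pyr, band, fs = 256) {
  as.numeric(mband_reconstruct(as_mpyr(pyr), band, fs))
}

#' Band-limited signals for every channel of an epoch
#'
#' @param ep an `eeg_epoch`.
#' @param band band name, or `"raw"` for the unfiltered epoch.
#' @param spec a [wavelet_spec()].
#' @param levels decomposition depth (defaults to the canonical depth for
#'   the epoch's sampling rate).
#' @return channels x samples matrix of the band signal.
#' @export
epoch_band_signals <- function(ep, band, spec = wavelet_spec(),
                               levels = as.integer(log2(ep$fs) - 3)) {
  epoch_band_multi(ep, band, spec, levels)[[band]]
}

# decompose each channel once and reconstruct all requested bands;
# "raw" passes the epoch through untouched
epoch_band_multi <- function(ep, bands, spec = wavelet_spec(),
                             levels = as.integer(log2(ep$fs) - 3)) {
  if ("gamma" %in% bands)
    stop("gamma band is computed but excluded from analysis ",
         "(movement-contaminated); request it via component name D",
         as.integer(log2(ep$fs)) - 6L, " explicitly if needed")
  out <- list()
  wav <- setdiff(bands, "raw")
  if (length(wav)) {
    mp <- mdwt_decompose(ep$data, spec, levels)
    for (b in wav) {
      m <- mband_reconstruct(mp, b, ep$fs)
      rownames(m) <- ep$channels
      out[[b]] <- m
    }
  }
  if ("raw" %in% bands) out$raw <- ep$data
  out[bands]
}

#' Per-channel mean rectified band amplitude of an epoch
#'
#' The feature behind the channel statistics: the mean absolute value of the
#' band-limited signal over the 2-s window, in microvolts. `band = "raw"`
#' uses the unfiltered signal.
#'
#' @inheritParams epoch_band_signals
#' @return Named numeric vector, one value per channel.
#' @export
band_feature <- function(ep, band, spec = wavelet_spec(),
                         levels = as.integer(log2(ep$fs) - 3)) {
  sig <- epoch_band_signals(ep, band, spec, levels)
  out <- rowMeans(abs(sig))
  names(out) <- ep$channels
  out
}

#' Feature matrix over a set of epochs
#'
#' @param epochs list of `eeg_epoch` objects.
#' @param bands bands to compute (default raw plus the four analysis bands).
#' @param spec a [wavelet_spec()].
#' @return list(features = list of epochs x channels matrices, one per band;
#'   labels = character vector; debate_id = vector).
#' @export
epoch_features <- function(epochs,
                           bands = c("raw", "delta", "theta", "alpha", "beta"),
                           spec = wavelet_spec()) {
  labels <- vapply(epochs, function(e) e$label, character(1))
  debate <- vapply(epochs, function(e) as.character(e$debate_id), character(1))
  n_ch <- length(epochs[[1]]$channels)
  feats <- lapply(bands, function(b)
    matrix(0, length(epochs), n_ch,
           dimnames = list(NULL, epochs[[1]]$channels)))
  names(feats) <- bands
  for (i in seq_along(epochs)) {
    sigs <- epoch_band_multi(epochs[[i]], bands, spec)
    for (b in bands) feats[[b]][i, ] <- rowMeans(abs(sigs[[b]]))
  }
  list(features = feats, labels = labels, debate_id = debate)
}
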