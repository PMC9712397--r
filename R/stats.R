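#' Channel-wise two-sample t-test between attentional states
#'
#' Independent two-sample t-test (pooled variance, two-sided) per channel on
#' per-epoch feature values, plus the conservative screening mask `|t| >= 4`
#' used to curb false positives before any correction.
#'
#' @param x_att epochs x channels matrix of features for attention epochs.
#' @param x_dis epochs x channels matrix for distraction epochs (same
#'   channels).
#' @param welch use the Welch (unequal-variance) variant instead of pooled?
#' @param t_screen screening threshold on `|t|` (default 4).
#' @return data.frame: channel, t, p, screened (`|t| >= t_screen`). `t` is
#'   attention minus distraction.
#' @export
channel_ttest <- function(x_att, x_dis, welch = FALSE, t_screen = 4) {
  if (ncol(x_att) != ncol(x_dis)) stop("channel count mismatch")
  if (nrow(x_att) < 2 || nrow(x_dis) < 2)
    stop("need at least 2 epochs per group")
  res <- lapply(seq_len(ncol(x_att)), function(j) {
    tt <- stats::t.test(x_att[, j], x_dis[, j], var.equal = !welch)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  m <- do.call(rbind, res)
  chan <- colnames(x_att) %||% paste0("ch", seq_len(ncol(x_att)))
  data.frame(channel = chan, t = m[, "t"], p = m[, "p"],
             screened = abs(m[, "t"]) >= t_screen,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up FDR procedure
#'
#' Finds the largest k with `p_(k) <= (k/m) q` over the sorted p-values and
#' declares everything at or below `p_(k)` significant; the realized p
#' threshold `p_(k)` is returned (0 when nothing passes), matching how an
#' applied FDR threshold is usually reported alongside topographies.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list(mask = logical vector in input order, threshold = realized p
#'   threshold, q, n_significant).
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0L) stop("fdr_bh: empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("fdr_bh: p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= (seq_len(m) / m) * q)
  if (length(ok) == 0L)
    return(list(mask = rep(FALSE, m), threshold = 0, q = q,
                n_significant = 0L))
  thr <- ps[max(ok)]
  mask <- p <= thr
  list(mask = mask, threshold = thr, q = q, n_significant = sum(mask))
}

#' Channel statistic maps across bands
#'
#' Runs [channel_ttest()] for every band's feature matrix and applies
#' [fdr_bh()] within each band, producing the per-band, per-channel map the
#' topography display consumes. The `|t| >= 4` screen and the FDR mask are
#' reported side by side (they are separate filters, not composed).
#'
#' @param features named list of epochs x channels feature matrices (one per
#'   band, e.g. the `features` element of [epoch_features()]).
#' @param labels character vector of epoch labels aligned with the matrices.
#' @param q FDR level.
#' @param t_screen screening threshold on `|t|`.
#' @param welch use Welch t-tests?
#' @return A `channel_stat_map`: data.frame with band, channel, t, p,
#'   screened, significant (FDR), plus attribute `thresholds` (realized p
#'   threshold per band).
#' @export
channel_stat_maps <- function(features, labels, q = 0.05, t_screen = 4,
                              welch = FALSE) {
  att <- labels == "attention"
  out <- list()
  thresholds <- numeric(0)
  for (band in names(features)) {
    m <- features[[band]]
    tt <- channel_ttest(m[att, , drop = FALSE], m[!att, , drop = FALSE],
                        welch = welch, t_screen = t_screen)
    fdr <- fdr_bh(tt$p, q)
    tt$band <- band
    tt$significant <- fdr$mask
    thresholds[band] <- fdr$threshold
    out[[band]] <- tt
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[, c("band", "channel", "t", "p", "screened", "significant")]
  attr(res, "thresholds") <- thresholds
  class(res) <- c("channel_stat_map", class(res))
  res
}

#' Topography display table
#'
#' Joins a stat map to 2-D montage coordinates for rendering: significant
#' channels keep their t-value, non-significant channels are flagged and
#' their displayed t is set to zero (the usual masked-topography
#' convention).
#'
#' @param stat_map a [channel_stat_maps()] result (or compatible data.frame
#'   with band/channel/t/significant).
#' @param montage data.frame with channel/x/y columns (default the Biosemi-32
#'   layout).
#' @return data.frame: band, channel, x, y, t_display, significant.
#' @export
topography_mask <- function(stat_map, montage = biosemi32_montage()) {
  idx <- match(stat_map$channel, montage$channel)
  if (anyNA(idx))
    stop("channel(s) missing montage coordinates: ",
         paste(unique(stat_map$channel[is.na(idx)]), collapse = ", "))
  data.frame(band = stat_map$band, channel = stat_map$channel,
             x = montage$x[idx], y = montage$y[idx],
             t_display = ifelse(stat_map$significant, stat_map$t, 0),
             significant = stat_map$significant,
             stringsAsFactors = FALSE)
}

#' Pearson chi-square test on a 2x2 attention/distraction x experience table
#'
#' Without continuity correction, df = 1 — the standard test for whether the
#' attention:distraction proportion differs between experience groups.
#'
#' @param counts 2x2 numeric matrix (rows: states, columns: groups).
#' @return list(chisq, df = 1, p).
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be a 2x2 table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in the 2x2 table")
  ct <- stats::chisq.test(counts, correct = FALSE)
  if (any(ct$expected <= 0)) stop("expected counts must be positive")
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Power of the two-sided two-sample t-test
#'
#' Standard noncentral-t power for a standardized effect size d, or, in
#' inverse mode, the minimal per-group n reaching a requested power.
#'
#' @param d standardized effect size (Cohen's d), > 0.
#' @param n per-group sample size (forward mode).
#' @param power requested power (inverse mode; supply instead of `n`).
#' @param alpha two-sided significance level.
#' @return Forward mode: the power (scalar). Inverse mode: the minimal
#'   integer per-group n whose power reaches `power`.
#' @export
power_twosample <- function(d, n = NULL, power = NULL, alpha = 0.05) {
  if (d <= 0) stop("effect size d must be > 0")
  if (is.null(n) == is.null(power))
    stop("supply exactly one of `n` (forward) or `power` (inverse)")
  pow_at <- function(n) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    tc <- stats::qt(1 - alpha / 2, df)
    # both rejection tails of the noncentral t, so the d -> 0 limit is alpha
    stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
  if (!is.null(n)) {
    if (n < 2) stop("n must be >= 2 per group")
    return(pow_at(n))
  }
  if (power <= alpha || power >= 1)
    stop("requested power must be in (alpha, 1)")
  n_hi <- 4
  while (pow_at(n_hi) < power) {
    n_hi <- n_hi * 2
    if (n_hi > 1e7) stop("requested power unreachable at this effect size")
  }
  n_min <- n_hi
  for (n_try in seq(max(2, n_hi / 2), n_hi))
    if (pow_at(n_try) >= power) { n_min <- n_try; break }
  as.integer(n_min)
}
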