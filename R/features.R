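# The 25-feature bank extracted from every MMG window, per channel:
#   time domain (7):       RMS, kurtosis, SD, SSC, MAV, ZC, WL
#   frequency domain (2):  MPF, MDF
#   time-frequency (9):    WPE, WP1..WP8 (3-level wavelet-packet energies)
#   nonlinear dynamics (7): LZC, SampEn, ApEn, FuzzyEn, DistEn, FD, LyapExp

FEATURE_NAMES <- c("RMS", "kurtosis", "SD", "SSC", "MAV", "ZC", "WL",
                   "MPF", "MDF",
                   "WPE", paste0("WP", 1:8),
                   "LZC", "SampEn", "ApEn", "FuzzyEn", "DistEn", "FD",
                   "LyapExp")

#' Tunable parameters of the nonlinear-dynamics features
#'
#' Literature defaults: embedding m = 2 and tolerance r = 0.2 SD for the
#' entropies, exponential fuzzy membership with gradient n = 2, 512
#' histogram bins for the distribution entropy, median binarization for the
#' Lempel-Ziv complexity, and a Rosenstein largest-Lyapunov estimate with
#' embedding dimension 5 and delay at the first autocorrelation zero
#' crossing.
#'
#' @param m Embedding dimension for SampEn/ApEn/FuzzyEn/DistEn.
#' @param r_frac Tolerance as a fraction of the window SD.
#' @param fuzzy_n Gradient of the exponential fuzzy membership function.
#' @param disten_bins Histogram bin count for DistEn.
#' @param lyap_dim Embedding dimension of the Lyapunov estimate.
#' @param lyap_fit_len Number of divergence-curve steps in the slope fit.
#' @return A list of parameters.
#' @export
feature_params <- function(m = 2L, r_frac = 0.2, fuzzy_n = 2,
                           disten_bins = 512L, lyap_dim = 5L,
                           lyap_fit_len = 30L) {
  list(m = as.integer(m), r_frac = r_frac, fuzzy_n = fuzzy_n,
       disten_bins = as.integer(disten_bins), lyap_dim = as.integer(lyap_dim),
       lyap_fit_len = as.integer(lyap_fit_len))
}

## ---------------------------------------------------------------- time domain

#' Time-domain features of one window
#'
#' RMS, Pearson (non-excess) kurtosis m4/m2^2, sample SD, slope sign
#' changes, mean absolute value, zero crossings (zero counted as positive,
#' strict sign changes), and waveform length (sum of absolute successive
#' differences).
#'
#' @param x Numeric vector, length >= 3, non-constant.
#' @return Named numeric vector of the 7 features.
#' @export
time_domain <- function(x) {
  n <- length(x)
  if (n < 3L) stop("time-domain features need length >= 3", call. = FALSE)
  if (max(x) == min(x))
    stop("constant window: kurtosis undefined", call. = FALSE)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  s <- ifelse(x >= 0, 1L, -1L)
  d1 <- x[2:(n - 1L)] - x[1:(n - 2L)]
  d2 <- x[2:(n - 1L)] - x[3:n]
  c(RMS = sqrt(mean(x^2)),
    kurtosis = mean((x - mu)^4) / m2^2,
    SD = stats::sd(x),
    SSC = sum(d1 * d2 > 0),
    MAV = mean(abs(x)),
    ZC = sum(s[-1] != s[-n]),
    WL = sum(abs(diff(x))))
}

## ----------------------------------------------------------- frequency domain

#' Welch power spectral density
#'
#' Hann-windowed segments of length \code{nseg} (512 by default) with 50
#' percent overlap, averaged modified periodograms, one-sided.
#'
#' @param x Signal vector.
#' @param fs Sampling rate (Hz).
#' @param nseg Segment length; shortened to \code{length(x)} if needed.
#' @return List with \code{freq} (Hz) and \code{power} (arbitrary units).
#' @export
welch_psd <- function(x, fs, nseg = 512L) {
  n <- length(x)
  nseg <- min(nseg, n)
  step <- max(1L, nseg %/% 2L)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  starts <- seq.int(1L, n - nseg + 1L, by = step)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nf)]
  }
  list(freq = (seq_len(nf) - 1L) * fs / nseg, power = acc / length(starts))
}

#' Frequency-domain features: mean and median power frequency
#'
#' MPF is the power-weighted mean frequency of the Welch spectrum; MDF is
#' the smallest frequency at which cumulative power reaches half the total.
#'
#' @param x Signal vector, length >= 64, not all zero.
#' @param fs Sampling rate (Hz).
#' @return Named vector \code{c(MPF, MDF)} in Hz.
#' @export
freq_domain <- function(x, fs) {
  if (length(x) < 64L) stop("frequency features need length >= 64", call. = FALSE)
  if (all(x == 0)) stop("all-zero signal has no spectrum", call. = FALSE)
  psd <- welch_psd(x, fs)
  tot <- sum(psd$power)
  mpf <- sum(psd$freq * psd$power) / tot
  mdf <- psd$freq[which(cumsum(psd$power) >= tot / 2)[1L]]
  c(MPF = mpf, MDF = mdf)
}

## ------------------------------------------------------------ wavelet packets

# Daubechies-4 (8-tap) orthonormal scaling filter.
DB4_H <- c(0.230377813308855230, 0.714846570552541500,
           0.630880767929590400, -0.027983769416983850,
           -0.187034811718881140, 0.030841381835986965,
           0.032883011666982945, -0.010597401784997278)
DB4_G <- rev(DB4_H) * c(1, -1, 1, -1, 1, -1, 1, -1)

# One analysis stage with periodic extension: returns the two half-length
# subbands. Orthogonality of the filter pair preserves total energy.
wp_split <- function(x) {
  n <- length(x)
  L <- length(DB4_H)
  idx <- outer(seq.int(0L, n - 2L, by = 2L), seq_len(L) - 1L, "+") %% n + 1L
  Xm <- matrix(x[idx], ncol = L)
  list(low = as.numeric(Xm %*% DB4_H), high = as.numeric(Xm %*% DB4_G))
}

#' Wavelet-packet band energies
#'
#' Three-level db4 wavelet-packet decomposition with periodic extension.
#' The 8 terminal nodes are reordered from the natural (Paley) order into
#' frequency order, so WP1 is the lowest-frequency band and WP8 the
#' highest; WPi is the sum of squared coefficients of band i and WPE their
#' total (equal to the signal energy, by orthogonality).
#'
#' @param x Signal vector; length must be a multiple of 8 and at least 64.
#' @return Named vector \code{c(WPE, WP1..WP8)}.
#' @export
wavelet_packet <- function(x) {
  n <- length(x)
  if (n < 64L || n %% 8L != 0L)
    stop("wavelet packet needs length >= 64 and divisible by 8", call. = FALSE)
  nodes <- list(x)
  for (lev in 1:3) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      sp <- wp_split(nodes[[i]])
      nxt[[2L * i - 1L]] <- sp$low
      nxt[[2L * i]] <- sp$high
    }
    nodes <- nxt
  }
  # Paley -> frequency order (Gray-code permutation, 3 levels)
  freq_order <- c(1L, 2L, 4L, 3L, 7L, 8L, 6L, 5L)
  wp <- vapply(nodes[freq_order], function(v) sum(v^2), numeric(1))
  out <- c(sum(wp), wp)
  names(out) <- c("WPE", paste0("WP", 1:8))
  out
}

## --------------------------------------------------------- nonlinear dynamics

#' Lempel-Ziv complexity of a binary sequence
#'
#' Exhaustive-history LZ76 parse: each phrase is the longest prefix of the
#' remaining sequence reproducible from the preceding text (overlap
#' allowed) plus one new symbol. Returns the raw phrase count and the
#' normalized complexity c(n) log2(n) / n.
#'
#' @param bits Integer/logical vector of 0s and 1s.
#' @return List with \code{count} and \code{normalized}.
#' @export
lz76_complexity <- function(bits) {
  s <- paste(as.integer(bits), collapse = "")
  n <- nchar(s)
  if (n < 2L) stop("sequence too short", call. = FALSE)
  c_cnt <- 0L
  i <- 1L
  while (i <= n) {
    l <- 1L
    while (i + l - 1L <= n &&
           grepl(substr(s, i, i + l - 1L), substr(s, 1L, i + l - 2L),
                 fixed = TRUE)) {
      l <- l + 1L
    }
    l <- min(l, n - i + 1L)
    c_cnt <- c_cnt + 1L
    i <- i + l
  }
  list(count = c_cnt, normalized = c_cnt * log2(n) / n)
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A / B) where B counts ordered template pairs (i != j,
#' i, j <= N - m) within Chebyshev tolerance r at length m and A the same
#' pairs at length m + 1.
#'
#' @param x Signal vector.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; defaults to 0.2 SD of \code{x}.
#' @return SampEn value (may be \code{Inf} when no m+1 matches exist).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  counts <- sampen_counts_cpp(as.numeric(x), as.integer(m), r)
  if (counts[1] == 0 || counts[2] == 0) return(Inf)
  -log(counts[1] / counts[2])
}

#' Approximate entropy
#'
#' ApEn(m, r) = Phi_m - Phi_(m+1) with Phi_m the mean log fraction of
#' templates (self-match included) within tolerance r.
#'
#' @inheritParams sample_entropy
#' @return ApEn value.
#' @export
approx_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  x <- as.numeric(x)
  apen_phi_cpp(x, as.integer(m), r) - apen_phi_cpp(x, as.integer(m) + 1L, r)
}

#' Fuzzy entropy
#'
#' Templates have their local mean removed; similarity is the exponential
#' membership exp(-(d^fn) / r) of the Chebyshev distance d. FuzzyEn =
#' ln phi_m - ln phi_(m+1), with phi averaged over ordered pairs i != j of
#' the N - m templates common to both lengths.
#'
#' @inheritParams sample_entropy
#' @param fn Gradient of the membership function (default 2).
#' @return FuzzyEn value.
#' @export
fuzzy_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x), fn = 2) {
  x <- as.numeric(x)
  log(fuzzyen_phi_cpp(x, as.integer(m), r, fn)) -
    log(fuzzyen_phi_cpp(x, as.integer(m) + 1L, r, fn))
}

#' Distribution entropy
#'
#' Normalized Shannon entropy of the histogram (\code{bins} equal-width
#' bins over [0, max distance]) of all inter-template Chebyshev distances
#' at embedding m.
#'
#' @inheritParams sample_entropy
#' @param bins Number of histogram bins (default 512).
#' @return DistEn in [0, 1].
#' @export
dist_entropy <- function(x, m = 2L, bins = 512L) {
  h <- disten_hist_cpp(as.numeric(x), as.integer(m), as.integer(bins))
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(bins)
}

#' Box-counting fractal dimension of a signal graph
#'
#' The graph (time, amplitude) is normalized to the unit square; box counts
#' at dyadic grid sizes are fit by least squares on the log-log scale.
#'
#' @param x Signal vector, non-constant.
#' @param scales Dyadic grid sizes (boxes per axis).
#' @return Estimated dimension (1 for a smooth line, larger for rougher
#'   graphs).
#' @export
box_counting_fd <- function(x, scales = 2^(2:7)) {
  n <- length(x)
  if (max(x) == min(x)) stop("constant signal has a degenerate graph", call. = FALSE)
  tt <- (seq_len(n) - 1) / (n - 1)
  y <- (x - min(x)) / (max(x) - min(x))
  counts <- vapply(scales, function(g) {
    col <- pmin(g - 1L, floor(tt * g))
    lo <- tapply(y, col, min)
    hi <- tapply(y, col, max)
    sum(pmin(g - 1, floor(hi * g)) - pmin(g - 1, floor(lo * g)) + 1)
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(scales))
  unname(stats::coef(fit)[2L])
}

# First zero crossing of the autocorrelation function (delay heuristic).
first_acf_zero <- function(x, max_lag = min(length(x) %/% 4L, 200L)) {
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1L]
  i <- which(a <= 0)[1L]
  if (is.na(i)) max_lag else i
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' Delay embedding (delay at the first autocorrelation zero crossing),
#' nearest neighbors outside a mean-period Theiler window, and the slope of
#' the mean log divergence curve over its initial section.
#'
#' @param x Signal vector (length >= 100 recommended).
#' @param dim Embedding dimension.
#' @param fit_len Number of divergence steps used in the slope fit.
#' @return Divergence rate in units of 1 / sample.
#' @export
lyapunov_rosenstein <- function(x, dim = 5L, fit_len = 30L) {
  n <- length(x)
  tau <- first_acf_zero(x)
  M <- n - (dim - 1L) * tau
  if (M < 3L * fit_len) stop("signal too short for Lyapunov estimation", call. = FALSE)
  E <- matrix(0, M, dim)
  for (k in seq_len(dim)) E[, k] <- x[seq.int(1L + (k - 1L) * tau, length.out = M)]
  # mean period (samples) from the spectral centroid -> Theiler window
  psd <- welch_psd(x - mean(x), fs = 1)
  mpf <- sum(psd$freq * psd$power) / sum(psd$power)
  W <- max(1L, min(M %/% 4L, as.integer(round(1 / max(mpf, 1 / M)))))
  sq <- rowSums(E^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(E)
  D2[D2 < 0] <- 0
  for (i in seq_len(M)) {
    lo <- max(1L, i - W); hi <- min(M, i + W)
    D2[i, lo:hi] <- Inf
  }
  nn <- max.col(-D2, ties.method = "first")
  K <- min(fit_len, M - 1L)
  y <- numeric(K + 1L)
  for (k in 0:K) {
    i_ok <- which(seq_len(M) + k <= M & nn + k <= M)
    d <- sqrt(rowSums((E[i_ok + k, , drop = FALSE] -
                         E[nn[i_ok] + k, , drop = FALSE])^2))
    d <- d[d > 0]
    if (length(d) == 0L) { y[k + 1L] <- NA_real_; next }
    y[k + 1L] <- mean(log(d))
  }
  k_idx <- 0:K
  ok <- !is.na(y)
  fit <- stats::lm(y[ok] ~ k_idx[ok])
  unname(stats::coef(fit)[2L])
}

#' Nonlinear-dynamics features of one window
#'
#' LZC (median-binarized, LZ76-normalized), SampEn, ApEn, FuzzyEn, DistEn,
#' box-counting FD, and the largest Lyapunov exponent. Infinite entropy
#' values (no template matches) are reported as errors so no silent NaN
#' enters the feature matrix.
#'
#' @param x Signal vector, length >= 100, non-constant.
#' @param params A \code{\link{feature_params}} list.
#' @return Named numeric vector of the 7 features.
#' @export
nonlinear <- function(x, params = feature_params()) {
  if (length(x) < 100L) stop("nonlinear features need length >= 100", call. = FALSE)
  if (max(x) == min(x)) stop("constant window", call. = FALSE)
  r <- params$r_frac * stats::sd(x)
  se <- sample_entropy(x, params$m, r)
  if (!is.finite(se)) stop("sample entropy has no template matches", call. = FALSE)
  c(LZC = lz76_complexity(as.integer(x >= stats::median(x)))$normalized,
    SampEn = se,
    ApEn = approx_entropy(x, params$m, r),
    FuzzyEn = fuzzy_entropy(x, params$m, r, params$fuzzy_n),
    DistEn = dist_entropy(x, params$m, params$disten_bins),
    FD = box_counting_fd(x),
    LyapExp = lyapunov_rosenstein(x, params$lyap_dim, params$lyap_fit_len))
}

## ------------------------------------------------------------------- assembly

#' All 25 features of one channel
#'
#' @param x Signal vector (one window of one channel).
#' @param fs Sampling rate (Hz).
#' @param params Nonlinear-feature parameters.
#' @return Named numeric vector of length 25 in the canonical order.
#' @export
channel_features <- function(x, fs, params = feature_params()) {
  out <- c(time_domain(x), freq_domain(x, fs), wavelet_packet(x),
           nonlinear(x, params))
  stopifnot(identical(names(out), FEATURE_NAMES))
  out
}

#' Feature matrix of a window list
#'
#' Applies \code{\link{channel_features}} to every channel of every window
#' and assembles the channel-major feature matrix (25 features per channel,
#' columns named \code{<channel>_<feature>}), with the per-window mean
#' force attached as the regression target.
#'
#' @param windows List of windows from \code{\link{slide_windows}}.
#' @param fs Sampling rate (Hz).
#' @param channel_labels Channel names; taken from the window matrices'
#'   implied order.
#' @param params Nonlinear-feature parameters.
#' @return A \code{feature_matrix}: list with \code{features} (matrix),
#'   \code{force} (vector, N) and \code{channel_labels}.
#' @export
extract_all <- function(windows, fs, channel_labels = NULL,
                        params = feature_params()) {
  if (length(windows) == 0L) stop("no windows to extract from", call. = FALSE)
  nch <- nrow(windows[[1L]]$channels)
  if (is.null(channel_labels))
    channel_labels <- if (nch == 3L) c("RF", "VL", "VM") else paste0("ch", seq_len(nch))
  stopifnot(length(channel_labels) == nch)
  col_names <- as.vector(vapply(channel_labels,
                                function(l) paste(l, FEATURE_NAMES, sep = "_"),
                                character(length(FEATURE_NAMES))))
  feat <- matrix(NA_real_, length(windows), length(col_names),
                 dimnames = list(NULL, col_names))
  force <- numeric(length(windows))
  for (w in seq_along(windows)) {
    row <- tryCatch(
      unlist(lapply(seq_len(nch), function(ch)
        channel_features(windows[[w]]$channels[ch, ], fs, params))),
      error = function(e)
        stop(sprintf("feature extraction failed at window %d: %s",
                     w, conditionMessage(e)), call. = FALSE))
    feat[w, ] <- row
    force[w] <- windows[[w]]$force
  }
  if (anyNA(feat)) stop("feature matrix contains missing values", call. = FALSE)
  structure(list(features = feat, force = force,
                 channel_labels = channel_labels),
            class = "feature_matrix")
}

#' Write a feature matrix as CSV
#'
#' Feature columns in canonical order plus a final \code{force_N} column.
#'
#' @param fm A \code{feature_matrix}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  df <- as.data.frame(fm$features)
  df$force_N <- fm$force
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"force_N" %in% names(df))
    stop("feature CSV must contain a force_N column", call. = FALSE)
  structure(list(features = as.matrix(df[setdiff(names(df), "force_N")]),
                 force = df$force_N, channel_labels = NULL),
            class = "feature_matrix")
}
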