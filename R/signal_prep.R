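# Preprocessing: Butterworth filtering, stable-segment admission,
# sliding-window segmentation, and Z-score scaling.

# Zero-phase Butterworth filtering, applied as the squared magnitude
# response in the frequency domain. Forward-backward application of an
# order-N Butterworth has exactly the real transfer function |H(f)|^2 and
# zero phase; applying that response via the FFT gives the same output
# while sidestepping the round-off noise a direct-form IIR accumulates at
# very low normalized cutoffs (the 2 Hz force filter at 1 kHz sampling has
# normalized cutoff 0.004, where filtfilt is accurate only to ~5e-4).
# Symmetric-reflection padding suppresses edge ringing at the circular
# seam without disturbing the local mean (an odd reflection pivoted on an
# oscillating sample injects a spurious DC step into the extension).
zero_phase_response <- function(x, pad, H2) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  mu <- mean(x)
  x <- x - mu
  left <- x[(pad + 1L):2L]
  right <- x[(n - 1L):(n - pad)]
  ext <- c(left, x, right)
  N <- length(ext)
  f <- seq_len(N) - 1L
  f <- pmin(f, N - f) / N  # fold to [0, 1/2] cycles/sample
  y <- Re(stats::fft(stats::fft(ext) * H2(f), inverse = TRUE)) / N
  y[(pad + 1L):(pad + n)] + H2(0) * mu
}

#' Band-pass filter an MMG channel
#'
#' Fourth-order Butterworth band-pass, 5-100 Hz, zero-phase (the
#' forward-backward squared-magnitude response, applied in the frequency
#' domain). Offline analysis favors zero-phase filtering because
#' window-level features must stay aligned with the force trace.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz; must exceed 200 so the passband lies
#'   below Nyquist.
#' @return Filtered vector of the same length.
#' @export
bandpass_mmg <- function(x, fs) {
  if (fs <= 200) stop("'fs' must exceed 200 Hz for a 5-100 Hz passband",
                      call. = FALSE)
  if (length(x) < 27L)
    stop("signal too short for fourth-order zero-phase filtering", call. = FALSE)
  fl <- 5 / fs; fh <- 100 / fs
  f0sq <- fl * fh; bwid <- fh - fl
  H2 <- function(f) {
    q <- ifelse(f == 0, Inf, (f^2 - f0sq) / (bwid * f))
    ifelse(is.infinite(q), 0, 1 / (1 + q^(2 * 4)))
  }
  zero_phase_response(x, pad = as.integer(2 * fs), H2)
}

#' Low-pass filter a force trace
#'
#' Third-order Butterworth low-pass at 2 Hz, zero-phase (squared-magnitude
#' response; see \code{\link{bandpass_mmg}}).
#'
#' @param x Numeric force vector.
#' @param fs Sampling rate in Hz; must exceed 4.
#' @return Filtered vector of the same length.
#' @export
lowpass_force <- function(x, fs) {
  if (fs <= 4) stop("'fs' must exceed 4 Hz for a 2 Hz low-pass", call. = FALSE)
  if (length(x) < 21L)
    stop("signal too short for third-order zero-phase filtering", call. = FALSE)
  fc <- 2 / fs
  H2 <- function(f) 1 / (1 + (f / fc)^(2 * 3))
  zero_phase_response(x, pad = as.integer(2 * fs), H2)
}

#' Select the earliest stable force segment
#'
#' Scans fixed-length windows (stepping one sample at a time) and returns
#' the earliest one whose relative fluctuation \code{(max - min) / mean}
#' is below \code{max_fluct} with a positive mean — the admission rule for
#' isometric trials.
#'
#' @param force Force vector (N).
#' @param fs Sampling rate (Hz).
#' @param duration_s Segment duration in seconds (default 6).
#' @param max_fluct Maximum admissible relative fluctuation (default 0.05).
#' @return Integer vector \code{c(start, end)} (1-based, inclusive).
#' @export
select_stable_segment <- function(force, fs, duration_s = 6, max_fluct = 0.05) {
  len <- as.integer(round(duration_s * fs))
  n <- length(force)
  if (n < len) stop("force trace shorter than the requested segment", call. = FALSE)
  # running min/max/sum over all candidate windows via cummax trick is
  # overkill here; a linear scan with incremental updates is fast enough
  # for kHz traces of a few tens of seconds.
  csum <- cumsum(force)
  for (start in seq_len(n - len + 1L)) {
    idx <- start:(start + len - 1L)
    m <- (csum[start + len - 1L] - if (start > 1L) csum[start - 1L] else 0) / len
    if (m <= 0) next
    rng <- range(force[idx])
    if ((rng[2] - rng[1]) / m < max_fluct)
      return(c(start, start + len - 1L))
  }
  stop("no stable segment: no window satisfies the fluctuation rule",
       call. = FALSE)
}

#' Sliding-window specification
#'
#' @param length Window length in samples (default 1000).
#' @param overlap Number of samples shared by consecutive windows
#'   (default 100), so the step is \code{length - overlap}.
#' @return An object of class \code{window_spec}.
#' @export
window_spec <- function(length = 1000L, overlap = 100L) {
  length <- as.integer(length); overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= length)
    stop("'overlap' must satisfy 0 <= overlap < length", call. = FALSE)
  structure(list(length = length, overlap = overlap, step = length - overlap),
            class = "window_spec")
}

#' Segment a recording into sliding windows
#'
#' Windows start at 0, step, 2 step, ...; the count is
#' \code{floor((n - length) / step) + 1}. Each element carries the channel
#' matrix of the window and the mean of the force trace over it (the
#' per-window regression target).
#'
#' @param recording An \code{mmg_recording}.
#' @param spec A \code{\link{window_spec}}.
#' @return List of lists with elements \code{channels}
#'   (n_channels x length), \code{force} (scalar mean), \code{start}
#'   (1-based index).
#' @export
slide_windows <- function(recording, spec = window_spec()) {
  n <- ncol(recording$channels)
  if (n < spec$length)
    stop("recording shorter than one window", call. = FALSE)
  starts <- seq.int(1L, n - spec$length + 1L, by = spec$step)
  lapply(starts, function(s) {
    idx <- s:(s + spec$length - 1L)
    list(channels = recording$channels[, idx, drop = FALSE],
         force = mean(recording$force[idx]),
         start = s)
  })
}

#' Z-score scaling fitted on training data
#'
#' \code{fit_zscore} computes per-column mean and sample SD (n - 1
#' denominator); zero-variance columns are dropped with a warning.
#' \code{apply_zscore} standardizes new data with the stored statistics;
#' \code{invert_zscore} undoes the transform.
#'
#' @param X Numeric matrix or data frame (rows = observations).
#' @return \code{fit_zscore}: a \code{zscore_scaler} with \code{mean},
#'   \code{sd} and \code{keep} (retained column names).
#' @export
fit_zscore <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance column(s): %s",
                    sum(!keep), paste(colnames(X)[!keep], collapse = ", ")),
            call. = FALSE)
  }
  structure(list(mean = mu[keep], sd = sdv[keep],
                 keep = colnames(X)[keep]),
            class = "zscore_scaler")
}

#' @rdname fit_zscore
#' @param scaler A fitted \code{zscore_scaler}.
#' @export
apply_zscore <- function(scaler, X) {
  if (!inherits(scaler, "zscore_scaler"))
    stop("scaler is not a fitted zscore_scaler", call. = FALSE)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  missing <- setdiff(scaler$keep, colnames(X))
  if (length(missing))
    stop("columns absent from new data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- X[, scaler$keep, drop = FALSE]
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' @rdname fit_zscore
#' @param Z Matrix of standardized values.
#' @export
invert_zscore <- function(scaler, Z) {
  if (!inherits(scaler, "zscore_scaler"))
    stop("scaler is not a fitted zscore_scaler", call. = FALSE)
  Z <- as.matrix(Z)
  sweep(sweep(Z, 2, scaler$sd, "*"), 2, scaler$mean, "+")
}
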