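# Seeded synthetic MMG + force generator.
#
# Emulates isometric knee-extension trials: three accelerometer channels
# (rectus femoris, vastus lateralis, vastus medialis) of band-limited
# (5-100 Hz) stochastic vibration whose RMS amplitude grows monotonically
# with the contraction level, and a synchronized force trace at a fixed
# fraction of maximal voluntary contraction (MVC) with a bounded slow
# fluctuation. The generator exists so the whole estimation pipeline is
# testable without human-subject recordings.

#' Configuration of the synthetic MMG generator
#'
#' @param mvc_newtons Maximal voluntary contraction force in newtons; the
#'   trial force is \code{level * mvc_newtons}.
#' @param levels Contraction levels as fractions of MVC, each in (0, 1].
#' @param duration_s Trial duration in seconds.
#' @param fs Sampling rate in Hz; \code{duration_s * fs} must be integer.
#' @param n_channels Number of MMG channels.
#' @param channel_labels Channel (muscle) names.
#' @param amp_gain Function mapping a level in (0, 1] to the target MMG RMS
#'   amplitude; must be monotone increasing for the amplitude-force
#'   relationship the pipeline assumes.
#' @param channel_gain Per-channel multiplicative gain on \code{amp_gain}.
#' @param noise_sd SD of additive white measurement noise.
#' @param fluctuation_frac Bound on the relative force fluctuation; must be
#'   below 0.05 so every trial passes the stable-segment admission rule.
#' @param seed Default master seed used when none is passed to the
#'   generating functions.
#'
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(mvc_newtons = 300,
                             levels = seq(0.1, 0.8, by = 0.1),
                             duration_s = 6, fs = 1000,
                             n_channels = 3L,
                             channel_labels = c("RF", "VL", "VM"),
                             amp_gain = function(l) 0.2 + 0.8 * l,
                             channel_gain = c(1.0, 0.9, 1.1),
                             noise_sd = 0.05,
                             fluctuation_frac = 0.04,
                             seed = 1L) {
  if (any(levels <= 0 | levels > 1))
    stop("all levels must lie in (0, 1]", call. = FALSE)
  if (fluctuation_frac >= 0.05)
    stop("'fluctuation_frac' must be < 0.05 (stable-segment admission rule)",
         call. = FALSE)
  if (duration_s <= 0 || fs <= 0)
    stop("'duration_s' and 'fs' must be positive", call. = FALSE)
  n_samples <- duration_s * fs
  if (abs(n_samples - round(n_samples)) > 1e-9)
    stop("duration_s * fs must be an integer sample count", call. = FALSE)
  stopifnot(is.function(amp_gain), n_channels >= 1L,
            length(channel_labels) == n_channels,
            length(channel_gain) == n_channels)
  structure(list(mvc_newtons = mvc_newtons, levels = levels,
                 duration_s = duration_s, fs = fs,
                 n_channels = as.integer(n_channels),
                 channel_labels = channel_labels,
                 amp_gain = amp_gain, channel_gain = channel_gain,
                 noise_sd = noise_sd, fluctuation_frac = fluctuation_frac,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

new_mmg_recording <- function(channels, force, fs, channel_labels, meta = list()) {
  stopifnot(is.matrix(channels), ncol(channels) == length(force), fs > 0,
            nrow(channels) >= 1L)
  structure(list(channels = channels, force = force, fs = fs,
                 channel_labels = channel_labels, meta = meta),
            class = "mmg_recording")
}

#' @export
print.mmg_recording <- function(x, ...) {
  cat(sprintf("<mmg_recording> %d channel(s) x %d samples @ %g Hz (%s)\n",
              nrow(x$channels), ncol(x$channels), x$fs,
              paste(x$channel_labels, collapse = ", ")))
  cat(sprintf("  force: mean %.2f N (level %s, seed %s)\n", mean(x$force),
              x$meta$level %||% "?", x$meta$seed %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one synthetic trial
#'
#' Each MMG channel is white Gaussian noise passed through the pipeline's
#' own 5-100 Hz fourth-order Butterworth band-pass, rescaled so its RMS
#' equals \code{channel_gain * amp_gain(level)}, plus additive white noise
#' of SD \code{noise_sd}. The force trace is
#' \code{level * mvc_newtons * (1 + slow sinusoid + smoothed noise)} with
#' total relative excursion bounded by \code{fluctuation_frac}. Identical
#' \code{(cfg, level, seed)} give bit-identical output.
#'
#' @param level Contraction level as a fraction of MVC, in (0, 1].
#' @param cfg A \code{\link{synthetic_config}}.
#' @param seed Integer RNG seed for this trial.
#'
#' @return An \code{mmg_recording}: \code{channels} matrix
#'   (n_channels x n_samples), \code{force} vector (N), \code{fs},
#'   \code{channel_labels} and provenance \code{meta}.
#' @export
generate_trial <- function(level, cfg = synthetic_config(), seed = cfg$seed) {
  if (!(level > 0 && level <= 1))
    stop("'level' must lie in (0, 1]", call. = FALSE)
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  set.seed(as.integer(seed))
  channels <- matrix(0, cfg$n_channels, n)
  for (ch in seq_len(cfg$n_channels)) {
    raw <- stats::rnorm(n)
    shaped <- bandpass_mmg(raw, cfg$fs)
    target_rms <- cfg$channel_gain[ch] * cfg$amp_gain(level)
    shaped <- shaped * (target_rms / sqrt(mean(shaped^2)))
    if (cfg$noise_sd > 0) shaped <- shaped + stats::rnorm(n, sd = cfg$noise_sd)
    channels[ch, ] <- shaped
  }
  base <- level * cfg$mvc_newtons
  if (cfg$fluctuation_frac > 0) {
    t <- seq_len(n) / cfg$fs
    # component amplitudes sum to fluctuation_frac / 2, so peak-to-peak
    # excursion stays below fluctuation_frac of the mean
    slow <- 0.35 * cfg$fluctuation_frac *
      sin(2 * pi * stats::runif(1, 0.1, 0.3) * t + stats::runif(1, 0, 2 * pi))
    # moving-average smoothed noise, rescaled to a hard bound
    w <- stats::filter(stats::rnorm(n), rep(1 / 200, 200), circular = TRUE)
    w <- as.numeric(w) / max(abs(w))
    force <- base * (1 + slow + 0.15 * cfg$fluctuation_frac * w)
  } else {
    force <- rep(base, n)
  }
  new_mmg_recording(channels, force, cfg$fs, cfg$channel_labels,
                    meta = list(level = level, seed = as.integer(seed)))
}

#' Generate a multi-level synthetic dataset
#'
#' One recording per (level, trial) pair; per-trial seeds are derived
#' deterministically from the master seed so the whole dataset is
#' reproducible from a single integer.
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @param trials_per_level Number of trials per contraction level. The
#'   default 9 yields 54 sliding windows per level under the default
#'   windowing, trimmed downstream to 50 per level (400 in total over the
#'   8 default levels).
#' @param seed Master seed.
#' @return List of \code{mmg_recording} objects, levels varying slowest.
#' @export
generate_dataset <- function(cfg = synthetic_config(), trials_per_level = 9L,
                             seed = cfg$seed) {
  stopifnot(trials_per_level >= 1L)
  out <- vector("list", length(cfg$levels) * trials_per_level)
  k <- 0L
  for (li in seq_along(cfg$levels)) {
    for (tr in seq_len(trials_per_level)) {
      k <- k + 1L
      trial_seed <- (as.integer(seed) + 7919L * li + 104729L * tr) %% .Machine$integer.max
      out[[k]] <- generate_trial(cfg$levels[li], cfg, seed = trial_seed)
    }
  }
  out
}

#' Write / read a recording as CSV
#'
#' Columns: \code{time_s}, one \code{mmg_<label>} column per channel, and
#' \code{force_N}. This dialect is the package's interchange format, so
#' external MMG data can replace the synthetic stage.
#'
#' @param recording An \code{mmg_recording}.
#' @param path Output CSV path.
#' @return \code{write_recording_csv}: the path, invisibly.
#'   \code{read_recording_csv}: an \code{mmg_recording}.
#' @export
write_recording_csv <- function(recording, path) {
  n <- ncol(recording$channels)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$fs)
  for (ch in seq_len(nrow(recording$channels)))
    df[[paste0("mmg_", recording$channel_labels[ch])]] <- recording$channels[ch, ]
  df$force_N <- recording$force
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param fs Sampling rate; if \code{NULL}, inferred from the time column.
#' @export
read_recording_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  mmg_cols <- grep("^mmg_", names(df), value = TRUE)
  if (length(mmg_cols) == 0L || !"force_N" %in% names(df))
    stop("CSV must contain mmg_* columns and a force_N column", call. = FALSE)
  if (is.null(fs)) {
    dt <- diff(df$time_s[1:2])
    fs <- 1 / dt
  }
  new_mmg_recording(t(as.matrix(df[mmg_cols])), df$force_N, fs,
                    sub("^mmg_", "", mmg_cols),
                    meta = list(source = path))
}
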