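# End-to-end pipeline: synthetic data -> preprocessing -> features -> GRA
# -> ICS-SVR -> evaluation report, with all artifacts written to disk and
# every stage reproducible from (config, seed).

#' Pipeline configuration
#'
#' Bundles the per-stage configurations; every run writes the resolved
#' configuration next to its outputs so results are reproducible from the
#' file alone.
#'
#' @param synthetic A \code{\link{synthetic_config}}.
#' @param trials_per_level Trials per contraction level.
#' @param windows_per_level Windows retained per level after segmentation
#'   (the default 50 yields 400 windows over the 8 default levels).
#' @param window A \code{\link{window_spec}}.
#' @param features A \code{\link{feature_params}} list.
#' @param rho GRA resolution coefficient.
#' @param combination Feature-combination label \code{"A"}..\code{"E"}.
#' @param ics \code{\link{ics_params}} for SVR tuning.
#' @param n_reps Evaluation repetitions.
#' @param split Training fraction.
#' @param seed Master seed.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            trials_per_level = 9L,
                            windows_per_level = 50L,
                            window = window_spec(),
                            features = feature_params(),
                            rho = 0.5, combination = "D",
                            ics = ics_params(n_nests = 8L, T = 12L,
                                             lower = 0.001, upper = 500),
                            n_reps = 10L, split = 0.9, seed = 1L) {
  structure(list(synthetic = synthetic, trials_per_level = trials_per_level,
                 windows_per_level = windows_per_level, window = window,
                 features = features, rho = rho, combination = combination,
                 ics = ics, n_reps = n_reps, split = split,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build the windowed feature dataset from synthetic recordings
#'
#' Generates trials at every level, low-pass filters the force, band-pass
#' filters each MMG channel, admits the stable segment, slides windows and
#' extracts the 75-dimensional feature vectors. Windows per level are
#' trimmed to \code{windows_per_level} so every level contributes equally.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @param seed Master seed (defaults to the config seed).
#' @return A \code{feature_matrix} with a \code{level} attribute recording
#'   each window's contraction level.
#' @export
build_feature_dataset <- function(cfg = pipeline_config(), seed = cfg$seed) {
  syn <- cfg$synthetic
  fs <- syn$fs
  windows <- list()
  levels_out <- numeric(0)
  for (li in seq_along(syn$levels)) {
    lvl_windows <- list()
    for (tr in seq_len(cfg$trials_per_level)) {
      trial_seed <- (as.integer(seed) + 7919L * li + 104729L * tr) %%
        .Machine$integer.max
      rec <- generate_trial(syn$levels[li], syn, seed = trial_seed)
      rec$force <- lowpass_force(rec$force, fs)
      seg <- select_stable_segment(rec$force, fs,
                                   duration_s = syn$duration_s,
                                   max_fluct = 0.05)
      idx <- seg[1]:seg[2]
      rec$channels <- rec$channels[, idx, drop = FALSE]
      rec$force <- rec$force[idx]
      for (ch in seq_len(nrow(rec$channels)))
        rec$channels[ch, ] <- bandpass_mmg(rec$channels[ch, ], fs)
      lvl_windows <- c(lvl_windows, slide_windows(rec, cfg$window))
      if (length(lvl_windows) >= cfg$windows_per_level) break
    }
    lvl_windows <- lvl_windows[seq_len(min(length(lvl_windows),
                                           cfg$windows_per_level))]
    windows <- c(windows, lvl_windows)
    levels_out <- c(levels_out, rep(syn$levels[li], length(lvl_windows)))
  }
  fm <- extract_all(windows, fs, channel_labels = syn$channel_labels,
                    params = cfg$features)
  attr(fm, "level") <- levels_out
  fm
}

#' Run the full estimation pipeline
#'
#' synthetic -> filtering/windowing -> features -> GRA ranking ->
#' combination selection -> ICS-SVR evaluation. Writes five artifacts to
#' \code{out_dir}: the feature table, the GRA ranking, the combination
#' membership table, the evaluation report (JSON) and the resolved
#' configuration (JSON).
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @param out_dir Output directory (created if missing); \code{NULL} skips
#'   writing.
#' @return The \code{evaluation_report}, with the GRA result and feature
#'   matrix attached as attributes.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  fm <- stage("synthetic/features", build_feature_dataset(cfg))
  gra <- stage("gra", {
    fx <- fit_zscore(fm$features)
    fy <- fit_zscore(matrix(fm$force, dimnames = list(NULL, "force")))
    relational_analysis(
      as.numeric(apply_zscore(fy, matrix(fm$force,
                                         dimnames = list(NULL, "force")))),
      apply_zscore(fx, fm$features), rho = cfg$rho,
      rows_are_sequences = FALSE)
  })
  stage("gra", select_combination(gra, cfg$combination))  # fail early if empty
  report <- stage("model",
                  evaluate_protocol(fm, combination = cfg$combination,
                                    ics = cfg$ics, n_reps = cfg$n_reps,
                                    split = cfg$split, seed = cfg$seed,
                                    rho = cfg$rho))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_csv(fm, file.path(out_dir, "features.csv"))
    utils::write.csv(gra_ranking(gra), file.path(out_dir, "gra_ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(combination_table(gra),
                     file.path(out_dir, "combinations.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(combination = report$combination,
           mean = as.list(report$mean), sd = as.list(report$sd),
           repetitions = report$repetitions, seed = cfg$seed),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(config_as_list(cfg),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(report, "gra") <- gra
  attr(report, "features") <- fm
  report
}

# JSON-serializable view of the configuration (functions summarized by
# their deparsed body).
config_as_list <- function(cfg) {
  syn <- cfg$synthetic
  list(
    synthetic = list(mvc_newtons = syn$mvc_newtons, levels = syn$levels,
                     duration_s = syn$duration_s, fs = syn$fs,
                     n_channels = syn$n_channels,
                     channel_labels = syn$channel_labels,
                     amp_gain = paste(deparse(syn$amp_gain), collapse = " "),
                     channel_gain = syn$channel_gain,
                     noise_sd = syn$noise_sd,
                     fluctuation_frac = syn$fluctuation_frac),
    trials_per_level = cfg$trials_per_level,
    windows_per_level = cfg$windows_per_level,
    window = list(length = cfg$window$length, overlap = cfg$window$overlap),
    features = cfg$features,
    rho = cfg$rho, combination = cfg$combination,
    ics = list(n_nests = cfg$ics$n_nests, T = cfg$ics$T, beta = cfg$ics$beta,
               amin = cfg$ics$amin, amax = cfg$ics$amax,
               pa_min = cfg$ics$pa_min, pa_max = cfg$ics$pa_max,
               lower = cfg$ics$lower, upper = cfg$ics$upper),
    n_reps = cfg$n_reps, split = cfg$split, seed = cfg$seed)
}
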