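# Command entry points: simulate / score / report.
#
# These functions back the exec/ergorula command-line tool but are exported
# so they can be driven from R directly. Errors are signalled with classed
# conditions so the CLI can map them to distinct exit codes:
# ergorula_usage_error (bad arguments/paths) and ergorula_validation_error
# (input data fails validation).

usage_error <- function(...) {
  stop(structure(class = c("ergorula_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

validation_error <- function(...) {
  stop(structure(class = c("ergorula_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

log_msg <- function(..., verbose = TRUE) {
  if (verbose) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  }
}

#' Simulate a scenario and write it to disk
#'
#' Synthesizes a preset scenario and writes the orientation CSV (matrix
#' dialect), the ground-truth angle series, the reference window scores and
#' a JSON echo of the scenario parameters into `out_dir`. Deterministic for
#' a fixed seed: two runs produce byte-identical files.
#'
#' @param preset preset name (see [scenario_preset()]).
#' @param out_dir output directory (created if missing).
#' @param seed RNG seed.
#' @param duration scenario duration in seconds.
#' @param verbose log progress to stderr.
#' @return Named character vector of the files written, invisibly.
#' @export
cmd_simulate <- function(preset, out_dir, seed = 42, duration = 605,
                         verbose = TRUE) {
  spec <- tryCatch(scenario_preset(preset, duration = duration, seed = seed),
                   error = function(e) usage_error(conditionMessage(e)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_msg("simulating preset '", preset, "' (", duration, " s, seed ", seed, ")",
          verbose = verbose)
  sim <- synthesize(spec)
  paths <- c(
    orientations = file.path(out_dir, "orientations.csv"),
    truth_spine = file.path(out_dir, "truth_spine.csv"),
    truth_neck = file.path(out_dir, "truth_neck.csv"),
    truth_scores = file.path(out_dir, "truth_scores.csv"),
    params = file.path(out_dir, "scenario.json"))
  write_orientation_csv(sim$triplet, paths[["orientations"]])
  write_series_csv(sim$truth$spine, paths[["truth_spine"]])
  write_series_csv(sim$truth$neck, paths[["truth_neck"]])
  utils::write.csv(sim$truth$windows, paths[["truth_scores"]], row.names = FALSE)
  jsonlite::write_json(list(preset = preset, duration = duration, seed = seed),
                       paths[["params"]], auto_unbox = TRUE, pretty = TRUE)
  log_msg("wrote ", length(paths), " files to ", out_dir, verbose = verbose)
  invisible(paths)
}

#' Score an orientation recording
#'
#' Full pipeline on a CSV recording: read and validate, calibrate on the
#' neutral window, extract spine and neck angles, compute the per-window
#' risk index and write the score CSV plus a JSON summary (time fractions
#' and minutes per score level) and a JSON echo of all parameters.
#'
#' @param input orientation CSV path.
#' @param out_dir output directory (created if missing).
#' @param dialect CSV dialect, `"matrix"` or `"quaternion"`.
#' @param calib_start,calib_duration neutral calibration window, seconds.
#' @param cfg a [scoring_config()] (or path to a YAML config file).
#' @param verbose log progress to stderr.
#' @return The `risk_index` data.frame, invisibly. Files written:
#'   `scores.csv`, `summary.json`, `run_params.json`.
#' @export
cmd_score <- function(input, out_dir, dialect = "matrix",
                      calib_start = 0, calib_duration = 5,
                      cfg = scoring_config(), verbose = TRUE) {
  if (!file.exists(input)) usage_error("input file not found: ", input)
  if (is.character(cfg)) {
    if (!file.exists(cfg)) usage_error("config file not found: ", cfg)
    cfg <- read_scoring_config(cfg)
  }
  stopifnot(inherits(cfg, "scoring_config"))
  triplet <- tryCatch(read_orientation_csv(input, dialect = dialect),
                      error = function(e) validation_error(conditionMessage(e)))
  log_msg("read ", length(triplet$imu1$t), " samples/sensor at ",
          signif(triplet$imu1$fs, 4), " Hz", verbose = verbose)
  pose <- tryCatch(calibrate(triplet, calib_start, calib_duration),
                   error = function(e) validation_error(conditionMessage(e)))
  angles <- angle_pipeline(triplet, pose)
  # score only the work period: drop the neutral calibration window
  work <- angles$spine$t >= calib_start + calib_duration
  angles <- lapply(angles, function(a) a[work, , drop = FALSE])
  risk <- tryCatch(score_pipeline(angles$spine, angles$neck, cfg),
                   error = function(e) validation_error(conditionMessage(e)))
  log_msg(nrow(risk), " full window(s) scored", verbose = verbose)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_series_csv(risk, file.path(out_dir, "scores.csv"))
  summ <- summarize_scores(risk)
  jsonlite::write_json(
    list(n_windows = nrow(risk),
         minutes_analyzed = sum(risk$window_end_s - risk$window_start_s) / 60,
         summary = summ),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  jsonlite::write_json(
    list(input = input, dialect = dialect, calib_start = calib_start,
         calib_duration = calib_duration, config = unclass(cfg)),
    file.path(out_dir, "run_params.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(risk)
}

#' Summarize a score CSV
#'
#' Reads a per-window score CSV (as written by [cmd_score()]) and prints a
#' per-score-level breakdown (windows, minutes, percentage) for neck, spine
#' and overall scores; optionally writes it as JSON.
#'
#' @param score_csv path to a score CSV.
#' @param out optional JSON output path.
#' @param verbose print the human-readable table.
#' @return The summary data.frame, invisibly.
#' @export
cmd_report <- function(score_csv, out = NULL, verbose = TRUE) {
  if (!file.exists(score_csv)) usage_error("score file not found: ", score_csv)
  risk <- tryCatch(read_series_csv(score_csv),
                   error = function(e) validation_error(conditionMessage(e)))
  if (!"overall_score" %in% names(risk)) {
    validation_error("not a score CSV: ", score_csv)
  }
  if (nrow(risk) == 0) validation_error("score CSV has no windows")
  summ <- summarize_scores(risk)
  if (verbose) {
    for (lab in unique(summ$output)) {
      sub <- summ[summ$output == lab, ]
      cat(sprintf("%s score:\n", lab))
      for (i in seq_len(nrow(sub))) {
        cat(sprintf("  score %d: %d window(s), %.1f min, %.1f%%\n",
                    sub$score[i], sub$n_windows[i], sub$minutes[i],
                    100 * sub$fraction[i]))
      }
    }
  }
  if (!is.null(out)) {
    jsonlite::write_json(summ, out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(summ)
}
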