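# The time-varying ergonomic risk index.
#
# Per segment (spine, neck) the angle series is low-pass filtered with a
# centered moving average, split into tumbling 5-min windows, and each
# window is scored in two lines:
#   * flexo-extension: per-sample staircase quantization into levels 1-4,
#     dwell-time accounting, and selection of the highest level held for
#     longer than the dwell threshold (1 min by default);
#   * twist and lateral bending: +1 each when the angle stays outside the
#     [-band, +band] interval for longer than the dwell threshold.
# The segment score (1-6) is the sum of the two lines; neck and spine
# scores enter the RULA section-B table with the legs score to give the
# overall head-and-trunk score per window.

#' Scoring configuration
#'
#' All tunable parameters of the risk-index algorithm, with the reference
#' defaults: 75 Hz sampling, an 875-sample moving average (11.67 s, -3 dB at
#' 0.038 Hz), 5-minute tumbling windows, a 1-minute dwell threshold,
#' flexion staircase thresholds 0/20/60 degrees for the spine and 0/10/20
#' degrees for the neck, a +/-10 degree twist/bend band and a constant legs
#' score of 1.
#'
#' The spine staircase maps (-Inf,0] to 1, (0,20] to 2, (20,60] to 3 and
#' (60,Inf) to 4; extension (negative flexion) of the spine takes the
#' lowest score. The neck staircase maps [0,10] to 1, (10,20] to 2,
#' (20,Inf) to 3, and any extension (flexion < 0) to 4, the highest level,
#' reflecting that a backwards-tilted head is the riskiest neck posture.
#'
#' @param fs sampling frequency, Hz.
#' @param filter_len moving-average length in samples (odd).
#' @param window_len analysis window length, seconds.
#' @param dwell_threshold dwell-time threshold, seconds (strictly exceeded).
#' @param spine_flexion_thresholds,neck_flexion_thresholds strictly
#'   increasing staircase thresholds, degrees; the first neck threshold is
#'   the extension boundary.
#' @param twist_bend_band half-width of the tolerated twist/bend interval,
#'   degrees.
#' @param legs_score 1 (supported, balanced) or 2.
#' @param muscle_score,force_score optional section additions (integers,
#'   default 0) applied only when deriving a grand score; they are never
#'   estimated from sensor data.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(fs = 75,
                           filter_len = 875,
                           window_len = 300,
                           dwell_threshold = 60,
                           spine_flexion_thresholds = c(0, 20, 60),
                           neck_flexion_thresholds = c(0, 10, 20),
                           twist_bend_band = 10,
                           legs_score = 1,
                           muscle_score = 0,
                           force_score = 0) {
  stopifnot(fs > 0, filter_len >= 3, window_len > 0, dwell_threshold > 0)
  if (filter_len %% 2 != 1) stop("filter_len must be odd (centered moving average)")
  if (window_len <= dwell_threshold) {
    stop("window_len must exceed dwell_threshold")
  }
  for (th in list(spine_flexion_thresholds, neck_flexion_thresholds)) {
    if (length(th) != 3 || any(diff(th) <= 0)) {
      stop("flexion thresholds must be 3 strictly increasing values")
    }
  }
  if (twist_bend_band <= 0) stop("twist_bend_band must be positive")
  if (!legs_score %in% c(1, 2)) stop("legs_score must be 1 or 2")
  structure(list(fs = fs, filter_len = filter_len, window_len = window_len,
                 dwell_threshold = dwell_threshold,
                 spine_flexion_thresholds = spine_flexion_thresholds,
                 neck_flexion_thresholds = neck_flexion_thresholds,
                 twist_bend_band = twist_bend_band, legs_score = legs_score,
                 muscle_score = muscle_score, force_score = force_score),
            class = "scoring_config")
}

#' Read / write a scoring configuration as YAML
#'
#' The file holds any subset of the [scoring_config()] fields; unspecified
#' fields take their defaults.
#'
#' @param path YAML file path.
#' @param cfg a `scoring_config` (for writing).
#' @return For reading, a `scoring_config`; for writing, `path` invisibly.
#' @export
read_scoring_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scoring_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(scoring_config, vals)
}

#' @rdname read_scoring_config
#' @export
write_scoring_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scoring_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Centered moving average with edge renormalization: out[i] is the mean of
# x over the available part of [i-h, i+h], so the DC gain is 1 everywhere,
# including block edges. O(n) via cumulative sums.
moving_average <- function(x, filter_len) {
  n <- length(x)
  h <- (filter_len - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Low-pass filter an angle series
#'
#' Applies the centered moving average independently to the flexion,
#' bending and twist channels. With the default 875-sample length at 75 Hz
#' the -3 dB cut-off is 0.038 Hz, so postures held for a short time (e.g.
#' 3-s excursions) are strongly attenuated while sustained postures pass
#' unchanged (DC gain 1). Edges use renormalized partial windows.
#'
#' @param series an angle-series data.frame
#'   (`t,segment,flexion_deg,bending_deg,twist_deg`).
#' @param cfg a [scoring_config()].
#' @return The filtered series, same schema.
#' @export
smooth_angles <- function(series, cfg = scoring_config()) {
  stopifnot(is.data.frame(series))
  if (nrow(series) < 3) stop("series too short to filter (< 3 samples)")
  out <- series
  for (cl in c("flexion_deg", "bending_deg", "twist_deg")) {
    if (any(!is.finite(series[[cl]]))) stop("non-finite values in ", cl)
    out[[cl]] <- moving_average(series[[cl]], cfg$filter_len)
  }
  out
}

#' Magnitude response of the smoothing filter
#'
#' Exact frequency response of the length-`filter_len` centered moving
#' average at sampling rate `fs` (the periodic-sinc / Dirichlet form), and a
#' numeric locator for its -3 dB cut-off frequency.
#'
#' @param f frequency in Hz (vectorized).
#' @param cfg a [scoring_config()].
#' @return `ma_response`: |H(f)| in [0, 1]. `ma_cutoff_hz`: the -3 dB
#'   frequency in Hz.
#' @export
ma_response <- function(f, cfg = scoring_config()) {
  L <- cfg$filter_len
  x <- pi * f / cfg$fs
  out <- ifelse(abs(x) < 1e-12, 1, abs(sin(L * x) / (L * sin(x))))
  pmin(out, 1)
}

#' @rdname ma_response
#' @export
ma_cutoff_hz <- function(cfg = scoring_config()) {
  target <- 1 / sqrt(2)
  upper <- cfg$fs / cfg$filter_len  # first spectral null of the average
  stats::uniroot(function(f) ma_response(f, cfg) - target,
                 lower = 1e-9, upper = upper * 0.999, tol = 1e-12)$root
}

#' Staircase quantization of flexo-extension angles
#'
#' Maps an angle to an instantaneous score level 1-4 using the
#' segment-specific staircase (see [scoring_config()] for the interval
#' conventions).
#'
#' @param angle angle(s) in degrees (vectorized).
#' @param segment `"spine"` or `"neck"`.
#' @param cfg a [scoring_config()].
#' @return Integer level(s) in 1..4.
#' @export
quantize_flexion <- function(angle, segment = c("spine", "neck"),
                             cfg = scoring_config()) {
  segment <- match.arg(segment)
  if (any(!is.finite(angle))) stop("non-finite angle passed to quantize_flexion")
  if (segment == "spine") {
    th <- cfg$spine_flexion_thresholds
    1L + findInterval(angle, th, left.open = TRUE)
  } else {
    th <- cfg$neck_flexion_thresholds
    lev <- 1L + findInterval(angle, th[-1], left.open = TRUE)
    lev[angle < th[1]] <- 4L  # neck extension: highest level, no dead band
    lev
  }
}

#' Dwell time per score level within a window
#'
#' Accumulated seconds spent at each instantaneous level, assuming uniform
#' sampling at `fs`: dwell(level) = count(level) / fs. The dwell times of a
#' window always sum to its sample count divided by `fs`.
#'
#' @param levels integer vector of per-sample levels (1..4).
#' @param cfg a [scoring_config()].
#' @return Named numeric vector of seconds for levels "1".."4".
#' @export
dwell_times <- function(levels, cfg = scoring_config()) {
  if (length(levels) == 0) stop("empty window")
  if (any(!is.finite(levels)) || any(!levels %in% 1:4)) {
    stop("levels must be integers in 1..4")
  }
  counts <- tabulate(levels, nbins = 4)
  stats::setNames(counts / cfg$fs, as.character(1:4))
}

#' Window flexo-extension score
#'
#' The highest level whose dwell time strictly exceeds the dwell threshold.
#' For a full window this is always defined: with 4 levels over 300 s some
#' level accumulates at least 75 s > 60 s (pigeonhole). Partial windows are
#' discarded upstream and never scored.
#'
#' @param dwell named dwell vector from [dwell_times()].
#' @param cfg a [scoring_config()].
#' @return Integer score in 1..4.
#' @export
window_flexo_score <- function(dwell, cfg = scoring_config()) {
  eligible <- which(dwell > cfg$dwell_threshold)
  if (length(eligible) == 0) {
    stop("no level held longer than the dwell threshold: window too short ",
         "for the dwell rule (only full windows may be scored)")
  }
  max(eligible)
}

#' Twist / bending adjustment for a window
#'
#' Adds 1 when the angle stays outside the [-band, +band] interval for a
#' total time strictly exceeding the dwell threshold, regardless of how far
#' outside it goes; otherwise 0.
#'
#' @param angles per-sample angles in degrees for one window.
#' @param cfg a [scoring_config()].
#' @return 0 or 1 (integer).
#' @export
window_adjustment <- function(angles, cfg = scoring_config()) {
  if (length(angles) == 0) stop("empty window")
  if (any(!is.finite(angles))) stop("non-finite angles in window")
  outside <- sum(abs(angles) > cfg$twist_bend_band) / cfg$fs
  as.integer(outside > cfg$dwell_threshold)
}

#' Segment score
#'
#' Sum of the flexo-extension score (1-4) and the twist and bending
#' adjustments (0 or 1 each), giving 1-6.
#'
#' @param flexo integer 1..4.
#' @param twist_adj,bend_adj integers 0 or 1.
#' @return Integer in 1..6. Vectorized.
#' @export
segment_score <- function(flexo, twist_adj, bend_adj) {
  if (any(!flexo %in% 1:4)) stop("flexo score out of range 1..4")
  if (any(!twist_adj %in% 0:1) || any(!bend_adj %in% 0:1)) {
    stop("adjustments must be 0 or 1")
  }
  as.integer(flexo + twist_adj + bend_adj)
}

# Score one full window of filtered angles for one segment.
score_window <- function(flexion, bending, twist, segment, cfg) {
  lev <- quantize_flexion(flexion, segment, cfg)
  flexo <- window_flexo_score(dwell_times(lev, cfg), cfg)
  tw <- window_adjustment(twist, cfg)
  bd <- window_adjustment(bending, cfg)
  list(flexo = flexo, twist_adj = tw, bend_adj = bd,
       score = segment_score(flexo, tw, bd))
}

#' Compute the per-window ergonomic risk index
#'
#' Runs the full scoring chain on a spine and a neck angle series sharing
#' timestamps: moving-average smoothing, segmentation into contiguous
#' blocks, division of each block into consecutive non-overlapping full
#' windows (a trailing remainder shorter than `window_len` is discarded
#' with a warning), per-window flexo-extension and adjustment scoring for
#' each segment, and combination through the section-B look-up table with
#' the configured legs score.
#'
#' @param spine,neck angle-series data.frames on identical timestamps.
#' @param cfg a [scoring_config()].
#' @param max_gap gap tolerance in seconds (default `3 / fs`).
#' @return A data.frame of class `risk_index` with one row per window:
#'   `window_start_s`, `window_end_s`, `neck_flexo`, `neck_adj`,
#'   `neck_score`, `spine_flexo`, `spine_adj`, `spine_score`, `legs`,
#'   `overall_score`.
#' @export
score_pipeline <- function(spine, neck, cfg = scoring_config(), max_gap = NULL) {
  stopifnot(is.data.frame(spine), is.data.frame(neck))
  if (!isTRUE(all.equal(spine$t, neck$t))) {
    stop("spine and neck series must share timestamps")
  }
  if (is.null(max_gap)) max_gap <- 3 / cfg$fs
  win_n <- as.integer(round(cfg$window_len * cfg$fs))

  blocks <- detect_gaps(list(t = spine$t, fs = cfg$fs), max_gap = max_gap)
  rows <- list()
  discarded <- 0
  for (b in seq_len(nrow(blocks))) {
    idx <- blocks$start[b]:blocks$end[b]
    sp <- smooth_angles(spine[idx, , drop = FALSE], cfg)
    nk <- smooth_angles(neck[idx, , drop = FALSE], cfg)
    nwin <- length(idx) %/% win_n
    discarded <- discarded + (length(idx) - nwin * win_n) / cfg$fs
    for (w in seq_len(nwin)) {
      sel <- ((w - 1) * win_n + 1):(w * win_n)
      s <- score_window(sp$flexion_deg[sel], sp$bending_deg[sel],
                        sp$twist_deg[sel], "spine", cfg)
      k <- score_window(nk$flexion_deg[sel], nk$bending_deg[sel],
                        nk$twist_deg[sel], "neck", cfg)
      rows[[length(rows) + 1]] <- data.frame(
        window_start_s = sp$t[sel[1]],
        window_end_s = sp$t[sel[1]] + cfg$window_len,
        neck_flexo = k$flexo, neck_adj = k$twist_adj + k$bend_adj,
        neck_score = k$score,
        spine_flexo = s$flexo, spine_adj = s$twist_adj + s$bend_adj,
        spine_score = s$score,
        legs = cfg$legs_score,
        overall_score = table_b(k$score, s$score, cfg$legs_score))
    }
  }
  if (length(rows) == 0) {
    stop("no full ", cfg$window_len, "-s window available in any contiguous block")
  }
  if (discarded > 0) {
    warning(sprintf("discarded %.1f s of trailing data not filling a full window",
                    discarded))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("risk_index", "data.frame")
  out
}

#' Summarize a risk index series
#'
#' Per-score time fractions and minutes for the neck, spine and overall
#' scores, mirroring the usual pie-chart style summary of time at each risk
#' level. Fractions sum to 1 for each output.
#'
#' @param risk a `risk_index` data.frame from [score_pipeline()].
#' @return A data.frame with columns `output` (neck/spine/overall), `score`,
#'   `n_windows`, `minutes`, `fraction`.
#' @export
summarize_scores <- function(risk) {
  stopifnot(is.data.frame(risk))
  if (nrow(risk) == 0) stop("empty risk index series")
  win_min <- (risk$window_end_s - risk$window_start_s) / 60
  per_output <- function(scores, label) {
    agg <- stats::aggregate(
      data.frame(n_windows = rep(1L, length(scores)), minutes = win_min),
      by = list(score = scores), FUN = sum)
    data.frame(output = label, score = agg$score, n_windows = agg$n_windows,
               minutes = agg$minutes, fraction = agg$n_windows / length(scores))
  }
  out <- rbind(per_output(risk$neck_score, "neck"),
               per_output(risk$spine_score, "spine"),
               per_output(risk$overall_score, "overall"))
  rownames(out) <- NULL
  out
}
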