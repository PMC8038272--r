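# Deliberately naive per-sample reference scorer (oracle pattern).
#
# This re-implements the whole window-scoring chain with explicit loops and
# no shared code with the production scorer (score_pipeline), so that the
# two can be compared against each other in tests and so that synthetic
# scenarios carry expected scores that do not depend on the code under
# test. Keep it slow and obvious; do not "optimize" it.

#' Brute-force reference window scorer
#'
#' Per-sample loop implementation of the risk-index algorithm: loop-based
#' centered moving average with renormalized edges, per-sample staircase
#' quantization via if/else chains, dwell counting by iteration, and the
#' same window partition rule as the production scorer. Used to compute the
#' expected scores attached to synthetic scenarios and as the independent
#' oracle in equivalence tests.
#'
#' @param spine,neck angle-series data.frames on identical timestamps
#'   (single contiguous block).
#' @param cfg a [scoring_config()].
#' @return A data.frame in the same schema as [score_pipeline()].
#' @export
reference_score_windows <- function(spine, neck, cfg = scoring_config()) {
  naive_ma <- function(x, L) {
    n <- length(x)
    h <- (L - 1) %/% 2
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1, i - h)
      hi <- min(n, i + h)
      out[i] <- mean(x[lo:hi])
    }
    out
  }
  quant_spine <- function(a) {
    th <- cfg$spine_flexion_thresholds
    if (a <= th[1]) 1L else if (a <= th[2]) 2L else if (a <= th[3]) 3L else 4L
  }
  quant_neck <- function(a) {
    th <- cfg$neck_flexion_thresholds
    if (a < th[1]) 4L else if (a <= th[2]) 1L else if (a <= th[3]) 2L else 3L
  }
  score_segment <- function(flex, bend, twist, segment) {
    dwell <- c(0, 0, 0, 0)
    t_twist <- 0
    t_bend <- 0
    for (i in seq_along(flex)) {
      lev <- if (segment == "spine") quant_spine(flex[i]) else quant_neck(flex[i])
      dwell[lev] <- dwell[lev] + 1 / cfg$fs
      if (abs(twist[i]) > cfg$twist_bend_band) t_twist <- t_twist + 1 / cfg$fs
      if (abs(bend[i]) > cfg$twist_bend_band) t_bend <- t_bend + 1 / cfg$fs
    }
    flexo <- 0L
    for (lev in 1:4) if (dwell[lev] > cfg$dwell_threshold) flexo <- lev
    if (flexo == 0L) stop("reference scorer: no level exceeds the dwell threshold")
    tw <- if (t_twist > cfg$dwell_threshold) 1L else 0L
    bd <- if (t_bend > cfg$dwell_threshold) 1L else 0L
    list(flexo = flexo, adj = tw + bd, score = flexo + tw + bd)
  }

  filt <- list()
  for (seg in c("spine", "neck")) {
    src <- if (seg == "spine") spine else neck
    filt[[seg]] <- data.frame(
      flexion = naive_ma(src$flexion_deg, cfg$filter_len),
      bending = naive_ma(src$bending_deg, cfg$filter_len),
      twist = naive_ma(src$twist_deg, cfg$filter_len))
  }
  win_n <- as.integer(round(cfg$window_len * cfg$fs))
  nwin <- nrow(spine) %/% win_n
  empty <- data.frame(window_start_s = numeric(0), window_end_s = numeric(0),
                      neck_flexo = integer(0), neck_adj = integer(0),
                      neck_score = integer(0), spine_flexo = integer(0),
                      spine_adj = integer(0), spine_score = integer(0),
                      legs = numeric(0), overall_score = integer(0))
  if (nwin == 0) return(empty)
  rows <- list()
  for (w in seq_len(nwin)) {
    sel <- ((w - 1) * win_n + 1):(w * win_n)
    s <- score_segment(filt$spine$flexion[sel], filt$spine$bending[sel],
                       filt$spine$twist[sel], "spine")
    k <- score_segment(filt$neck$flexion[sel], filt$neck$bending[sel],
                       filt$neck$twist[sel], "neck")
    rows[[w]] <- data.frame(
      window_start_s = spine$t[sel[1]],
      window_end_s = spine$t[sel[1]] + cfg$window_len,
      neck_flexo = k$flexo, neck_adj = k$adj, neck_score = k$score,
      spine_flexo = s$flexo, spine_adj = s$adj, spine_score = s$score,
      legs = cfg$legs_score,
      overall_score = table_b(k$score, s$score, cfg$legs_score))
  }
  do.call(rbind, rows)
}
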