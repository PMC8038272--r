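# Smoothing filter, quantization, dwell-time scoring, look-up tables.

test_that("moving average has unit DC gain and renormalized edges", {
  cfg <- scoring_config()
  ser <- const_series("spine", flexion = 30, duration = 20)
  out <- smooth_angles(ser, cfg)
  expect_equal(out$flexion_deg, rep(30, nrow(ser)), tolerance = 1e-9)

  # short series still filter (renormalized partial windows)
  ser3 <- const_series("spine", flexion = 7, duration = 3 / 75)
  expect_equal(smooth_angles(ser3, cfg)$flexion_deg, rep(7, 3), tolerance = 1e-12)
  expect_error(smooth_angles(ser3[1:2, ], cfg), "too short")
})

test_that("a 3-s 30-degree pulse is attenuated to pulse_samples/filter_len", {
  cfg <- scoring_config()
  n <- 3000
  x <- numeric(n)
  x[1400:1624] <- 30  # 225 samples = 3 s at 75 Hz
  ser <- const_series("spine", duration = n / 75)
  ser$flexion_deg <- x
  out <- smooth_angles(ser, cfg)$flexion_deg
  expect_equal(max(out), 30 * 225 / 875, tolerance = 1e-9)
  # interior of the output matches a direct convolution oracle
  conv <- stats::filter(x, rep(1 / 875, 875), sides = 2)
  interior <- 438:(n - 437)
  expect_equal(out[interior], as.numeric(conv[interior]), tolerance = 1e-9)
  # peak stays below the first spine threshold change band (10 deg) and
  # below the twist/bend band
  expect_lt(max(out), 10)
})

test_that("the filter passes 0.707 amplitude at its -3 dB frequency", {
  cfg <- scoring_config()
  f3 <- ma_cutoff_hz(cfg)
  n <- 45000  # 600 s
  t <- (seq_len(n) - 1) / cfg$fs
  ser <- const_series("spine", duration = n / cfg$fs)
  ser$flexion_deg <- sin(2 * pi * f3 * t)
  out <- smooth_angles(ser, cfg)$flexion_deg
  interior <- 875:(n - 875)
  expect_equal(max(abs(out[interior])), 1 / sqrt(2), tolerance = 0.01)
})

test_that("flexion staircases follow the segment-specific thresholds", {
  cfg <- scoring_config()
  # spine: (-inf,0] 1, (0,20] 2, (20,60] 3, (60,inf) 4
  expect_identical(quantize_flexion(c(-40, 0, 10, 20, 30, 60, 61), "spine", cfg),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L))
  # neck: extension scores 4; [0,10] 1, (10,20] 2, (20,inf) 3
  expect_identical(quantize_flexion(c(-15, -0.001, 0, 10, 15, 20, 25), "neck", cfg),
                   c(4L, 4L, 1L, 1L, 2L, 2L, 3L))
  expect_error(quantize_flexion(NaN, "spine", cfg), "non-finite")
})

test_that("dwell times count samples per level and sum to window coverage", {
  cfg <- scoring_config()
  lev <- rep(3L, 300 * 75)
  d <- dwell_times(lev, cfg)
  expect_equal(unname(d), c(0, 0, 300, 0))

  lev <- c(rep(4L, 120 * 75), rep(2L, 180 * 75))
  d <- dwell_times(lev, cfg)
  expect_equal(unname(d), c(0, 180, 0, 120))

  lev <- rep(c(2L, 3L), 150 * 75)
  d <- dwell_times(lev, cfg)
  expect_equal(d[["2"]], 150)
  expect_equal(d[["3"]], 150)
  expect_equal(sum(d), length(lev) / cfg$fs)
  expect_error(dwell_times(integer(0), cfg), "empty")
})

test_that("window score is the highest level held beyond the dwell threshold", {
  cfg <- scoring_config()
  expect_identical(window_flexo_score(c(`1` = 0, `2` = 180, `3` = 0, `4` = 120), cfg), 4L)
  # 50 s at level 4 does not exceed the 60-s threshold
  expect_identical(window_flexo_score(c(`1` = 0, `2` = 250, `3` = 0, `4` = 50), cfg), 2L)
  expect_identical(window_flexo_score(c(`1` = 0, `2` = 0, `3` = 300, `4` = 0), cfg), 3L)
  # exactly at the threshold is not "longer than"
  expect_identical(window_flexo_score(c(`1` = 240, `2` = 0, `3` = 0, `4` = 60), cfg), 1L)
  expect_error(window_flexo_score(c(`1` = 10, `2` = 10, `3` = 10, `4` = 10), cfg),
               "dwell threshold")
})

test_that("twist/bend adjustments require both magnitude and dwell", {
  cfg <- scoring_config()
  fs <- cfg$fs
  expect_identical(window_adjustment(rep(45, 300 * fs), cfg), 1L)
  expect_identical(window_adjustment(rep(5, 300 * fs), cfg), 0L)
  # 59 s outside the band is not longer than 60 s
  expect_identical(window_adjustment(c(rep(15, 59 * fs), rep(0, 241 * fs)), cfg), 0L)
  # 61 s is
  expect_identical(window_adjustment(c(rep(-15, 61 * fs), rep(0, 239 * fs)), cfg), 1L)
  # band is exclusive: exactly 10 degrees is inside
  expect_identical(window_adjustment(rep(10, 300 * fs), cfg), 0L)
  expect_error(window_adjustment(c(1, NaN), cfg), "non-finite")
})

test_that("segment score sums its components within 1..6", {
  expect_identical(segment_score(4L, 1L, 1L), 6L)
  expect_identical(segment_score(1L, 0L, 0L), 1L)
  expect_identical(segment_score(3L, 1L, 0L), 4L)
  expect_error(segment_score(5L, 0L, 0L), "out of range")
  expect_error(segment_score(2L, 2L, 0L), "0 or 1")
})

test_that("section-B table matches the published structure", {
  expect_identical(table_b(1, 1, 1), 1L)
  # high-risk cells of 7 or more are reachable with legs = 1
  all_cells <- outer(1:6, 1:6, function(n, s) table_b(n, s, 1))
  expect_true(any(all_cells >= 7))
  expect_identical(table_b(4, 4, 1), 7L)
  # monotone non-decreasing in each argument
  expect_true(all(apply(all_cells, 1, diff) >= 0))
  expect_true(all(apply(all_cells, 2, diff) >= 0))
  legs2 <- outer(1:6, 1:6, function(n, s) table_b(n, s, 2))
  expect_true(all(legs2 >= all_cells))
  expect_error(table_b(7, 1, 1), "1..6")
  expect_error(table_b(1, 0, 1), "1..6")
  expect_error(table_b(1, 1, 3), "1..2")
  # transcription checksum
  expect_identical(sum(all_cells) + sum(legs2), 211L + 227L)
})

test_that("grand-score table obeys the published constraints", {
  expect_identical(grand_score(1, 1), 1L)
  grid <- outer(1:8, 1:7, grand_score)
  expect_identical(max(grid), 7L)
  expect_true(all(apply(grid, 1, diff) >= 0))
  expect_true(all(apply(grid, 2, diff) >= 0))
  # a neck-trunk-legs section score of 6 forces a grand score of at least 5
  expect_identical(min(grand_score(1:8, 6)), 5L)
  # "8+" / "7+" saturation
  expect_identical(grand_score(11, 9), grand_score(8, 7))
  expect_error(grand_score(0, 1), ">= 1")
  # transcription checksum
  expect_identical(sum(grid), 269L)
})

test_that("score pipeline reproduces the canonical single-window cases", {
  spine0 <- const_series("spine")
  neck0 <- const_series("neck")
  risk <- score_pipeline(spine0, neck0)
  expect_identical(nrow(risk), 1L)
  expect_identical(risk$neck_score, 1L)
  expect_identical(risk$spine_score, 1L)
  expect_identical(risk$overall_score, 1L)

  # sustained neck extension scores the maximum flexo level
  risk <- score_pipeline(spine0, const_series("neck", flexion = -15))
  expect_identical(risk$neck_flexo, 4L)
  expect_identical(risk$overall_score, table_b(4, 1, 1))

  # deep spine flexion with twist and bend saturates the segment score
  risk <- score_pipeline(const_series("spine", flexion = 90, bending = 20, twist = 20),
                         neck0)
  expect_identical(risk$spine_flexo, 4L)
  expect_identical(risk$spine_adj, 2L)
  expect_identical(risk$spine_score, 6L)

  # trailing data short of a full window is discarded with a warning
  expect_warning(risk <- score_pipeline(const_series("spine", duration = 310),
                                        const_series("neck", duration = 310)),
                 "discarded")
  expect_identical(nrow(risk), 1L)
  # no full window at all
  expect_error(suppressWarnings(
    score_pipeline(const_series("spine", duration = 100),
                   const_series("neck", duration = 100))), "no full")
})

test_that("window scoring is well defined for any full window (pigeonhole)", {
  cfg <- cfg_small()  # 30-s windows, 6-s dwell threshold, fs 10
  set.seed(41)
  n <- cfg$window_len * cfg$fs
  for (i in 1:200) {
    lev <- sample(1:4, n, replace = TRUE, prob = stats::runif(4))
    d <- dwell_times(lev, cfg)
    expect_gte(max(d), cfg$window_len / 4)
    s <- window_flexo_score(d, cfg)
    expect_true(s %in% 1:4)
    expect_gt(d[[as.character(s)]], cfg$dwell_threshold)
  }
})

test_that("vectorized window scorer equals a per-sample brute-force accumulator", {
  cfg <- cfg_small()
  set.seed(43)
  n <- cfg$window_len * cfg$fs
  brute <- function(flex, bend, twist, segment) {
    th <- if (segment == "spine") cfg$spine_flexion_thresholds else cfg$neck_flexion_thresholds
    dwell <- c(0, 0, 0, 0); tt <- 0; tb <- 0
    for (i in seq_along(flex)) {
      a <- flex[i]
      lev <- if (segment == "spine") {
        if (a <= th[1]) 1 else if (a <= th[2]) 2 else if (a <= th[3]) 3 else 4
      } else {
        if (a < th[1]) 4 else if (a <= th[2]) 1 else if (a <= th[3]) 2 else 3
      }
      dwell[lev] <- dwell[lev] + 1 / cfg$fs
      if (abs(twist[i]) > cfg$twist_bend_band) tt <- tt + 1 / cfg$fs
      if (abs(bend[i]) > cfg$twist_bend_band) tb <- tb + 1 / cfg$fs
    }
    flexo <- max(which(dwell > cfg$dwell_threshold))
    flexo + (tt > cfg$dwell_threshold) + (tb > cfg$dwell_threshold)
  }
  for (i in 1:1000) {
    segment <- if (i %% 2 == 0) "spine" else "neck"
    # random-walk angles so dwell patterns are serially correlated
    flex <- cumsum(stats::rnorm(n, sd = 3)) + stats::runif(1, -30, 70)
    bend <- cumsum(stats::rnorm(n, sd = 2)) + stats::runif(1, -15, 15)
    twist <- cumsum(stats::rnorm(n, sd = 2)) + stats::runif(1, -15, 15)
    got <- ergorula:::score_window(flex, bend, twist, segment, cfg)
    expect_identical(got$score, as.integer(brute(flex, bend, twist, segment)))
  }
})

test_that("increasing spine flexion never decreases any score", {
  cfg <- cfg_small()
  set.seed(44)
  n <- cfg$window_len * cfg$fs
  for (i in 1:50) {
    flex <- cumsum(stats::rnorm(n, sd = 2)) + stats::runif(1, -20, 60)
    bend <- stats::rnorm(n, sd = 5)
    twist <- stats::rnorm(n, sd = 5)
    delta <- stats::runif(1, 0, 40)
    a <- ergorula:::score_window(flex, bend, twist, "spine", cfg)
    b <- ergorula:::score_window(flex + delta, bend, twist, "spine", cfg)
    expect_gte(b$flexo, a$flexo)
    expect_gte(b$score, a$score)
    expect_gte(table_b(1, b$score, 1), table_b(1, a$score, 1))
  }
})

test_that("scoring config validates its invariants and round-trips via YAML", {
  expect_error(scoring_config(filter_len = 874), "odd")
  expect_error(scoring_config(window_len = 50, dwell_threshold = 60), "exceed")
  expect_error(scoring_config(spine_flexion_thresholds = c(0, 60, 20)), "increasing")
  expect_error(scoring_config(twist_bend_band = 0), "positive")
  expect_error(scoring_config(legs_score = 3), "legs_score")

  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- scoring_config(window_len = 120, dwell_threshold = 30, legs_score = 2)
  write_scoring_config(cfg, path)
  expect_equal(read_scoring_config(path), cfg)
  writeLines("bogus_field: 3", path)
  expect_error(read_scoring_config(path), "unknown config field")
})

test_that("summaries report fractions that sum to one per output", {
  risk <- suppressWarnings(score_pipeline(
    const_series("spine", flexion = 90, duration = 600),
    const_series("neck", duration = 600)))
  summ <- summarize_scores(risk)
  for (lab in c("neck", "spine", "overall")) {
    expect_equal(sum(summ$fraction[summ$output == lab]), 1, tolerance = 1e-12)
  }
  expect_equal(sum(summ$minutes[summ$output == "overall"]), 10)
  expect_error(summarize_scores(risk[0, ]), "empty")
})
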