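# RULA look-up tables (McAtamney & Corlett's published scoring tables).
#
# TABLE_B combines the neck posture score (1-6) and trunk posture score
# (1-6) with the legs score (1 = supported/balanced, 2 otherwise) into the
# section-B head-and-trunk score. TABLE_C (the grand-score table) combines
# the arm-and-wrist section score (rows, 1-8 with 8 meaning "8 or more")
# with the neck-trunk-legs section score (columns, 1-7 with 7 meaning
# "7 or more") into the final RULA score 1-7.

TABLE_B <- array(0L, c(6, 6, 2), dimnames = list(
  neck = 1:6, trunk = 1:6, legs = 1:2))
TABLE_B[, , 1] <- rbind(
  c(1L, 2L, 3L, 5L, 6L, 7L),
  c(2L, 2L, 4L, 5L, 6L, 7L),
  c(3L, 3L, 4L, 5L, 6L, 7L),
  c(5L, 5L, 6L, 7L, 7L, 8L),
  c(7L, 7L, 7L, 8L, 8L, 8L),
  c(8L, 8L, 8L, 8L, 9L, 9L))
TABLE_B[, , 2] <- rbind(
  c(3L, 3L, 4L, 5L, 6L, 7L),
  c(3L, 3L, 5L, 5L, 7L, 7L),
  c(3L, 4L, 5L, 6L, 7L, 7L),
  c(5L, 6L, 7L, 7L, 7L, 8L),
  c(7L, 7L, 8L, 8L, 8L, 8L),
  c(8L, 8L, 8L, 9L, 9L, 9L))

TABLE_C <- rbind(
  c(1L, 2L, 3L, 3L, 4L, 5L, 5L),
  c(2L, 2L, 3L, 4L, 4L, 5L, 5L),
  c(3L, 3L, 3L, 4L, 4L, 5L, 6L),
  c(3L, 3L, 3L, 4L, 5L, 6L, 6L),
  c(4L, 4L, 4L, 5L, 6L, 7L, 7L),
  c(4L, 4L, 5L, 6L, 6L, 7L, 7L),
  c(5L, 5L, 6L, 6L, 7L, 7L, 7L),
  c(5L, 5L, 6L, 7L, 7L, 7L, 7L))
dimnames(TABLE_C) <- list(arm_wrist = 1:8, neck_trunk_legs = 1:7)

#' Section-B look-up: overall head-and-trunk score
#'
#' Combines the neck and spine (trunk) segment scores, each 1-6, with the
#' legs score into the overall head-and-trunk score via the RULA section-B
#' table. Entries are monotone non-decreasing in every argument.
#'
#' @param neck_score,spine_score integer segment scores in 1..6.
#' @param legs 1 when legs and feet are supported and evenly balanced, 2
#'   otherwise.
#' @return Integer overall score (1-9). Vectorized over the score arguments.
#' @export
table_b <- function(neck_score, spine_score, legs = 1) {
  n <- max(length(neck_score), length(spine_score), length(legs))
  neck_score <- rep_len(neck_score, n)
  spine_score <- rep_len(spine_score, n)
  legs <- rep_len(legs, n)
  chk <- function(x, lo, hi, what) {
    if (any(!is.finite(x)) || any(x != as.integer(x)) || any(x < lo | x > hi)) {
      stop(what, " must be an integer in ", lo, "..", hi)
    }
  }
  chk(neck_score, 1, 6, "neck_score")
  chk(spine_score, 1, 6, "spine_score")
  chk(legs, 1, 2, "legs")
  TABLE_B[cbind(neck_score, spine_score, legs)]
}

#' RULA grand score
#'
#' Combines the arm-and-wrist section score (section A plus muscle-use and
#' force additions) with the neck-trunk-legs section score (section B plus
#' the same additions) into the final RULA score via the published grand
#' table. Rows above 8 and columns above 7 saturate, following the table's
#' "8+" / "7+" convention.
#'
#' @param score_arm_wrist arm-and-wrist section score (integer >= 1).
#' @param score_neck_trunk_legs neck-trunk-legs section score (integer >= 1).
#' @return Integer grand score in 1..7. Vectorized.
#' @export
grand_score <- function(score_arm_wrist, score_neck_trunk_legs) {
  n <- max(length(score_arm_wrist), length(score_neck_trunk_legs))
  a <- rep_len(score_arm_wrist, n)
  b <- rep_len(score_neck_trunk_legs, n)
  if (any(!is.finite(a)) || any(!is.finite(b)) ||
      any(a != as.integer(a)) || any(b != as.integer(b)) ||
      any(a < 1) || any(b < 1)) {
    stop("section scores must be integers >= 1")
  }
  TABLE_C[cbind(pmin(a, 8L), pmin(b, 7L))]
}
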