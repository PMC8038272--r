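# Neutral-pose calibration and segment angle extraction.
#
# The chain mirrors the platform's processing: each sensor's orientation is
# re-expressed relative to its neutral (upright standing) orientation,
#     R_new = R0^-1 R,
# then the spine rotation is the thoracic sensor relative to the sacral one
# and the neck rotation the head sensor relative to the thoracic one,
#     R_spine = R_IMU1^-1 R_IMU2,   R_neck = R_IMU2^-1 R_IMU3,
# and each relative rotation is decomposed into flexion, lateral bending and
# twist with the intrinsic x-y-z sequence of euler_compose().

#' Estimate the neutral calibration pose
#'
#' Averages each sensor's orientation over a short window in which the
#' subject stands upright in the anatomical position (5 s in the reference
#' protocol). The average is the chordal mean: the element-wise matrix mean
#' projected onto the rotation group, which is unique and accurate for the
#' tightly clustered samples of a static pose.
#'
#' @param triplet a [stream_triplet()].
#' @param t_start window start in seconds (default 0).
#' @param duration window length in seconds (default 5).
#' @param max_gap gap tolerance used to verify the window is contiguous;
#'   default `3 / fs`.
#' @return An object of class `calibration_pose`: list with `R0` (named list
#'   of 3x3 rotations per sensor), `t_start`, `duration`.
#' @export
calibrate <- function(triplet, t_start = 0, duration = 5, max_gap = NULL) {
  stopifnot(inherits(triplet, "stream_triplet"))
  if (duration <= 0) stop("calibration duration must be positive")
  R0 <- lapply(triplet, function(s) {
    if (is.null(max_gap)) max_gap <- 3 / s$fs
    sel <- which(s$t >= t_start & s$t < t_start + duration)
    if (length(sel) == 0) {
      stop("calibration window [", t_start, ", ", t_start + duration,
           ") contains no samples of ", s$sensor_id)
    }
    if (t_start < s$t[1] - max_gap || t_start + duration > s$t[length(s$t)] + 1 / s$fs) {
      stop("calibration window extends outside the data of ", s$sensor_id)
    }
    if (length(sel) > 1 && any(diff(s$t[sel]) > max_gap)) {
      stop("calibration window spans a data gap in ", s$sensor_id)
    }
    chordal_mean_rotation(s$R[, , sel, drop = FALSE])
  })
  names(R0) <- vapply(triplet, `[[`, character(1), "sensor_id")
  structure(list(R0 = R0, t_start = t_start, duration = duration),
            class = "calibration_pose")
}

#' Re-express a stream relative to its neutral pose
#'
#' Applies the calibration transform \eqn{R_{new} = R_0^{-1} R} sample by
#' sample, so that the stream equals the identity at the neutral posture.
#'
#' @param stream an [orientation_stream()].
#' @param pose a `calibration_pose` from [calibrate()] containing this
#'   stream's sensor.
#' @return A calibrated [orientation_stream()].
#' @export
apply_calibration <- function(stream, pose) {
  stopifnot(inherits(stream, "orientation_stream"),
            inherits(pose, "calibration_pose"))
  R0 <- pose$R0[[stream$sensor_id]]
  if (is.null(R0)) stop("no calibration for sensor ", stream$sensor_id)
  Rnew <- rot_array_mult(t(R0), stream$R)
  orientation_stream(stream$sensor_id, stream$t, Rnew, fs = stream$fs,
                     validate = FALSE)
}

#' Relative rotation of a child sensor with respect to its parent
#'
#' Computes \eqn{R_{rel} = R_{parent}^{-1} R_{child}} on the streams' exact
#' common timestamps. The spine uses (IMU1, IMU2) and the neck (IMU2, IMU3).
#' The result is invariant to any rigid re-orientation of the global frame
#' applied to both streams.
#'
#' @param parent,child [orientation_stream()]s on a shared clock.
#' @param segment `"spine"` or `"neck"`.
#' @return A list of class `segment_rotation_series`: `segment`, `t`,
#'   `R_rel` (3x3xN), `fs`.
#' @export
segment_rotation <- function(parent, child, segment = c("spine", "neck")) {
  segment <- match.arg(segment)
  stopifnot(inherits(parent, "orientation_stream"),
            inherits(child, "orientation_stream"))
  ip <- match(child$t, parent$t)
  keep <- which(!is.na(ip))
  if (length(keep) == 0) stop("streams share no timestamps: empty overlap")
  Rp <- parent$R[, , ip[keep], drop = FALSE]
  Rc <- child$R[, , keep, drop = FALSE]
  structure(list(segment = segment, t = child$t[keep],
                 R_rel = rot_array_crossprod(Rp, Rc), fs = parent$fs),
            class = "segment_rotation_series")
}

#' Full angle-extraction pipeline
#'
#' Calibrates all three streams, forms the spine (sacral to thoracic) and
#' neck (thoracic to head) relative rotations on the common timestamps, and
#' decomposes each into flexion-extension, lateral bending and twist.
#'
#' @param triplet a [stream_triplet()].
#' @param pose a `calibration_pose` from [calibrate()].
#' @return A list with elements `spine` and `neck`, each a data.frame in the
#'   angle-series schema `t,segment,flexion_deg,bending_deg,twist_deg`.
#' @export
angle_pipeline <- function(triplet, pose) {
  stopifnot(inherits(triplet, "stream_triplet"))
  cal <- lapply(triplet, apply_calibration, pose = pose)
  out <- list(
    spine = segment_rotation(cal$imu1, cal$imu2, "spine"),
    neck = segment_rotation(cal$imu2, cal$imu3, "neck")
  )
  lapply(out, function(sr) {
    ang <- euler_decompose(sr$R_rel)
    data.frame(t = sr$t, segment = sr$segment,
               flexion_deg = ang$flexion_deg,
               bending_deg = ang$bending_deg,
               twist_deg = ang$twist_deg)
  })
}
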