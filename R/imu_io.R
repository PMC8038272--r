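# Reading, validating and writing orientation streams and derived series.
#
# Interchange is plain CSV, long format, one row per sample per sensor:
#   matrix dialect:     t,sensor_id,r11,r12,r13,r21,r22,r23,r31,r32,r33
#   quaternion dialect: t,sensor_id,qw,qx,qy,qz        (unit, scalar-first)
# sensor_id is one of IMU1 (sacral), IMU2 (thoracic), IMU3 (head).
# Matrices are serialized row-major (r11..r13 is the first row).

SENSOR_IDS <- c("IMU1", "IMU2", "IMU3")
MATRIX_COLS <- c("t", "sensor_id",
                 "r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32", "r33")
QUAT_COLS <- c("t", "sensor_id", "qw", "qx", "qy", "qz")
ANGLE_COLS <- c("t", "segment", "flexion_deg", "bending_deg", "twist_deg")
SCORE_COLS <- c("window_start_s", "window_end_s",
                "neck_flexo", "neck_adj", "neck_score",
                "spine_flexo", "spine_adj", "spine_score",
                "legs", "overall_score")

# Validation tolerances for incoming rotation matrices: accept below
# ORTH_TOL_ACCEPT, repair by projection below ORTH_TOL_REPAIR, reject beyond
# (serialization rounding is tolerated, corruption is not).
ORTH_TOL_ACCEPT <- 1e-6
ORTH_TOL_REPAIR <- 1e-2

#' Construct an orientation stream
#'
#' An orientation stream is one sensor's time series of 3x3 rotation
#' matrices (sensor-to-global). Timestamps must be strictly increasing and
#' nominally uniform at `fs`; holes larger than the nominal interval are
#' permitted and later segmented out by [detect_gaps()].
#'
#' @param sensor_id one of `"IMU1"` (sacral), `"IMU2"` (thoracic),
#'   `"IMU3"` (head).
#' @param t numeric vector of non-negative times in seconds, strictly
#'   increasing.
#' @param R 3x3xN array of rotation matrices, N = `length(t)`.
#' @param fs sampling frequency in Hz; if `NULL`, inferred as the reciprocal
#'   of the median inter-sample interval.
#' @param validate check (and if mildly violated, repair) the rotation
#'   invariants of every sample.
#' @return An object of class `orientation_stream`.
#' @export
orientation_stream <- function(sensor_id, t, R, fs = NULL, validate = TRUE) {
  sensor_id <- match.arg(sensor_id, SENSOR_IDS)
  if (length(t) == 0) stop("empty stream for ", sensor_id)
  if (!all(is.finite(t)) || any(t < 0)) stop("timestamps must be finite and non-negative")
  if (is.matrix(R)) R <- array(R, c(3, 3, 1))
  if (length(dim(R)) != 3 || dim(R)[3] != length(t)) {
    stop("R must be a 3x3xN array matching length(t)")
  }
  if (!all(is.finite(R))) stop("non-finite values in orientation data for ", sensor_id)
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing for ", sensor_id)
  }
  if (is.null(fs)) {
    fs <- if (length(t) > 1) 1 / stats::median(diff(t)) else 75
  }
  if (validate) {
    dets <- rot_array_det(R)
    if (any(dets <= 0)) {
      stop("sample(s) with non-positive determinant in ", sensor_id,
           ": improper rotation (reflection) or corrupted data")
    }
    defect <- orthogonality_defect(R)
    bad <- defect > ORTH_TOL_REPAIR
    if (any(bad)) {
      stop(sum(bad), " sample(s) in ", sensor_id,
           " exceed the orthogonality repair tolerance (", ORTH_TOL_REPAIR,
           "): corrupted data")
    }
    fix <- defect > ORTH_TOL_ACCEPT
    if (any(fix)) {
      for (k in which(fix)) R[, , k] <- orthonormalize(R[, , k])
    }
    # nominal uniformity: intervals within 10% of 1/fs, except at gaps
    if (length(t) > 1) {
      dt <- diff(t)
      nominal <- 1 / fs
      irregular <- (dt < 0.9 * nominal | dt > 1.1 * nominal) & dt < 3 * nominal
      if (any(irregular)) {
        stop(sum(irregular), " inter-sample interval(s) in ", sensor_id,
             " deviate >10% from 1/fs without qualifying as gaps")
      }
    }
  }
  structure(list(sensor_id = sensor_id, fs = fs, t = t, R = R),
            class = "orientation_stream")
}

#' @export
print.orientation_stream <- function(x, ...) {
  cat(sprintf("<orientation_stream %s: %d samples, %.6g-%.6g s, fs = %.4g Hz>\n",
              x$sensor_id, length(x$t), min(x$t), max(x$t), x$fs))
  invisible(x)
}

#' Bundle the three sensor streams
#'
#' @param imu1,imu2,imu3 `orientation_stream`s for the sacral, thoracic and
#'   head sensors. All must share the sampling frequency.
#' @return An object of class `stream_triplet` with elements `imu1`, `imu2`,
#'   `imu3`.
#' @export
stream_triplet <- function(imu1, imu2, imu3) {
  streams <- list(imu1 = imu1, imu2 = imu2, imu3 = imu3)
  ok <- vapply(streams, inherits, logical(1), "orientation_stream")
  if (!all(ok)) stop("all elements must be orientation_streams")
  ids <- vapply(streams, `[[`, character(1), "sensor_id")
  if (!identical(unname(ids), SENSOR_IDS)) {
    stop("triplet must hold IMU1, IMU2, IMU3 in order; got: ",
         paste(ids, collapse = ", "))
  }
  fss <- vapply(streams, `[[`, numeric(1), "fs")
  if (max(fss) - min(fss) > 0.01 * max(fss)) {
    stop("sensors disagree on sampling frequency: ", paste(signif(fss, 6), collapse = ", "))
  }
  structure(streams, class = "stream_triplet")
}

#' Read a three-sensor orientation CSV
#'
#' Reads the long-format CSV interchange file (see the package README for the
#' schema), validates every sample against the rotation-matrix invariants
#' (orthonormality and determinant +1, with automatic projection repair of
#' small serialization rounding), and returns the three per-sensor streams.
#'
#' @param path CSV file path.
#' @param dialect `"matrix"` (columns r11..r33, row-major) or `"quaternion"`
#'   (columns qw,qx,qy,qz, scalar-first unit quaternions).
#' @param fs sampling frequency override; inferred from timestamps when `NULL`.
#' @return A [stream_triplet()].
#' @export
read_orientation_csv <- function(path, dialect = c("matrix", "quaternion"), fs = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- if (dialect == "matrix") MATRIX_COLS else QUAT_COLS
  if (!identical(names(df), want)) {
    stop("column mismatch for dialect '", dialect, "': expected ",
         paste(want, collapse = ","), " but found ",
         paste(names(df), collapse = ","))
  }
  num_cols <- setdiff(want, "sensor_id")
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]]) || any(!is.finite(df[[cl]]))) {
      stop("non-finite or non-numeric values in column '", cl, "'")
    }
  }
  unknown <- setdiff(unique(df$sensor_id), SENSOR_IDS)
  if (length(unknown)) stop("unknown sensor_id: ", paste(unknown, collapse = ", "))
  missing <- setdiff(SENSOR_IDS, unique(df$sensor_id))
  if (length(missing)) stop("missing sensor(s): ", paste(missing, collapse = ", "))

  streams <- lapply(SENSOR_IDS, function(id) {
    sub <- df[df$sensor_id == id, , drop = FALSE]
    if (dialect == "matrix") {
      R <- array(0, c(3, 3, nrow(sub)))
      R[1, 1, ] <- sub$r11; R[1, 2, ] <- sub$r12; R[1, 3, ] <- sub$r13
      R[2, 1, ] <- sub$r21; R[2, 2, ] <- sub$r22; R[2, 3, ] <- sub$r23
      R[3, 1, ] <- sub$r31; R[3, 2, ] <- sub$r32; R[3, 3, ] <- sub$r33
    } else {
      q <- as.matrix(sub[, c("qw", "qx", "qy", "qz")])
      nrm <- sqrt(rowSums(q^2))
      if (any(abs(nrm - 1) > 1e-3)) {
        stop("non-unit quaternion(s) in ", id, " (norm off by > 1e-3)")
      }
      R <- quat_to_rotmat(q)
    }
    orientation_stream(id, sub$t, R, fs = fs)
  })
  stream_triplet(streams[[1]], streams[[2]], streams[[3]])
}

#' Write a three-sensor orientation CSV
#'
#' Inverse of [read_orientation_csv()] for the matrix dialect (the canonical
#' interchange dialect). Rows are emitted sensor by sensor in time order, so
#' identical triplets serialize byte-identically.
#'
#' @param triplet a [stream_triplet()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_orientation_csv <- function(triplet, path) {
  stopifnot(inherits(triplet, "stream_triplet"))
  rows <- lapply(triplet, function(s) {
    data.frame(t = s$t, sensor_id = s$sensor_id,
               r11 = s$R[1, 1, ], r12 = s$R[1, 2, ], r13 = s$R[1, 3, ],
               r21 = s$R[2, 1, ], r22 = s$R[2, 2, ], r23 = s$R[2, 3, ],
               r31 = s$R[3, 1, ], r32 = s$R[3, 2, ], r33 = s$R[3, 3, ])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segment a stream into contiguous blocks
#'
#' Splits a stream at holes larger than `max_gap` so that downstream
#' windowed analysis only runs on stretches where the data flow was stable.
#' The returned blocks partition the samples: every sample belongs to
#' exactly one block.
#'
#' @param stream an [orientation_stream()], or any object with numeric `t`
#'   and `fs` fields.
#' @param max_gap largest tolerated inter-sample interval, in seconds.
#'   Default `3 / fs` (two missing samples).
#' @return A data.frame with one row per block: `start`, `end` (1-based
#'   inclusive sample indices) and `duration` in seconds.
#' @export
detect_gaps <- function(stream, max_gap = NULL) {
  t <- if (is.list(stream)) stream$t else stream
  if (length(t) == 0) stop("empty stream")
  if (is.null(max_gap)) {
    fs <- if (is.list(stream) && !is.null(stream$fs)) stream$fs else 1 / stats::median(diff(t))
    max_gap <- 3 / fs
  }
  if (max_gap <= 0) stop("max_gap must be positive")
  breaks <- which(diff(t) > max_gap)
  start <- c(1L, breaks + 1L)
  end <- c(breaks, length(t))
  data.frame(start = start, end = end, duration = t[end] - t[start])
}

#' Write an angle or score series to CSV
#'
#' Serializes a segment angle series (columns
#' `t,segment,flexion_deg,bending_deg,twist_deg`) or a per-window risk index
#' series (see [score_pipeline()]) so that reading the file back reproduces
#' every value to 1e-9. Non-finite values signal an upstream bug and are
#' rejected.
#'
#' @param series a data.frame in one of the two schemas.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (!is.data.frame(series)) stop("series must be a data.frame")
  if (nrow(series) == 0) stop("refusing to write an empty series")
  if (!identical(names(series), ANGLE_COLS) &&
      !identical(names(series), SCORE_COLS)) {
    stop("unrecognized series schema: ", paste(names(series), collapse = ","))
  }
  num <- series[vapply(series, is.numeric, logical(1))]
  if (any(!vapply(num, function(x) all(is.finite(x)), logical(1)))) {
    stop("non-finite values in series: refusing to serialize")
  }
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a series written by [write_series_csv()]
#'
#' @param path CSV path.
#' @return A data.frame in the angle-series or score-series schema.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), ANGLE_COLS) && !identical(names(df), SCORE_COLS)) {
    stop("unrecognized series schema in ", path)
  }
  df
}
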