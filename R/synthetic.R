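# Forward simulation of three-sensor recordings from declarative posture
# scenarios, with ground-truth angles and reference window scores. The
# forward model inverts the kinematic chain: IMU1 holds the (arbitrary)
# global base orientation, IMU2 = IMU1 * R_spine(angles) and
# IMU3 = IMU2 * R_neck(angles), with angle-to-rotation composition using
# the package's declared intrinsic flexion -> bending -> twist sequence.

SEGMENTS <- c("spine", "neck")
CHANNELS <- c("flexion", "bending", "twist")

#' Declare a synthetic posture scenario
#'
#' A scenario is a piecewise-static posture programme: per segment and
#' channel a target angle (or a data.frame of `time,value` plateaus) held
#' from the end of the calibration window onwards, reached through linear
#' ramps; optional short rectangular spikes; isotropic per-sample
#' orientation noise; and an arbitrary global base orientation. The first
#' `calibration_duration` seconds are always exactly neutral (all angles
#' zero) so the standard calibration protocol applies.
#'
#' @param duration total duration in seconds (must exceed the calibration
#'   window).
#' @param fs sampling frequency, Hz.
#' @param spine,neck named lists with entries `flexion`, `bending`, `twist`;
#'   each entry is a single target angle in degrees or a data.frame with
#'   columns `time` (seconds, ordered, >= calibration end) and `value`
#'   (degrees). Missing entries default to 0.
#' @param noise_rms per-sample orientation noise in degrees RMS (the
#'   rotation angle of an isotropic random perturbation applied to each
#'   sensor), emulating the dynamic accuracy of commercial IMUs (~2 deg
#'   RMS).
#' @param spikes list of spikes, each a list with `t` (onset, s), `segment`,
#'   `channel`, and optional `duration` (default 3 s) and `amplitude`
#'   (default 30 degrees): short rectangular posture excursions.
#' @param global_base 3x3 rotation applied to all sensors (room/bed frame).
#' @param calibration_duration length of the leading neutral segment,
#'   seconds.
#' @param ramp linear ramp length between posture plateaus, seconds.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(duration,
                          fs = 75,
                          spine = list(),
                          neck = list(),
                          noise_rms = 2,
                          spikes = list(),
                          global_base = diag(3),
                          calibration_duration = 5,
                          ramp = 2,
                          seed = 42) {
  stopifnot(duration > calibration_duration, fs > 0, noise_rms >= 0, ramp >= 0)
  norm_seg <- function(seg, name) {
    bad <- setdiff(names(seg), CHANNELS)
    if (length(bad)) stop("unknown channel(s) in ", name, ": ", paste(bad, collapse = ", "))
    for (ch in CHANNELS) {
      v <- seg[[ch]]
      if (is.null(v)) v <- 0
      if (is.numeric(v) && length(v) == 1) {
        v <- data.frame(time = calibration_duration, value = v)
      }
      if (!is.data.frame(v) || !all(c("time", "value") %in% names(v))) {
        stop(name, "$", ch, " must be a number or a data.frame(time, value)")
      }
      if (is.unsorted(v$time, strictly = TRUE)) stop("transition times must be strictly increasing")
      if (any(v$time < calibration_duration)) {
        stop("transitions must not start before the calibration window ends")
      }
      seg[[ch]] <- v
    }
    seg[CHANNELS]
  }
  for (sp in spikes) {
    if (is.null(sp$t) || is.null(sp$segment) || is.null(sp$channel)) {
      stop("each spike needs t, segment and channel")
    }
    d <- if (is.null(sp$duration)) 3 else sp$duration
    if (sp$t < 0 || sp$t + d > duration) stop("spike extends outside the scenario duration")
    if (!sp$segment %in% SEGMENTS || !sp$channel %in% CHANNELS) {
      stop("spike segment/channel unknown")
    }
  }
  structure(list(duration = duration, fs = fs,
                 spine = norm_seg(spine, "spine"), neck = norm_seg(neck, "neck"),
                 noise_rms = noise_rms, spikes = spikes,
                 global_base = global_base,
                 calibration_duration = calibration_duration,
                 ramp = ramp, seed = as.integer(seed)),
            class = "scenario_spec")
}

# Piecewise-constant plateaus with linear ramps, zero during calibration.
angle_track <- function(t, steps, calib_end, ramp) {
  kx <- c(0, calib_end)
  ky <- c(0, 0)
  prev <- 0
  for (i in seq_len(nrow(steps))) {
    t0 <- steps$time[i]
    kx <- c(kx, t0, t0 + ramp)
    ky <- c(ky, prev, steps$value[i])
    prev <- steps$value[i]
  }
  # knots must be non-decreasing; overlapping ramps are a spec error
  if (is.unsorted(kx)) stop("posture transitions overlap (ramp too long)")
  stats::approx(kx, ky, xout = t, rule = 2, ties = "ordered")$y
}

#' Scenario presets
#'
#' Ready-made scenarios mirroring the postures the platform is meant to
#' expose:
#' \describe{
#'   \item{neutral}{upright standing throughout; noiseless. Every window
#'     scores 1/1 and overall 1.}
#'   \item{spiky}{neutral baseline plus 3-s, 30-degree rectangular spikes on
#'     several channels; noiseless. The smoothing filter absorbs the spikes,
#'     so end-to-end scores equal the neutral preset's.}
#'   \item{laparoscopy_like}{sustained neck extension (-15 deg) with spine
#'     flexion (30 deg) and lateral bending (15 deg), 2 deg RMS noise —
#'     the monitor-gazing laparoscopic posture (neck flexo 4, spine 3+bend,
#'     overall 7).}
#'   \item{laparotomy_like}{sustained forward flexion of neck (25 deg) and
#'     spine (25 deg) with a twisted neck (15 deg), 2 deg RMS noise — the
#'     look-down open-surgery posture.}
#' }
#' The neutral and spiky presets are noiseless because they hold angles
#' exactly on the staircase boundaries (0 degrees), where any noise makes
#' the instantaneous level flip by construction; the noisy presets keep all
#' angles at least 5 degrees away from every threshold.
#'
#' @param name preset name.
#' @param duration scenario length in seconds (default 605: a 5-s
#'   calibration window plus two full 5-min windows).
#' @param seed RNG seed.
#' @return A [scenario_spec()].
#' @export
scenario_preset <- function(name = c("neutral", "spiky", "laparoscopy_like",
                                     "laparotomy_like"),
                            duration = 605, seed = 42) {
  name <- match.arg(name)
  switch(name,
    neutral = scenario_spec(duration, noise_rms = 0, seed = seed),
    spiky = scenario_spec(duration, noise_rms = 0, seed = seed, spikes = list(
      list(t = 60, segment = "spine", channel = "flexion"),
      list(t = 150, segment = "neck", channel = "flexion"),
      list(t = 250, segment = "spine", channel = "twist"),
      list(t = 400, segment = "neck", channel = "bending", amplitude = -30),
      list(t = 520, segment = "spine", channel = "flexion"))),
    laparoscopy_like = scenario_spec(duration, seed = seed,
      neck = list(flexion = -15),
      spine = list(flexion = 30, bending = 15)),
    laparotomy_like = scenario_spec(duration, seed = seed,
      neck = list(flexion = 25, twist = 15),
      spine = list(flexion = 25)))
}

#' Synthesize a three-sensor recording
#'
#' Forward-simulates the orientation streams of the sacral, thoracic and
#' head sensors for a scenario, and returns them together with the
#' noiseless ground-truth angle series and the expected per-window scores
#' computed by the naive reference scorer ([reference_score_windows()]),
#' which is kept deliberately independent of the production pipeline.
#'
#' @param spec a [scenario_spec()].
#' @param ground_truth also compute ground-truth window scores (set to
#'   `FALSE` to skip the reference scorer).
#' @return A list: `triplet` (a [stream_triplet()]), `truth` (list with
#'   `spine`, `neck` angle-series data.frames and, when requested,
#'   `windows`, a `risk_index` data.frame from the reference scorer).
#' @export
synthesize <- function(spec, ground_truth = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- as.integer(round(spec$duration * spec$fs))
  t <- (seq_len(n) - 1) / spec$fs
  calib_end <- spec$calibration_duration

  ang <- list()
  for (seg in SEGMENTS) {
    ang[[seg]] <- lapply(CHANNELS, function(ch) {
      angle_track(t, spec[[seg]][[ch]], calib_end, spec$ramp)
    })
    names(ang[[seg]]) <- CHANNELS
  }
  for (sp in spec$spikes) {
    d <- if (is.null(sp$duration)) 3 else sp$duration
    a <- if (is.null(sp$amplitude)) 30 else sp$amplitude
    pulse <- as.numeric(t >= sp$t & t < sp$t + d) * a
    ang[[sp$segment]][[sp$channel]] <- ang[[sp$segment]][[sp$channel]] + pulse
  }

  truth <- list(
    spine = data.frame(t = t, segment = "spine",
                       flexion_deg = ang$spine$flexion,
                       bending_deg = ang$spine$bending,
                       twist_deg = ang$spine$twist),
    neck = data.frame(t = t, segment = "neck",
                      flexion_deg = ang$neck$flexion,
                      bending_deg = ang$neck$bending,
                      twist_deg = ang$neck$twist))

  Rspine <- euler_compose(ang$spine$flexion, ang$spine$bending, ang$spine$twist)
  Rneck <- euler_compose(ang$neck$flexion, ang$neck$bending, ang$neck$twist)
  R1 <- array(spec$global_base, c(3, 3, n))
  R2 <- rot_array_mult(spec$global_base, Rspine)
  R3 <- rot_array_mult(R2, Rneck)

  if (spec$noise_rms > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(spec$seed)
    perturb <- function(R) {
      axis <- matrix(stats::rnorm(3 * n), nrow = 3)
      angle <- stats::rnorm(n, sd = spec$noise_rms * DEG2RAD)
      rot_array_mult(R, axis_angle_rotmat(axis, angle))
    }
    R1 <- perturb(R1); R2 <- perturb(R2); R3 <- perturb(R3)
  }

  triplet <- stream_triplet(
    orientation_stream("IMU1", t, R1, fs = spec$fs, validate = FALSE),
    orientation_stream("IMU2", t, R2, fs = spec$fs, validate = FALSE),
    orientation_stream("IMU3", t, R3, fs = spec$fs, validate = FALSE))

  if (ground_truth) {
    cfg <- scoring_config(fs = spec$fs)
    truth$windows <- reference_score_windows(truth$spine, truth$neck, cfg)
  }
  list(triplet = triplet, truth = truth)
}
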