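# Shared test helpers and lazily built fixtures.

# Random rotations from random unit quaternions (independent of the
# package's Euler machinery).
rand_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  quat_to_rotmat(q)
}

rand_rotation <- function() rand_rotations(1)[, , 1]

# Constant angle series for one segment.
const_series <- function(segment, flexion = 0, bending = 0, twist = 0,
                         duration = 300, fs = 75) {
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  data.frame(t = t, segment = segment,
             flexion_deg = rep(flexion, n), bending_deg = rep(bending, n),
             twist_deg = rep(twist, n))
}

# Build a synchronized identity-orientation triplet (optionally a constant
# rotation per sensor).
const_triplet <- function(n = 10, fs = 75, R1 = diag(3), R2 = diag(3),
                          R3 = diag(3)) {
  t <- (seq_len(n) - 1) / fs
  stream_triplet(
    orientation_stream("IMU1", t, array(R1, c(3, 3, n)), fs = fs),
    orientation_stream("IMU2", t, array(R2, c(3, 3, n)), fs = fs),
    orientation_stream("IMU3", t, array(R3, c(3, 3, n)), fs = fs))
}

frob <- function(M) sqrt(sum(M^2))

# Down-scaled scoring config used by randomized window-level tests: same
# structure as the reference defaults, 30x fewer samples per window.
cfg_small <- function() {
  scoring_config(fs = 10, filter_len = 5, window_len = 30, dwell_threshold = 6)
}

# Memoised full-scale simulations shared across test files.
.fixture_env <- new.env()

fixture_sim <- function(preset, duration = 605, seed = 7) {
  key <- paste(preset, duration, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- synthesize(
      scenario_preset(preset, duration = duration, seed = seed))
  }
  .fixture_env[[key]]
}
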