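---
title: "Posture monitoring and the windowed ergonomic risk index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posture monitoring and the windowed ergonomic risk index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surgeons hold harmful static postures — a forward-flexed trunk, an extended
neck fixed on a monitor — for hours at a time, and are among the worker
groups most exposed to musculoskeletal disorders. Observational ergonomic
assessments such as RULA (Rapid Upper Limb Assessment) score such postures
from angle categories on a worksheet, but they produce a single score per
observation and require an observer. `ergorula` implements a direct,
sensor-based variant for the head-and-trunk region: three inertial
measurement units (IMUs) — sacral, thoracic, and head-mounted — stream 3D
orientations at 75 Hz, from which the package computes spine and neck joint
angles over time and a RULA-derived risk index per 5-minute window.

## Kinematic model

Each sensor reports a rotation matrix $R_{GX}$ mapping its frame into the
global frame. A short neutral acquisition (5 s of upright anatomical
standing) defines a reference orientation $R_{GX_0}$ per sensor, estimated
as the chordal mean of the windowed samples (the element-wise matrix mean
projected back onto the rotation group by SVD). Calibrated orientations are

$$R_{GX}^{new} = R_{GX_0}^{-1} R_{GX},$$

so the neutral posture is the identity. The two monitored joints are
modelled as single segments:

$$R_{spine} = R_{IMU1}^{-1} R_{IMU2}, \qquad R_{neck} = R_{IMU2}^{-1} R_{IMU3}.$$

Because both sides of each product live in the same global frame, any rigid
re-orientation of the room, bed, or magnetic north cancels exactly — a
property the test suite checks to below $10^{-9}$ degrees on the extracted
angles.

### Angle decomposition

The vendor sheets and the worksheet categories speak of flexion-extension,
lateral bending, and axial twist but fix no Euler sequence; this is a
genuinely open design point, since the three conventions differ at second
order in the angles. The package declares an intrinsic x–y–z sequence in
the calibrated anatomical frame,

$$R = R_x(\text{flexion})\; R_y(\text{bending})\; R_z(\text{twist}),$$

with x the medio-lateral, y the antero-posterior and z the longitudinal
axis. Flexion is deliberately first: flexo-extension drives the staircase
quantizer with the finest thresholds, and the first angle of an intrinsic
sequence is the one least distorted by the other two. Signs: forward
flexion, right bend, and right twist are positive; the sign of neck flexion
matters because neck *extension* is its own (highest) scoring category.
Within 0.5° of the $\pm 90°$ bending singularity the flexion/twist split is
ill-conditioned; samples there are flagged, returned with the conventional
twist = 0 resolution, and are unreachable for human spine/neck postures.

## The risk-index algorithm

Per segment and channel the pipeline is:

1. **Smoothing.** A centered moving average of `filter_len = 875` samples
   (11.67 s at 75 Hz). The reference description gives both "approximately
   10 s" and a 0.038 Hz cut-off; these are inconsistent (10 s gives
   0.044 Hz), and the stated cut-off is taken as normative: a centered
   moving average has its −3 dB point at $\approx 0.443 f_s / L$, and
   $L = 875$ yields 0.038 Hz (`ma_cutoff_hz()` locates it numerically).
   Edges divide by the actual window coverage, so the DC gain is exactly 1
   everywhere. Linearity gives the useful calibration fact that a
   rectangular excursion of $m$ samples attenuates to $m/L$ of its
   amplitude: a 3-s, 30° spike surfaces as 7.7°, below both the 10°
   twist/bend band and the second neck threshold.
2. **Windowing.** Each contiguous block (no inter-sample hole above
   `3/fs`) is divided into consecutive, non-overlapping 300-s windows;
   "division into 5-min windows" is the operational reading, and one score
   per 5-min block is what the reference timelines show. A trailing
   remainder is discarded with a warning: the dwell rule below is only
   guaranteed well-defined on full windows.
3. **Quantization.** Flexo-extension maps through a staircase:
   spine $(-\infty,0] \to 1$, $(0,20] \to 2$, $(20,60] \to 3$,
   $(60,\infty) \to 4$; neck $[0,10] \to 1$, $(10,20] \to 2$,
   $(20,\infty) \to 3$ and any extension ($< 0$) $\to 4$ with no dead
   band. Intervals are half-open with exact threshold hits taking the
   lower score — a convention that must be fixed for exact tests, and that
   the smoothed signal makes measure-zero in practice. Spine extension
   takes the lowest score: the spine staircase leaves it unaddressed, and
   scoring it 1 is the conservative, explicit choice (configurable).
4. **Dwell-time selection.** The window's flexo score is the *highest*
   level whose accumulated time strictly exceeds `dwell_threshold = 60` s.
   Four levels over 300 s guarantee one level with $\geq 75$ s by
   pigeonhole, so the rule is total on full windows (and only there: below
   240 s the argument fails, which is why partial windows are dropped).
5. **Adjustments.** Twist and lateral bending each add 1 when the angle
   stays outside $[-10°, +10°]$ for more than the dwell threshold —
   magnitude beyond the band does not matter. The band is three times the
   sensors' ~3° angle-reconstruction error, giving a robust indication of
   a genuinely twisted or bent posture.
6. **Combination.** Segment score = flexo + twist + bend $\in [1, 6]$;
   neck and spine scores enter the published section-B look-up table with
   the legs score (constant 1 for a standing surgeon; 2 configurable) to
   give the overall head-and-trunk score. The grand-score table is also
   included (`grand_score()`) for context — e.g. a section-B score of 6
   forces a final RULA score of at least 5 — with muscle-use and force
   additions accepted as explicit config inputs (default 0), never
   estimated from sensor data.

## The synthetic scenario generator

Real operating-room recordings are not redistributable, so the generator is
a first-class module: it inverts the kinematic chain
($R_{IMU1} = G$, $R_{IMU2} = R_{IMU1} R_{spine}$,
$R_{IMU3} = R_{IMU2} R_{neck}$) over piecewise-static posture programmes
with 2-s linear ramps, a leading 5-s exactly-neutral calibration segment,
optional 3-s/30° rectangular spikes, and isotropic per-sample orientation
noise whose rotation angle is Gaussian with the stated 2° RMS — matching
the one published accuracy figure without inventing spectral structure.
Expected window scores ship with each scenario, computed by a deliberately
naive per-sample reference scorer (`reference_score_windows()`) that shares
no code with the production scorer.

What the generator does *not* emulate: sensor drift, magnetic disturbance,
soft-tissue and skin-slide artifacts, and the broadband spectrum of real
human movement (plateaus idealize the "harmful static posture" regime).
Passing tests therefore demonstrate algorithmic correctness of the
pipeline, not field robustness of the hardware.

Preset notes. `laparoscopy_like` (sustained neck extension −15°, spine
flexion 30° with 15° lateral bend) and `laparotomy_like` (forward flexion
of both segments, twisted neck) keep every sustained angle at least 5° from
every threshold, so with 2° RMS noise the filtered residual
($\approx 2°/\sqrt{875} \approx 0.07°$) never flips a score and window
scores match ground truth exactly. `neutral` and `spiky` sit *on* the 0°
neck boundary by construction; since extension has no dead band, any noise
makes the instantaneous neck level flip sign randomly, which is a property
of the scoring rule, not a bug. These two presets are therefore noiseless,
which also keeps the spiky-equals-neutral comparison sharp: the spikes are
the only difference between the two recordings.

## Numerical choices

- Incoming matrices are accepted when $\|R^\top R - I\|_F \le 10^{-6}$,
  repaired by SVD projection up to $10^{-2}$ (serialization rounding), and
  rejected beyond (corruption); determinant $\le 0$ is always rejected.
- The chordal mean is used for calibration averaging: unique and accurate
  for the tightly clustered samples of a static 5-s pose.
- The moving average is computed by cumulative sums ($O(n)$); the naive
  $O(nL)$ loop lives only in the reference scorer.
- Streams are joined on exact timestamps; resampling is intentionally not
  performed because the acquisition hub synchronizes the sensors. The
  reader enforces nominal uniformity (±10% of $1/f_s$) except at declared
  gaps (> $3/f_s$), which segment the analysis into contiguous blocks.
- The filtered neutral residual is validated on its RMS (against
  $3\sigma/\sqrt{L}$) rather than its maximum: the calibration-mean error
  of 375 samples propagates through two sensors per joint and makes a
  max-statistic exceed that scale with appreciable probability even when
  the filter behaves exactly as designed.

## Problem sizes used in validation

The test-suite runs the full-scale configuration (75 Hz, 875-sample
filter, 300-s windows) on scenarios of 305–605 s — one to two full windows
— and exercises the randomized window-level properties (pigeonhole, oracle
equivalence on 1000 windows, monotonicity) on a structurally identical
configuration scaled to 10 Hz / 30-s windows / 6-s dwell, chosen so the
whole suite validates the same code paths at interactive run times.

## Known limitations

- Only the head-and-trunk (section B) side is sensor-derived; upper-limb
  scores, EMG-based muscle-use terms and dynamic legs scoring are out of
  scope by design.
- A single-segment model per joint: the spine is treated as one rigid
  segment between sacral and thoracic sensors, which underestimates
  multi-segmental curvature.
- Scores are per-window categories; the package reports dwell fractions
  and minutes per score level but does not model score dynamics.
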