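---
title: "Estimating running kinematics and kinetics from three inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating running kinematics and kinetics from three inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imu2grf)
```

## The estimation problem

Biomechanical analysis of running traditionally needs a gait laboratory: an
optical motion-capture system for joint kinematics and an instrumented
treadmill or force plates for ground reaction forces.  `imu2grf`
implements a reduced-sensor alternative: three inertial measurement units
(IMUs) — one on the pelvis and one on each lower leg — feed two
concatenated feed-forward neural networks,

1. **ANN 1** maps the orientation of each lower-leg sensor *relative to the
   pelvis sensor* (two unit quaternions, 8 input columns) to the six
   sagittal lower-body joint angles (hip, knee, ankle flexion/extension,
   both sides, degrees);
2. **ANN 2** maps the *estimated* joint angles together with the vertical
   sensor accelerations (rotated to the global frame, gravity removed) to
   the per-foot vertical ground reaction force (vGRF) in body weights (BW).

The concatenation keeps the two learning problems separate: the kinematic
network can be retrained on data recorded without a force reference, and
the kinetic network can be swapped independently.  Both networks are
two-hidden-layer "function fitting" perceptrons with 250 and 100 tanh
units and a linear output layer.

Two *training schemes* mirror the choice of kinematic reference: an
inertial-like full-body reference (`scheme = "imu"`) or an optical,
Plug-in-Gait-like reference (`scheme = "optical"`).  Two *evaluation
scenarios* probe personalization: single-subject training (train on a
subject's 10 and 14 km/h bouts, evaluate at 12 km/h) and
leave-one-subject-out (LOSO) training across subjects.

## Why a simulator

The laboratory dataset behind the method (8 runners on an instrumented
treadmill, three speeds) is not publicly available.  The package therefore
ships a synthetic treadmill-running generator whose trials have the
statistical and mechanical structure the method relies on, so that the
entire pipeline — preprocessing, feature construction, training, outcome
metrics — can be validated end to end.  The generator is first-class,
tested code, not a fixture.

### Subjects

`make_subject(seed)` draws anthropometry near the emulated cohort (mass
77.7 ± 9.4 kg, height 1.837 ± 0.045 m), a cadence near 82 strides/min, a
peak-vGRF multiple in 2.75–3.2 BW, and a foot-strike type.  Over any block
of 8 consecutive seeds the strike mix is 5 rearfoot / 2 midfoot /
1 forefoot; the real cohort's mix is unreported, so this assumption is
explicit and configurable through the seed mapping.  Per-subject gait
style enters through Fourier-coefficient joint-angle templates, a
left/right asymmetry (amplitude and phase), sensor-mounting misalignment
quaternions (3–4° scale), and a knee-axis obliquity near 10°.

### Joint angles and the kinematic chain

Hip, knee and ankle trajectories are truncated Fourier series over the
stride cycle with a linear-in-speed modulation, so the stance knee-flexion
maximum grows with belt speed (roughly +2 % per km/h) — reproducing the
interpolation/extrapolation structure the speed-generalization experiment
depends on.  The swing knee peak is kept below ~88°, for a reason that is
worth stating openly: the shank-orientation decomposition below has a
second algebraic solution branch that meets the physiologic branch near
90° of knee flexion, and the simulator stays on the identifiable side of
it.

Sensor orientations come from a kinematic chain: the shank segment is the
pelvis composed with a hip rotation about the mediolateral axis, a knee
rotation about an axis tilted ~10° in the transverse plane, and a weak
(0.35 gain) coupling of the ankle angle into shank roll, representing
mounting/soft-tissue compliance.  The distinct axes make **all six target
angles identifiable from the eight quaternion inputs** — on noise-free
data, `extract_chain_angles()` recovers the reference angles to below
1e-6°.  A strictly planar single-axis chain could not provide this: the
relative shank orientation would collapse to one angle per side and ANN 1's
target would not be a function of its input.  Real running data earns the
same identifiability from postural couplings; the simulator makes it exact
and verifiable.

### Forces and accelerations

Each stance is an active half-sine with peak equal to the subject's
(speed-adjusted) peak multiple, plus — for rearfoot strikers — a passive
impact transient peaking 20–30 ms after contact, shaped as a smooth
gamma-like bump that is exactly zero at contact (a raw Gaussian bump
leaves a step at contact that trips the 20 N threshold after zero-phase
filtering).  The stance duty factor is *derived* from the peak multiple
and impact parameters through impulse balance — per stride, each foot must
deliver an impulse of one body weight times half the stride period — so
the time-averaged total force of every trial is body weight within 2 %.
Mid/forefoot strikers get a monotone early rise instead, since their
passive peak is not well defined.

The pelvis vertical trajectory is obtained by double integration of
`total force / mass − g`, with a one-stride moving-average detrend of the
velocity to absorb the random walk injected by per-stance amplitude jitter
(2 % SD).  This makes the pelvis accelerometer physically consistent with
the force target (Newton's second law), which is exactly what makes
ANN 2's task well-posed.  Shank sensors additionally carry an impact
displacement transient whose acceleration peak coincides with the passive
force peak within ±10 ms — the landmark the loading-rate computation
needs.  Accelerometers report specific force (gravity included) in the
sensor frame, computed by second central differences of position;
orientation noise (0.5°), acceleration noise (0.2 m/s²) and force noise
(5 N) are the default measurement-noise scales.

Two kinematic references are emitted per trial: `ref_angles_imu` is the
exact chain ground truth; `ref_angles_optical` adds a smooth
subject-specific offset (cubic polynomial of stride phase, amplitude
capped at 5°) plus 0.3° noise, emulating the systematic model differences
between inertial and marker-based references.

### What the simulator does *not* reproduce

Soft-tissue artifact dynamics, orientation drift, magnetometer
disturbances, treadmill-belt compliance, fatigue effects and 3-D force
components are absent; subject-to-subject variation is parametric rather
than anatomical.  Passing the synthetic validation therefore shows the
pipeline is implemented correctly and that the method works when its
assumptions hold — it does not certify accuracy on any particular real
dataset.

## Preprocessing

Following the processing protocol: trials can be cropped to steady state;
vGRF is low-pass filtered at 20 Hz with a zero-phase 6th-order Butterworth
filter (forward–backward, so 12th-order magnitude); all streams are
resampled to a common 120 Hz grid (integer-ratio streams by sample
picking, the 1000 Hz force by linear interpolation — legitimate because
the 20 Hz low-pass already band-limits it far below the 60 Hz target
Nyquist); stance phases are maximal runs of force ≥ 20 N.

Numerical choices not fixed by the protocol, all configurable:

* **Filter edges**: odd-reflection padding of three filter lengths with
  steady-state initial conditions (a constant signal passes unchanged to
  1e-9).
* **Debounce** (`min_phase = 0.05` s): runs shorter than 50 ms are dropped
  *before* sub-50 ms gaps are merged.  The order matters: the zero-phase
  filter pre-rings ahead of a rearfoot impact and can push a ~15 ms blip
  above 20 N just before true contact; dropping it first keeps the contact
  time unbiased, which the duty-factor recovery test checks (±0.02).
* **Boundary contacts** touching the first or last sample are discarded —
  incomplete stances would bias peak and loading-rate statistics.
* Negative post-filter force values are clipped to zero.
* **Stride convention**: ipsilateral contact to next ipsilateral contact,
  contact at 0 %.

## Training

Both networks are trained full-batch by L-BFGS with Armijo backtracking on
the mean-squared error of min-max-scaled (train range → [−1, 1]) inputs
and targets; the scalers are stored in the model, so inference is
self-contained.  Monotone descent is guaranteed by the line search and
asserted by a property test.  The stopping rule follows the method's
protocol: at most 2000 iterations, stop when the gradient norm falls below
1e-6 or when it fails to decrease for 6 consecutive iterations.  "Did not
decrease" is read literally as a comparison with the previous iteration;
the alternative reading — a validation-failure counter, as in common
neural-network toolboxes — is available via
`train_config(stop_rule = "validation")`.  Weights are initialized
fan-in-scaled uniform from the configuration seed; the whole training path
is bit-deterministic given the seed.

ANN 2 is trained on *reference* angles and evaluated on ANN 1's *estimated*
angles (the deployment path); training on estimated angles is available
via `ann2_training_angles = "estimated"`.  A single ANN 2 with two outputs
serves both feet.  vGRF targets are in BW rather than newtons so that
cross-subject (LOSO) training is not dominated by body-mass differences.

## Outcome measures

Knee flexion/extension agreement is computed per stride, vGRF agreement
per stance (kinetics only exist during contact): per-segment Pearson ρ
(Fisher-averaged across segments, with clipping at ±(1−1e-12) so perfect
fits stay finite) and unnormalized RMSE (mean and SD across segments).
Discrete outcomes per stance: maximal knee flexion, peak vGRF in BW, the
passive-peak time located as the maximum-magnitude shank vertical
acceleration in the first half of the stance, and the loading rate — the
vGRF slope between 20 % and 80 % of the passive-peak time, linearly
interpolated at off-grid times, in BW/s.  Estimates and references are
compared with two-sided paired t-tests (α = 0.05, no multiplicity
correction) and Bland–Altman bias with 1.96 SD limits of agreement.

## Problem sizes of the shipped validation study

`headline_study()` runs the full validation: 8 subjects × 3 speeds × 60 s
(the sample count, not the bout duration, drives learnability, so the
3-minute protocol bouts are shortened), networks at the full 250/100
architecture.  Training matrices are deterministically thinned — at most
7000 rows for single-subject fits and 20 000 for LOSO — and iteration caps
of 80 (single-subject) and 60 (LOSO) are applied: 120 Hz samples within a
stride are highly redundant, and the quasi-Newton fits are near-converged
well before these caps (doubling them changes the headline numbers only in
the third decimal).  With these sizes a full run takes a few minutes on a
single CPU.

## Known limitations

* The angle extractor's closed-form branch disambiguation assumes knee
  flexion stays below ~90°; it is an analysis/validation tool, not part of
  the estimation path.
* The simulator's optical-like reference shares the inertial reference's
  segmentation; real optical/inertial pairs also differ in soft-tissue
  artifact and calibration drift.
* LOSO performance on synthetic subjects is driven by mounting and
  axis-obliquity variation; real cohorts add anatomy and technique
  diversity, so synthetic LOSO numbers are optimistic.
* The loading rate depends strongly on the detected passive-peak time at
  120 Hz resolution (8.3 ms); stances whose 20 %–80 % window collapses
  below one sample period are excluded from the summaries.
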