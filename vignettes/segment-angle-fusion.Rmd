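---
title: "Cooperative Kalman filtering of body-worn inertial sensors: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative Kalman filtering of body-worn inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfuse)
```

# The estimation problem

During walking, the absolute sagittal angle of a body segment — trunk (B),
thigh (T), shank (S) or foot (F) — can be obtained two ways from a
body-worn IMU.  Integrating the sagittal-axis gyroscope gives a smooth
estimate that drifts without bound as soon as the gyro carries a bias.
The accelerometer acts as an inclinometer, but only in quasi-static
instants: when the body accelerates, gravity no longer dominates the
measurement.  `gaitfuse` fuses the two with discrete *error-state* Kalman
filters: the filter never touches the angle directly but estimates the
correction

$$\hat\theta_i(t) = \hat\theta^g_i(t) + \widehat{\Delta\theta}_i(t),$$

where $\hat\theta^g_i$ is the gyro-integrated angle and
$\Delta\theta_i$ the accumulated error.

## State-space model

Per segment the state is $x = (\Delta\theta, \Delta b)$ — angle error
(deg) and gyro bias error (deg/s) — with continuous dynamics

$$\dot x = \begin{bmatrix} 0 & 1 \\ 0 & -1/\tau_g \end{bmatrix} x + w,
\qquad z = [\,1\;\;0\,]\,x + v.$$

The angle error grows at the rate of the bias error; the bias error is a
first-order Gauss–Markov process with correlation time $\tau_g$.
Discretization follows the simple forward rule $F = I + A\,T$,
$G = B\,\sqrt{T}$, $H = C$, so the discrete process noise is $Q\,T$ with
$Q = \mathrm{diag}(\sigma_g^2, \sigma_{bg}^2)$ per segment and the
simulator's bias process uses the same forward-Euler discretization —
model and data generator agree by construction.

The measurement is the accelerometer inclination
$\mathrm{atan2}(a_x, a_z)$ (the convention places gravity along sensor
$+Z$ at zero inclination, sagittal rotation about sensor $Y$) minus the
gyro-integrated angle — an observation of $\Delta\theta$.  A frame is
used only when it passes the reliability gate
$\Psi: |\,\lVert a\rVert - |g|\,| \le \zeta$.

**On the units of ζ.**  The gate compares acceleration magnitudes, so ζ is
interpreted in m/s² with default 0.4 (about 4 % of gravity).  It is the
single most influential tuning knob: small ζ yields few but clean updates,
large ζ admits inclination measurements contaminated by motion
acceleration.

## The three filters

* **Local** — four independent two-state filters.  Each segment updates
  only when its own accelerometer passes Ψ.
* **Matricial** — one filter over the stacked eight-dimensional state.
  $\bar A$ is block-diagonal with the per-segment blocks above, $\bar C$
  selects the angle-error component of every segment, and $Q, R$ are
  diagonal.  Updates use only the $\bar C$ rows of reliable segments and
  require **at least two** reliable IMUs; cross-segment corrections arise
  through the off-diagonal covariance that the update itself creates.
  With a block-diagonal covariance and all segments reliable the filter
  is algebraically identical to four local filters — a property the test
  suite exploits as an oracle.
* **Markovian** — a jump filter using only the *most* reliable IMU,
  $\Theta(k) = \arg\min_i |\,\lVert a_i\rVert - |g|\,|$ with reliability
  index $\rho(k)$ equal to the attained minimum.  If $\rho$ fails Ψ, only
  the prediction runs.  Otherwise the anchor's inclination is chained to
  every other segment through the exoskeleton potentiometer joint angles
  (hip = θ_T − θ_B, knee = θ_S − θ_T, ankle = θ_F − θ_S), producing a
  full four-element measurement each update.  The anchor choice depends
  only on the current frame — the Markovian jump.

**Reconstruction note.**  The precise measurement model of the original
Markovian jump formulation is not fully specified in the literature this
package draws on; the potentiometer-chaining construction here is our
reconstruction.  The measurement covariance of a non-anchor segment is
inflated by one potentiometer noise variance per joint crossed, which is
the natural error propagation of the chain.  Ties in the argmin are broken
in the fixed segment order B, T, S, F.

## Numerical choices

* Covariance updates use the Joseph form
  $P = (I-KH)P(I-KH)^\top + KRK^\top$ and every predict/update symmetrizes
  $P \leftarrow (P + P^\top)/2$; the test suite verifies the minimum
  eigenvalue stays above $-10^{-9}$ over $10^4$ steps for all filters.
* Initial covariance is $\mathrm{diag}(\sigma_{\theta_0}^2, \sigma_{b_0}^2)$
  with defaults (1 deg)², (0.5 deg/s)² — wide enough to converge from a
  poor initial angle within a few updates.
* Angles are kept in degrees throughout and never wrapped: simulated and
  estimated gait stays well inside ±120°, and `run_filter()` warns if the
  integrated angle leaves ±175°.
* The exported step functions validate symmetry/PSD-ness of the incoming
  covariance; the trial driver uses the same arithmetic on a fast path.

## Filter parameters

| parameter    | units          | default | role |
|--------------|----------------|---------|------|
| `tau_g`      | s              | 50      | bias correlation time; large values make the bias nearly constant |
| `sigma_g`    | deg/s          | 0.3     | process noise on the angle error (gyro white noise) |
| `sigma_bg`   | deg/s/√s       | 0.07    | driving noise of the bias state |
| `sigma_meas` | deg            | 1       | inclination measurement noise; ≈ (σ_a/g)·180/π plus a margin for motion leakage below ζ |
| `sigma_pot`  | deg            | 0.25    | potentiometer joint-angle noise (Markovian only) |
| `zeta`       | m/s²           | 0.4     | reliability gate width |

`optimize_params()` searches any subset of these by a small
differential-evolution population loop (deterministic given a seed),
minimizing mean validation-window RMSE across the protocol's start points.
It is a generic stand-in for the genetic optimizers common in this
literature; no equivalence with any specific optimizer is claimed.

# The synthetic data generator

No motion-capture reference is distributed with the package; all claims
are verified on synthetic data whose generating process is fully known.

Each segment angle is a two-term Fourier series (fundamental at the gait
cycle frequency plus one harmonic).  Defaults — 1.1 s cycle, amplitudes
3/25/35/20° for trunk/thigh/shank/foot — are plausible slow-treadmill
magnitudes, chosen once as configuration, not as a reproduction of any
subject.  The generated series carries its analytic derivative so the
simulated gyroscope reads the true angular rate; hand-built trajectories
fall back to central differences.

The gyroscope adds a Gauss–Markov bias (forward-Euler, matching the
filter model) and white noise.  The accelerometer reads gravity rotated
by the segment angle plus a *motion acceleration* term that is zero during
a per-segment quasi-static dwell window in each gait cycle.  The trunk is
configured with the smallest dwell fraction — it is the segment with the
fewest quasi-static moments — so the cooperative filters have something
real to cooperate about.  The motion term acts mostly along the local
gravity direction, with a 30 % tangential leakage along sensor X.  This
split has two deliberate consequences: the acceleration-norm deviation
equals the motion magnitude (so the fraction of Ψ-passing frames is
provably non-increasing in the motion amplitude, a tested invariant), and
frames that pass the gate still carry a bounded inclination error of up to
about `0.3·ζ/g` radians — the realistic price of a finite gate.

What the simulator does **not** emulate: soft-tissue artifact,
out-of-sagittal-plane motion (the whole package is planar by design),
magnetometers, impact transients at heel strike, or exoskeleton
compliance.  Passing tests therefore demonstrate the correctness of the
algorithms under the stated error model, not clinical accuracy on real
gait data.

# Calibration

Sensor models are linear: digital = gain·physical + bias, with a linear
temperature drift of the gyroscope offset and, optionally, a linear rate
dependence of the gyroscope scale (`digital = gain(1 + s·|ω|)ω + …`).

* **Six-position** (accelerometer): the six ±g static poses give 18
  equations for the 12 parameters of a full 3×3 gain and bias — fitted by
  ordinary least squares.  The full matrix captures cross-axis
  misalignment; the gyroscope rigs rotate about one axis at a time, so
  only a diagonal gyro gain is identifiable and fitted.
* **90° executions** (simplified): bias from the static dwells; the scale
  correction is the one-parameter least-squares fit of the integrated,
  bias-removed angle of every execution to its ±90° reference,
  $c = \sum I_e r_e / \sum I_e^2$.  Static dwells are detected by
  thresholding the signal against its median (default 5 counts for at
  least 0.5 s) and the moving mask is dilated by 0.2 s so that the
  low-rate tails of each pulse are not clipped from the integral.
* **Turntable** (complex): per axis, the mean reading at each constant
  rate is regressed on ω and ω·|ω|; the quadratic term (normalized by the
  gain) is the rate-dependent scale — the component the 90° protocol
  *cannot* observe, because a single integrated scale absorbs the rate
  dependence only at the rig's own rates.
* **Temperature sweep**: offset drift regressed on temperature over a
  10–50 °C ramp; compensation is applied to the offset only, not the
  scale.  The complex protocol reuses the six-position accelerometer fit —
  the protocols differ in their gyroscope calibration.

Applying a calibration inverts the model; the rate-dependent scale is
removed by a four-iteration fixed point, ample for |s·ω| well below 1.

# Evaluation protocol and the factorial experiment

`eval_protocol()` splits a trial into disjoint optimization and validation
windows with `n_start` start points each (default 6, i.e. 36 combinations
per filter), since the initialization point influences KF convergence.
`run_factorial_experiment()` runs the full loop per replicate seed:
simulate a trial, corrupt it through an injected sensor-error truth
(gains ~2–4 %, biases, 1–1.5·10⁻⁴ per deg/s rate-dependent scale),
simulate all four rigs, fit both calibration protocols, apply each, run
each filter from each start point, and score RMSE/ME on the validation
window.  `summarize_factorial()` reduces the table to filter × calibration
means and per-replicate paired differences; the acceptance suite turns the
simplified-vs-complex contrast into a sign test across 20 replicates.

Problem sizes used by the shipped tests — 10–20 s trials for unit and
factorial checks, 60 s for drift correction, 200 s for the covariance
stress test — were chosen to exercise hundreds of gait cycles while
keeping the whole suite comfortably interactive.

# Known limitations

* Strictly planar: a scalar angle per segment, no quaternions, no
  magnetometer.
* The Markovian measurement construction is a documented reconstruction,
  not a verified reimplementation of the original jump filter.
* The optimizer is a generic population search; published results
  obtained with specific genetic algorithms are not expected to be
  numerically reproduced.
* Calibration models are linear; spline or polynomial sensor
  nonlinearities and in-field calibration are out of scope.
* Published RMSE tables from studies of this design rest on subject data
  that is not publicly deposited; this package verifies *properties*
  (oracle equivalences, parameter recovery, drift correction, calibration
  ordering) rather than reproducing those numbers.
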