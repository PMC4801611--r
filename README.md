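# gaitfuse

Sensor fusion for gait analysis: estimating absolute sagittal-plane segment
angles (trunk, thigh, shank, foot) from body-worn IMUs and exoskeleton
potentiometers, and quantifying how inertial sensor **calibration quality**
interacts with the choice of **Kalman filter**.

## The problem

Integrating a gyroscope gives a segment's orientation but drifts without
bound; an accelerometer doubles as an inclinometer, but only in the
quasi-static instants when the measured acceleration is almost pure gravity.
`gaitfuse` fuses the two with discrete error-state Kalman filters.  Writing
θ̂ᵢ(t) = θ̂ᵍᵢ(t) + Δθ̂ᵢ(t) for segment i ∈ {B, T, S, F} (trunk, thigh,
shank, foot), the filter state per segment is the correction
x = (Δθ, Δb) — angle error and gyro bias error — with dynamics

    ẋ = A x + w,   A = [[0, 1], [0, −1/τ_g]],   z = [1, 0] x + v

discretized as F = I + A·T, G = B·√T, H = C at T = 1/50 s.  The bias error
is a first-order Gauss–Markov process with correlation time τ_g.
Accelerometer frames pass the reliability gate Ψ only when
| ‖a‖ − |g| | ≤ ζ.

Three filters share this model:

* **Local KF** — four independent 2-state filters; a segment is corrected
  only when its own accelerometer is reliable.  Segments with few
  quasi-static moments (the trunk, during walking) go long stretches
  without updates.
* **Matricial KF** (cooperative) — one filter over the stacked 8-state
  vector; updates use the C̄ rows of every reliable segment and require at
  least two reliable IMUs.  Corrections propagate across segments through
  the shared covariance.
* **Markovian KF** (cooperative jump filter) — each frame the most reliable
  IMU, Θ(k) = argminᵢ | ‖aᵢ‖ − |g| |, anchors the measurement, and the
  exoskeleton potentiometer joint angles (hip, knee, ankle) chain its
  inclination to every other segment.  The anchor switch is memoryless — a
  Markovian jump.

Around the filters the package provides the two **calibration pipelines**
that map raw digital sensor counts to physical units — a *simplified*
protocol (six-position accelerometer holds, hand-rig 90° gyroscope
executions, linear temperature model) and a *complex* protocol (precision
turntable at ±100…500 deg/s that additionally resolves the rate-dependent
gyroscope scale) — plus a **synthetic gait simulator** (ground-truth
trajectories, gyro bias drift, gated motion acceleration, potentiometers,
and every calibration rig) that makes the full pipeline verifiable end to
end, and an **evaluation harness** (ME/RMSE, multi-start protocol,
differential-evolution parameter search, filter × calibration factorial).

## Worked example

Simulate a 30 s walk with a 0.5 deg/s initial gyro bias, then run each
filter against the ground truth:

```r
library(gaitfuse)

cfg  <- gait_config(duration = 30, bias_init = 0.5, seed = 7)
traj <- generate_trajectory(cfg)
sim  <- simulate_imu(traj, cfg)
pots <- simulate_potentiometers(traj, seed = 8)

for (f in c("gyro", "local", "matricial", "markovian")) {
  res <- run_filter(sim$recording, pots = pots, filter = f,
                    theta0 = traj$angles[1, ])
  sc <- score_filter(res, traj)
  cat(sprintf("%-10s  RMSE %.2f deg (trunk %.2f)  updates %.0f%%\n",
              f, mean(sc$rmse), sc$rmse[1], 100 * update_fraction(res)))
}
#> gyro        RMSE 8.40 deg (trunk 8.72)  updates 0%
#> local       RMSE 0.12 deg (trunk 0.12)  updates 56%
#> matricial   RMSE 0.12 deg (trunk 0.11)  updates 82%
#> markovian   RMSE 0.08 deg (trunk 0.08)  updates 95%
```

Uncorrected gyro integration drifts to an 8° RMSE within 30 s; every
filter holds the error an order of magnitude lower, and the cooperative
filters update far more often than the local one because they pool
reliability across sensors.  The calibration side:

```r
truth <- sensor_model(gyro_gain = c(1.03, 1.04, 0.97),
                      gyro_bias = c(0.5, 0.8, -0.6),
                      rate_scale = c(1e-4, 1.5e-4, 1.2e-4))
rigs <- list(six_position = simulate_rig("six_position", truth),
             ninety_deg   = simulate_rig("ninety_deg", truth),
             turntable    = simulate_rig("turntable", truth))
fit_calibration(rigs, "complex")$rate_scale   # recovers ~ c(1e-4, 1.5e-4, 1.2e-4)
fit_calibration(rigs, "simplified")$rate_scale # cannot: c(0, 0, 0)
```

`run_factorial_experiment()` turns this contrast into the full filter ×
calibration comparison across replicate trials; see the methods vignette
(`vignettes/segment-angle-fusion.Rmd`) for the model details and design
choices.

A command-line wrapper is installed at `inst/cli/gaitfuse` with
`simulate`, `calibrate`, `filter` and `evaluate` subcommands over the same
functions.

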