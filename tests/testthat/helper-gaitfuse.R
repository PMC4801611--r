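# Shared fixtures, all generated in code.

# short clean trial: no noise, no bias, no motion acceleration
clean_config <- function(duration = 10, seed = 42, bias_init = 0,
                         motion_amp = 0, ...) {
  gait_config(duration = duration, seed = seed,
              motion_amp = motion_amp, bias_init = bias_init,
              sigma_g = 0, sigma_b = 0, sigma_a = 0, ...)
}

# short realistic trial with drifting gyros
noisy_config <- function(duration = 10, seed = 42, ...) {
  gait_config(duration = duration, seed = seed, bias_init = 0.5, ...)
}

make_trial <- function(cfg, pot_noise = 0, pot_seed = cfg$seed + 1L) {
  traj <- generate_trajectory(cfg)
  sim <- simulate_imu(traj, cfg)
  pots <- simulate_potentiometers(traj, noise_std = pot_noise,
                                  seed = pot_seed)
  list(cfg = cfg, traj = traj, rec = sim$recording,
       bias = sim$bias_truth, pots = pots)
}

# a deliberately imperfect sensor used across calibration tests
example_truth <- function(rate_scale = c(1e-4, 1.5e-4, 1.2e-4)) {
  sensor_model(
    accel_gain = matrix(c(1.02, 0.003, -0.002,
                          0.001, 0.98, 0.004,
                          -0.003, 0.002, 1.01), 3, 3, byrow = TRUE),
    accel_bias = c(10, -5, 3),
    gyro_gain = c(1.03, 1.04, 0.97),
    gyro_bias = c(0.5, 0.8, -0.6),
    gyro_temp_coeff = c(0.02, 0.2, 0.05),
    rate_scale = rate_scale
  )
}
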