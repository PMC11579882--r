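# Shared synthetic fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

# noise-free walking trial bundle (kinematics, sensors, body, ground truth)
clean_trial <- function() {
  if (is.null(.fixture_cache$clean)) {
    cfg <- synthetic_config(n_cycles = 6, imu_noise_sd_acc = 0,
                            imu_noise_sd_gyro = 0, rng_seed = 11L)
    poses <- generate_segment_kinematics(cfg)
    body <- scale_body_model(cfg$height, cfg$mass)
    .fixture_cache$clean <- list(
      cfg = cfg, poses = poses, body = body,
      trial = derive_imu_signals(poses, cfg),
      truth = truth_loads(poses, body, cfg))
  }
  .fixture_cache$clean
}

# trial with default (small) sensor noise, for detection under noise
noisy_trial <- function() {
  if (is.null(.fixture_cache$noisy)) {
    cfg <- synthetic_config(n_cycles = 6, rng_seed = 23L)
    poses <- generate_segment_kinematics(cfg)
    .fixture_cache$noisy <- list(
      cfg = cfg, poses = poses,
      trial = derive_imu_signals(poses, cfg),
      truth = truth_loads(poses, config = cfg))
  }
  .fixture_cache$noisy
}

# short EMG recording plus its processed envelopes
emg_fixture <- function() {
  if (is.null(.fixture_cache$emg)) {
    cfg <- synthetic_config(n_cycles = 4, rng_seed = 31L)
    poses <- generate_segment_kinematics(cfg)
    truth <- truth_loads(poses, config = cfg)
    rec <- generate_emg(cfg, truth)
    .fixture_cache$emg <- list(cfg = cfg, truth = truth, rec = rec,
                               proc = suppressMessages(process_emg(rec)))
  }
  .fixture_cache$emg
}

# events detected on the clean trial
clean_events <- function() {
  if (is.null(.fixture_cache$events)) {
    .fixture_cache$events <- suppressMessages(detect_gait_events(clean_trial()$trial))
  }
  .fixture_cache$events
}

# minimum-distance event timing errors (s) between detected and true events
event_timing_errors <- function(events, truth_events) {
  err <- function(det, tru) vapply(det, function(d) min(abs(tru - d)), 0)
  c(err(events$impaired$ic_time, truth_events$ic_imp),
    err(events$impaired$tc_time, truth_events$tc_imp),
    err(events$contralateral$ic_time, truth_events$ic_contra),
    err(events$contralateral$tc_time, truth_events$tc_contra))
}

# fourth-order central second-difference (error O(h^4), exact for quintics)
second_derivative_o4 <- function(x, rate) {
  n <- length(x)
  d <- rep(NA_real_, n)
  i <- 3:(n - 2)
  d[i] <- (-x[i - 2] + 16 * x[i - 1] - 30 * x[i] + 16 * x[i + 1] - x[i + 2]) *
    rate^2 / 12
  d
}

# samples well inside the trial and away from piecewise-curve boundaries
interior_mask <- function(time, cfg, margin = 0.08) {
  T <- cfg$stride_period
  u <- (time / T) %% 1
  d <- cfg$duty_factor
  r <- cfg$rotation_halfwidth
  wf <- min(0.15, 0.8 * (1 - d - 2 * r))   # generator's pivot fade-out width
  boundaries <- c(0, r, d - r, d, d + r, d + r + wf, 1 - r, 1)
  near <- Reduce(`|`, lapply(boundaries, function(b) {
    pmin(abs(u - b), abs(u - b + 1), abs(u - b - 1)) < margin
  }))
  ok <- !near
  ok[seq_len(10)] <- FALSE
  ok[(length(ok) - 9):length(ok)] <- FALSE
  ok
}
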