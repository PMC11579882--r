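test_that("static registration: identity, mount recovery, pose bias", {
  cfg <- synthetic_config(n_cycles = 2, imu_noise_sd_acc = 0, imu_noise_sd_gyro = 0)
  static <- derive_imu_signals(generate_static_trial(cfg), cfg)
  reg <- register_sensors_static(static)
  expect_lt(max(reg$angles), 1e-9)
  # a 15-degree sensor mount offset on the shank is recovered
  offs <- stats::setNames(rep(list(quat(1)), 5), wearlab:::SEGMENTS)
  offs$shank <- quat_from_axis_angle(c(0, 0, 1), 15 * pi / 180)
  cfg2 <- synthetic_config(n_cycles = 2, imu_noise_sd_acc = 0,
                           imu_noise_sd_gyro = 0, mount_offsets = offs)
  static2 <- derive_imu_signals(generate_static_trial(cfg2), cfg2)
  reg2 <- register_sensors_static(static2)
  expect_lt(abs(reg2$angles[["shank"]] - 15 * pi / 180), 0.1 * pi / 180)
  # flexed static pose biases the downstream knee angle by that flexion
  static3 <- derive_imu_signals(
    generate_static_trial(cfg, pose = list(knee = 10 * pi / 180)), cfg)
  reg3 <- register_sensors_static(static3)
  walking <- derive_imu_signals(generate_segment_kinematics(cfg), cfg)
  truth <- generate_segment_kinematics(cfg)$truth
  ang3 <- joint_angles(walking, reg3)
  bias <- mean(ang3$knee - truth$knee_angle)
  expect_equal(bias, -10 * pi / 180, tolerance = 1e-6)
  # a moving trial is rejected
  expect_error(register_sensors_static(walking), "gyro RMS")
})

test_that("joint angles from relative orientations", {
  cfg <- synthetic_config(n_cycles = 2, imu_noise_sd_acc = 0, imu_noise_sd_gyro = 0)
  static <- derive_imu_signals(generate_static_trial(cfg), cfg)
  reg <- register_sensors_static(static)
  # all segments identically oriented: zero angles
  ang0 <- joint_angles(static, reg)
  expect_lt(max(abs(ang0$knee)), 1e-9)
  expect_lt(max(abs(ang0$ankle)), 1e-9)
  # shank rotated 30 degrees about +z relative to thigh: knee flexion 30
  trial30 <- static
  q30 <- quat_from_axis_angle(c(0, 0, 1), 30 * pi / 180)
  trial30$sensors$shank$quat <- quat_multiply(trial30$sensors$shank$quat, q30)
  trial30$sensors$foot_imp$quat <- quat_multiply(trial30$sensors$foot_imp$quat, q30)
  ang30 <- joint_angles(trial30, reg)
  expect_equal(ang30$knee, rep(30 * pi / 180, length(ang30$knee)),
               tolerance = 1e-9)
  expect_lt(max(abs(ang30$ankle)), 1e-9)
  expect_error(joint_angles(structure(list(sensors = list()), class = "ImuTrial"),
                            reg), "missing sensor")
})

test_that("noise-free pipeline angles recover the generator truth within 2 deg", {
  fx <- clean_trial()
  static <- derive_imu_signals(generate_static_trial(fx$cfg), fx$cfg)
  reg <- register_sensors_static(static)
  ang <- joint_angles(fx$trial, reg)
  expect_lt(sqrt(mean((ang$knee - fx$truth$knee_angle)^2)), 2 * pi / 180)
  expect_lt(sqrt(mean((ang$ankle - fx$truth$ankle_angle)^2)), 2 * pi / 180)
})

test_that("planar inverse dynamics reproduces closed-form static cases", {
  body <- scale_body_model(1.70, 80)
  n <- 600; rate <- 100
  pos <- matrix(rep(c(1, 0.05, 0.1), each = n), n)
  q <- quat(rep(1, n), 0, 0, 0)
  acc <- matrix(rep(c(0, 9.81, 0), each = n), n)    # resting accelerometer
  # GRF applied directly below the ankle: no GRF moment, gravity term only
  p_ankle <- c(1, 0.05, 0.1) + body$ankle_offset
  Fv <- 500
  grf <- matrix(rep(c(0, Fv, 0), each = n), n)
  cop <- matrix(rep(c(p_ankle[1], 0, p_ankle[3]), each = n), n)
  tq <- ankle_inverse_dynamics(pos, q, acc, grf, cop, body, rate)
  r <- body$foot_com_offset - body$ankle_offset
  expected <- r[1] * body$masses[["foot"]] * 9.81   # [r x m(a - g)]_z
  expect_equal(mean(tq$nm[50:550]), expected, tolerance = 1e-9)
  expect_equal(tq$nm_per_kg, tq$nm / 80)
  # zero GRF, horizontal static foot: pure gravity moment about the ankle
  grf0 <- matrix(0, n, 3)
  cop0 <- matrix(NA_real_, n, 3)
  tq0 <- ankle_inverse_dynamics(pos, q, acc, grf0, cop0, body, rate)
  expect_equal(mean(tq0$nm[50:550]), expected, tolerance = 1e-9)
  expect_error(ankle_inverse_dynamics(pos[1:10, ], q, acc, grf, cop, body, rate),
               "misaligned")
})

test_that("inverse dynamics with true loads matches the generator torque", {
  fx <- clean_trial()
  am <- to_model_frame(fx$trial$sensors$foot_imp$acc, fx$trial$sensors$foot_imp$quat)
  tq <- ankle_inverse_dynamics(fx$poses$segments$foot_imp$pos,
                               fx$poses$segments$foot_imp$quat,
                               am, fx$truth$grf$imp, fx$truth$cop$imp,
                               fx$body, fx$cfg$imu_rate)
  rmse <- sqrt(mean((tq$nm - fx$truth$ankle_torque)^2)) / fx$body$mass
  expect_lt(rmse, 0.02)
})

test_that("cycle normalisation: endpoints, identical cycles, rate invariance", {
  phases <- structure(data.frame(ic_imp = 1L, tc_contra = 10L, ic_contra = 40L,
                                 tc_imp = 60L, ic_next = 101L),
                      class = c("GaitPhaseTable", "data.frame"))
  ramp <- seq(0, 1, length.out = 101)
  nc <- normalize_cycles(ramp, phases)
  expect_equal(nc$mean, ramp)
  expect_equal(nc$mean[c(1, 101)], c(0, 1))
  two <- structure(data.frame(ic_imp = c(1L, 101L), tc_contra = c(10L, 110L),
                              ic_contra = c(40L, 140L), tc_imp = c(60L, 160L),
                              ic_next = c(101L, 201L)),
                   class = c("GaitPhaseTable", "data.frame"))
  x <- rep(sin(seq(0, 2 * pi, length.out = 101))[-101], length.out = 201)
  nc2 <- normalize_cycles(x, two)
  expect_lt(max(nc2$sd), 1e-9)
  # same sine sampled at two rates normalises to the same curve
  mk <- function(n) {
    ph <- structure(data.frame(ic_imp = 1L, tc_contra = round(n * 0.1),
                               ic_contra = round(n * 0.4), tc_imp = round(n * 0.6),
                               ic_next = n), class = c("GaitPhaseTable", "data.frame"))
    normalize_cycles(sin(2 * pi * seq(0, 1, length.out = n)), ph)$mean
  }
  expect_lt(max(abs(mk(1001) - mk(2001))), 1e-3)
})

test_that("agreement metrics separate shape from amplitude", {
  x <- c(1, 2, 3, 4)
  expect_equal(agreement_metrics(x, x), list(r2 = 1, rmse = 0))
  m5 <- agreement_metrics(x, x + 5)
  expect_equal(m5$r2, 1)
  expect_equal(m5$rmse, 5)
  # hand-computed case
  m <- agreement_metrics(c(1, 2, 3, 4), c(2, 2, 4, 4))
  expect_equal(m$r2, 0.8)
  expect_equal(m$rmse, sqrt(0.5))
  # RMSE symmetric, R^2 invariant to positive affine transforms
  expect_equal(agreement_metrics(c(2, 2, 4, 4), c(1, 2, 3, 4))$rmse, m$rmse)
  expect_equal(agreement_metrics(c(1, 2, 3, 4), 3 * c(2, 2, 4, 4) + 1)$r2, m$r2)
  expect_warning(z <- agreement_metrics(rep(1, 5), 1:5), "zero-variance")
  expect_true(is.na(z$r2))
  expect_equal(agreement_metrics(x, x + 5, mass = 10)$rmse_per_kg, 0.5)
  expect_error(agreement_metrics(1:2, 1:2), "3 finite")
  # SSE variant penalises the offset
  expect_lt(agreement_metrics(x, x + 5, variant = "sse")$r2, 0)
})
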