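test_that("pre-calibration scales fiber and slack lengths consistently", {
  generic <- generic_mtu_table()
  # s = 1: parameters unchanged
  p1 <- precalibrate_lom_lst(scale_mtu_geometry(generic, 1), 1)
  expect_equal(p1$l_om, generic$l_om, tolerance = 1e-6)
  expect_equal(p1$l_st, generic$l_st, tolerance = 1e-6)
  # uniform geometry scaling with uniformly scaled lengths leaves the
  # normalised fiber length curve unchanged (algebraic identity)
  s <- 1.12
  grid <- seq(-0.4, 0.4, length.out = 17)
  ps <- precalibrate_lom_lst(scale_mtu_geometry(generic, s), s)
  for (i in seq_len(nrow(generic))) {
    g <- generic[i, ]
    lmt_gen <- g$c0 + g$c1 * grid + g$c2 * grid^2
    lnorm <- function(lmt, lom, lst)
      sqrt(pmax(lmt - lst, 0)^2 + (lom * sin(g$penn0))^2) / lom
    expect_equal(lnorm(lmt_gen * s, ps$l_om[i], ps$l_st[i]),
                 lnorm(lmt_gen, g$l_om, g$l_st), tolerance = 1e-6)
  }
  expect_true(all(ps$l_om > 0 & ps$l_st > 0))
  expect_error(precalibrate_lom_lst(generic, -1), "positive")
})

test_that("excitation-to-activation shaping: endpoints, limit, monotonicity", {
  expect_equal(excitation_to_activation(0, -2), 0)
  expect_equal(excitation_to_activation(1, -2), 1)
  u <- seq(0, 1, by = 0.05)
  expect_lt(max(abs(excitation_to_activation(u, -1e-6) - u)), 1e-5)
  a <- excitation_to_activation(u, -2.5)
  expect_true(all(diff(a) > 0))
  expect_true(all(a[-c(1, length(a))] > u[-c(1, length(u))]))  # A < 0 amplifies
  expect_error(excitation_to_activation(0.5, 0), "A must")
  expect_error(excitation_to_activation(0.5, -3.5), "A must")
})

test_that("muscle-tendon lengths and analytic moment arms", {
  geom <- generic_mtu_table()
  # constant and linear geometries
  gc <- geom[1, ]; gc$c1 <- 0; gc$c2 <- 0; gc$ck <- 0
  ang <- list(knee = rep(0, 5), ankle = seq(-0.3, 0.3, length.out = 5))
  expect_true(all(mtu_length_and_arm(ang, gc)$arm == 0))
  gl <- gc; gl$c1 <- -0.05
  expect_true(all(mtu_length_and_arm(ang, gl)$arm == 0.05))
  # analytic arm equals central differences of lmt
  ka <- mtu_length_and_arm(ang, geom)
  h <- 1e-5
  kp <- mtu_length_and_arm(list(knee = ang$knee, ankle = ang$ankle + h), geom)
  km <- mtu_length_and_arm(list(knee = ang$knee, ankle = ang$ankle - h), geom)
  fd <- -(kp$lmt - km$lmt) / (2 * h)
  expect_lt(max(abs(ka$arm - fd)), 1e-6)
  # out-of-range angles are clamped with a warning
  expect_warning(mtu_length_and_arm(list(knee = 0, ankle = 2), geom), "clamped")
  # sign conventions over the neutral range: dorsiflexors positive
  angn <- list(knee = rep(0, 9), ankle = seq(-0.3, 0.3, length.out = 9))
  arms <- mtu_length_and_arm(angn, geom)$arm
  expect_true(all(arms[, c("tib_ant", "ext_hal_long")] > 0))
  expect_true(all(arms[, c("med_gas", "lat_gas", "soleus",
                           "per_brev", "per_long")] < 0))
})

test_that("Hill force anchors and monotonicity", {
  params <- precalibrate_lom_lst(generic_mtu_table(), 1)
  m <- nrow(params)
  # lmt chosen so the normalised fiber length is exactly 1
  lmt1 <- matrix(params$l_st + params$l_om * cos(params$penn0), 1, m, byrow = TRUE)
  v0 <- matrix(0, 1, m)
  Fmax <- hill_mtu_force(matrix(1, 1, m), lmt1, v0, params)
  expect_equal(as.numeric(Fmax), params$f_max * cos(params$penn0),
               tolerance = 1e-9)
  F0 <- hill_mtu_force(matrix(0, 1, m), lmt1, v0, params)
  expect_equal(as.numeric(F0), rep(0, m))
  # non-decreasing in activation for fixed kinematics
  prev <- rep(-Inf, m)
  for (a in seq(0, 1, by = 0.1)) {
    Fa <- as.numeric(hill_mtu_force(matrix(a, 1, m), lmt1 * 1.02, v0 + 0.01, params))
    expect_true(all(Fa >= prev - 1e-12))
    prev <- Fa
  }
  # slack muscle-tendon unit produces no force and is flagged
  slack <- hill_mtu_force(matrix(1, 1, m), matrix(0.9 * params$l_st, 1, m,
                                                  byrow = TRUE), v0, params)
  expect_equal(as.numeric(slack), rep(0, m))
  expect_true(all(attr(slack, "slack") == 1))
})

test_that("torque assembly and plantar-flexion sign convention", {
  z <- matrix(0, 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_true(all(ankle_torque_from_mtus(z, z, 100, 70)$nm == 0))
  F <- matrix(c(100, 0), 1, dimnames = list(NULL, c("a", "b")))
  r <- matrix(c(-0.05, 0.02), 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(ankle_torque_from_mtus(F, r, 100, 70)$nm, -5)
  expect_error(ankle_torque_from_mtus(F, r[, 2:1]), "mismatched")
  # a soleus-only activation bump gives plantar-flexion (negative) torque
  geom <- generic_mtu_table()
  params <- precalibrate_lom_lst(geom, 1)
  n <- 50
  env <- matrix(0, n, 7, dimnames = list(NULL, wearlab:::MUSCLES))
  env[20:30, "soleus"] <- 0.8
  ang <- list(knee = rep(0, n), ankle = rep(0, n))
  est <- estimate_torque(params, env, ang, geom, 100, 70)
  expect_true(all(est$torque$nm[20:30] < 0))
})

test_that("estimated torque decomposes into passive and activation parts", {
  geom <- generic_mtu_table()
  params <- precalibrate_lom_lst(geom, 1)
  n <- 60
  ang <- list(knee = rep(0.2, n), ankle = seq(-0.35, 0.35, length.out = n))
  env0 <- matrix(0, n, 7)
  est0 <- estimate_torque(params, env0, ang, geom, 100, 70)
  expect_equal(est0$torque$nm, est0$passive_torque)
  set.seed(14)
  env <- matrix(runif(n * 7, 0, 0.8), n, 7)
  est1 <- estimate_torque(params, env, ang, geom, 100, 70)
  est2 <- estimate_torque(params, env * 0.5, ang, geom, 100, 70)
  expect_equal(est1$passive_torque, est2$passive_torque)
  expect_false(isTRUE(all.equal(est1$torque$nm, est2$torque$nm)))
})

test_that("calibration recovers a known model on held-out data", {
  body <- scale_body_model(1.775, 94.2)
  geometry <- scale_mtu_geometry(generic_mtu_table(), body$scale)
  p0 <- precalibrate_lom_lst(geometry, body$scale)
  set.seed(42)
  truth_p <- p0
  truth_p$l_om <- p0$l_om * runif(7, 0.96, 1.04)
  truth_p$l_st <- p0$l_st * runif(7, 0.96, 1.04)
  truth_p$strength <- runif(7, 0.8, 1.5)
  truth_p$shape_A <- runif(7, -2.5, -0.5)
  one_cycle <- function(cadence) {
    cfg <- synthetic_config(n_cycles = 3, cadence = cadence,
                            imu_noise_sd_acc = 0, imu_noise_sd_gyro = 0)
    poses <- generate_segment_kinematics(cfg)
    tr <- truth_loads(poses, body, cfg)
    T <- cfg$stride_period
    idx <- which(poses$time >= T & poses$time < 2 * T)
    list(env = tr$activations[idx, ],
         ang = list(knee = tr$knee_angle[idx], ankle = tr$ankle_angle[idx]),
         rate = cfg$imu_rate)
  }
  cal_data <- one_cycle(100)
  ref <- estimate_torque(truth_p, cal_data$env, cal_data$ang, geometry,
                         cal_data$rate, body$mass)$torque
  # self-consistency: starting at the truth, the objective is already zero
  cal0 <- calibrate_mtu(cal_data$env, cal_data$ang, ref$nm, geometry, truth_p,
                        cal_data$rate, seed = 1,
                        control = list(pop = 8, gens = 2))
  expect_equal(cal0$objective_init, 0, tolerance = 1e-12)
  expect_lte(cal0$objective_final, cal0$objective_init + 1e-12)
  # recovery from the perturbed pre-calibrated start
  cal <- calibrate_mtu(cal_data$env, cal_data$ang, ref$nm, geometry, p0,
                       cal_data$rate, seed = 7,
                       control = list(pop = 30, gens = 60))
  expect_lte(cal$objective_final, cal$objective_init)
  expect_gte(cal$metrics$r2, 0.99)
  expect_lte(cal$metrics$rmse / body$mass, 0.02)
  expect_true(all(cal$params$l_om >= p0$l_om * 0.95 - 1e-12 &
                    cal$params$l_om <= p0$l_om * 1.05 + 1e-12))
  # held-out cycle at a different cadence
  new_data <- one_cycle(115)
  ref2 <- estimate_torque(truth_p, new_data$env, new_data$ang, geometry,
                          new_data$rate, body$mass)$torque
  est2 <- estimate_torque(cal, new_data$env, new_data$ang, geometry,
                          new_data$rate, body$mass)$torque
  expect_gte(agreement_metrics(ref2$nm, est2$nm)$r2, 0.95)
  # determinism under a fixed seed
  cal_b <- calibrate_mtu(cal_data$env, cal_data$ang, ref$nm, geometry, p0,
                         cal_data$rate, seed = 7,
                         control = list(pop = 30, gens = 60))
  expect_identical(cal$params, cal_b$params)
  expect_identical(cal$trace, cal_b$trace)
  # objective invariant to a common rescaling of reference and model strength
  p2 <- p0; p2$f_max <- p0$f_max * 2
  cal2 <- calibrate_mtu(cal_data$env, cal_data$ang, 2 * ref$nm, geometry, p2,
                        cal_data$rate, seed = 1, control = list(pop = 8, gens = 2))
  expect_equal(cal2$objective_init, cal$objective_init, tolerance = 1e-12)
  expect_error(calibrate_mtu(cal_data$env, cal_data$ang, rep(1, nrow(cal_data$env)),
                             geometry, p0, cal_data$rate), "zero variance")
})
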