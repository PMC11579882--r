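#' Synthetic walking trials
#'
#' Self-consistent synthetic gait: smooth periodic planar segment kinematics,
#' inertial signals derived from those kinematics, gait-phase-locked
#' 64-channel EMG, and closed-form ground-truth loads and ankle torque. Every
#' downstream stage of the pipeline can be checked against this generator.
#'
#' The stride is parameterised by cycle phase `u in [0,1)` with the impaired
#' initial contact (IC) at `u = 0`, terminal contact (TC) at `u = duty`, and
#' the contralateral side offset by half a cycle. Foot rotation is
#' concentrated in short heel-strike and push-off windows of half-width `r`
#' (fraction of the cycle) centred exactly on the IC and TC instants, so the
#' angular-velocity magnitude peaks at the true events — the synthetic
#' counterpart of the heel-strike and push-off spikes that foot-worn gyros
#' show in real gait. The foot is exactly stationary over the whole stance
#' and exactly flat (constant orientation) on `[IC + r, TC - r]`.
#'
#' @name synthetic_gait
NULL

#' Synthetic trial configuration
#'
#' @param cadence steps per minute (two steps per stride); stride period is
#'   `120 / cadence` s.
#' @param walking_speed average forward pelvis speed, m/s.
#' @param n_cycles number of complete impaired-side gait cycles (>= 2).
#' @param duty_factor fraction of the cycle each foot spends in stance, in
#'   (0.5, 0.8); double support per transition lasts `duty_factor - 0.5`.
#' @param height,mass participant height (m) and mass (kg).
#' @param imu_rate,emg_rate sampling rates, Hz.
#' @param imu_noise_sd_acc,imu_noise_sd_gyro Gaussian sensor noise, m/s^2 and
#'   rad/s.
#' @param rotation_halfwidth half-width `r` of the heel-strike / push-off
#'   rotation windows, fraction of the cycle.
#' @param envelope_profiles per-muscle activation profiles, see
#'   [default_envelope_profiles()].
#' @param channel_map length-64 labels assigning grid channels to muscles or
#'   `"noisy"`, see [default_channel_map()].
#' @param mount_offsets named list of unit quaternions (sensor-to-segment
#'   mount offsets), default identity for all five sensors.
#' @param rng_seed integer seed for all stochastic parts of the generator.
#' @return a validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(cadence = 100, walking_speed = 1.1, n_cycles = 10,
                             duty_factor = 0.6, height = 1.775, mass = 94.2,
                             imu_rate = 100, emg_rate = 2000,
                             imu_noise_sd_acc = 0.05, imu_noise_sd_gyro = 0.01,
                             rotation_halfwidth = 0.05,
                             envelope_profiles = default_envelope_profiles(),
                             channel_map = default_channel_map(),
                             mount_offsets = NULL,
                             rng_seed = 1L) {
  if (cadence <= 0) stop("cadence must be positive")
  if (walking_speed <= 0) stop("walking_speed must be positive")
  if (n_cycles < 2) stop("n_cycles must be >= 2")
  if (duty_factor <= 0.5 || duty_factor >= 0.8)
    stop("duty_factor must lie in (0.5, 0.8) so double support exists")
  if (rotation_halfwidth <= 0 || rotation_halfwidth >= (duty_factor - 0.5))
    stop("rotation_halfwidth must be positive and smaller than duty_factor - 0.5")
  if (length(channel_map) != 64)
    stop("channel_map must assign exactly 64 channels")
  unknown <- setdiff(unique(channel_map), c(MUSCLES, "noisy"))
  if (length(unknown))
    stop("channel_map contains unknown labels: ", paste(unknown, collapse = ", "))
  if (!setequal(names(envelope_profiles), MUSCLES))
    stop("envelope_profiles must cover the seven muscles")
  if (is.null(mount_offsets))
    mount_offsets <- stats::setNames(rep(list(quat(1)), length(SEGMENTS)), SEGMENTS)
  cfg <- list(
    cadence = cadence, walking_speed = walking_speed, n_cycles = as.integer(n_cycles),
    duty_factor = duty_factor, height = height, mass = mass,
    imu_rate = imu_rate, emg_rate = emg_rate,
    imu_noise_sd_acc = imu_noise_sd_acc, imu_noise_sd_gyro = imu_noise_sd_gyro,
    rotation_halfwidth = rotation_halfwidth,
    envelope_profiles = envelope_profiles, channel_map = channel_map,
    mount_offsets = mount_offsets, rng_seed = as.integer(rng_seed),
    stride_period = 120 / cadence,
    stride_length = walking_speed * 120 / cadence
  )
  class(cfg) <- "synthetic_config"
  cfg
}

# ---- C2 curve primitives (value and first two derivatives wrt phase) -------

# quintic smoothstep: zero 1st and 2nd derivatives at both ends
.smoothstep <- function(u) {
  list(v  = u^3 * (10 - 15 * u + 6 * u^2),
       d1 = 30 * u^2 - 60 * u^3 + 30 * u^4,
       d2 = 60 * u - 180 * u^2 + 120 * u^3)
}

# unit bump with zero value/1st/2nd derivatives at both ends, max 1 at 0.5
.bump <- function(u) {
  list(v  = 64 * u^3 * (1 - u)^3,
       d1 = 192 * u^2 * (1 - u)^2 * (1 - 2 * u),
       d2 = 384 * u * (1 - u) * (5 * u^2 - 5 * u + 1))
}

# evaluate primitive f on window [a, b] of phase u; zero (incl. derivatives)
# outside; derivatives returned wrt u
.windowed <- function(u, a, b, f, scale = 1) {
  v <- d1 <- d2 <- numeric(length(u))
  inside <- u >= a & u <= b
  if (any(inside)) {
    w <- (u[inside] - a) / (b - a)
    g <- f(w)
    v[inside] <- scale * g$v
    d1[inside] <- scale * g$d1 / (b - a)
    d2[inside] <- scale * g$d2 / (b - a)^2
  }
  list(v = v, d1 = d1, d2 = d2)
}

.curve_add <- function(...) {
  cs <- list(...)
  list(v = Reduce(`+`, lapply(cs, `[[`, "v")),
       d1 = Reduce(`+`, lapply(cs, `[[`, "d1")),
       d2 = Reduce(`+`, lapply(cs, `[[`, "d2")))
}

.curve_const <- function(n, value = 0) {
  list(v = rep(value, n), d1 = numeric(n), d2 = numeric(n))
}

.curve_sin <- function(arg_u, freq, phase, amp, offset = 0) {
  a <- 2 * pi * freq
  list(v  = offset + amp * sin(a * arg_u + phase),
       d1 = amp * a * cos(a * arg_u + phase),
       d2 = -amp * a^2 * sin(a * arg_u + phase))
}

# convert phase-domain derivatives to time domain (u = t / T)
.to_time <- function(curve, T) {
  list(v = curve$v, d1 = curve$d1 / T, d2 = curve$d2 / T^2)
}

# foot sagittal pitch over one cycle: heel-strike rotation centred at u = 0,
# push-off rotation centred at u = d, smooth swing recovery between; C2
# across all region boundaries (quintic steps) and identically zero on the
# foot-flat interval [r, d - r]
.foot_pitch_curve <- function(u, d, r, theta_land, theta_push) {
  v <- d1 <- d2 <- numeric(length(u))
  piece <- function(idx, w, width, scale, offset = 0, flip = FALSE) {
    g <- .smoothstep(w)
    sgn <- if (flip) -1 else 1
    v[idx] <<- offset + sgn * scale * g$v
    d1[idx] <<- sgn * scale * g$d1 / width
    d2[idx] <<- sgn * scale * g$d2 / width^2
  }
  i <- u < r                                   # landing tail (window [-r, r])
  piece(i, (u[i] + r) / (2 * r), 2 * r, theta_land, theta_land, flip = TRUE)
  i <- u >= 1 - r                              # landing head
  piece(i, (u[i] - 1 + r) / (2 * r), 2 * r, theta_land, theta_land, flip = TRUE)
  i <- u >= d - r & u < d + r                  # push-off (window [d-r, d+r])
  piece(i, (u[i] - d + r) / (2 * r), 2 * r, theta_push, flip = TRUE)
  i <- u >= d + r & u < 1 - r                  # swing recovery
  piece(i, (u[i] - d - r) / (1 - d - 2 * r), 1 - d - 2 * r,
        theta_push + theta_land, -theta_push)
  list(v = v, d1 = d1, d2 = d2)
}

# foot forward translation within one cycle (0 in stance, stride in swing)
.foot_advance_curve <- function(u, d, stride) {
  .windowed(u, d, 1, .smoothstep, stride)
}

# rigid point attached to a rotating planar segment:
# p = base + Rz(theta) offset, with analytic time derivatives
.attach_point <- function(base, theta, offset) {
  ct <- cos(theta$v); st <- sin(theta$v)
  ox <- offset[1]; oy <- offset[2]; oz <- offset[3]
  rx <- ct * ox - st * oy
  ry <- st * ox + ct * oy
  # d/dtheta of rotated offset
  dx <- -st * ox - ct * oy
  dy <- ct * ox - st * oy
  pos <- cbind(base$pos[, 1] + rx, base$pos[, 2] + ry, base$pos[, 3] + oz)
  vel <- cbind(base$vel[, 1] + theta$d1 * dx,
               base$vel[, 2] + theta$d1 * dy,
               base$vel[, 3])
  acc <- cbind(base$acc[, 1] + theta$d2 * dx - theta$d1^2 * rx,
               base$acc[, 2] + theta$d2 * dy - theta$d1^2 * ry,
               base$acc[, 3])
  list(pos = pos, vel = vel, acc = acc)
}

.point <- function(x, y, z) {
  list(pos = cbind(x$v, y$v, z$v),
       vel = cbind(x$d1, y$d1, z$d1),
       acc = cbind(x$d2, y$d2, z$d2))
}

# knee flexion profile: small loading-response bump plus large swing bump
.knee_curve <- function(u) {
  .curve_add(.windowed(u, 0.02, 0.55, .bump, 0.18),
             .windowed(u, 0.60, 0.98, .bump, 1.05))
}

#' Generate smooth periodic segment kinematics for a walking trial
#'
#' Builds planar (sagittal) pelvis, impaired thigh/shank and both-feet
#' trajectories with analytic velocities and accelerations. Feet are exactly
#' stationary during their stance and exactly flat (constant orientation) on
#' the foot-flat interval `[IC + r, TC - r]`; small out-of-plane foot wobble
#' and mediolateral excursions during swing exercise the 3D code paths.
#'
#' @param config a [synthetic_config()].
#' @return object of class `"SegmentPoseSeries"`: `time`, `rate`, per-segment
#'   `pos` (n x 3, m), `quat` (n x 4), analytic `vel`/`acc`, and a `truth`
#'   attribute with event times, phase intervals, joint angles and the foot
#'   sagittal pitch derivatives used by [truth_loads()].
#' @export
generate_segment_kinematics <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  T <- config$stride_period
  L <- config$stride_length
  d <- config$duty_factor
  r <- config$rotation_halfwidth
  s <- config$height / GENERIC_HEIGHT
  rate <- config$imu_rate
  n <- round(config$n_cycles * T * rate)
  t <- seq(0, length.out = n, by = 1 / rate)
  ut <- t / T
  u <- ut - floor(ut)

  theta_land <- 0.30; theta_push <- 0.45
  foot_lift <- 0.06 * s
  toe_off <- generic_anthropometry()$toe_offset * s

  make_foot <- function(u_foot, ut_foot, x0, z0) {
    k <- floor(ut_foot)
    adv <- .foot_advance_curve(u_foot, d, L)
    x <- list(v = x0 + k * L + adv$v, d1 = adv$d1 / T, d2 = adv$d2 / T^2)
    y <- .to_time(.windowed(u_foot, d, 1, .bump, foot_lift), T)
    y$v <- y$v + 0.05 * s
    z <- .to_time(.windowed(u_foot, d, 1, .bump, 0.012), T)
    z$v <- z$v + z0
    pitch <- .to_time(.foot_pitch_curve(u_foot, d, r, theta_land, theta_push), T)

    # push-off pivots about the planted toe: the origin (calcaneus CoM) rises
    # and advances while the toe point stays put until terminal contact; the
    # pivot offset fades out smoothly in early swing. The offset
    # fade * (v - R(pitch) v), v = toe offset, is C2 because the pitch has two
    # vanishing derivatives where the fade switches on.
    nfu <- length(u_foot)
    wf <- min(0.15, 0.8 * (1 - d - 2 * r))
    fade <- list(v = numeric(nfu), d1 = numeric(nfu), d2 = numeric(nfu))
    i <- u_foot >= d - r & u_foot <= d + r
    fade$v[i] <- 1
    i <- u_foot > d + r & u_foot <= d + r + wf
    gs <- .smoothstep((u_foot[i] - d - r) / wf)
    fade$v[i] <- 1 - gs$v; fade$d1[i] <- -gs$d1 / wf; fade$d2[i] <- -gs$d2 / wf^2
    fade <- .to_time(fade, T)
    th <- pitch$v; thd <- pitch$d1; thdd <- pitch$d2
    vx <- toe_off[1]; vy <- toe_off[2]
    Rx <- vx * cos(th) - vy * sin(th); Ry <- vx * sin(th) + vy * cos(th)
    dRx <- -vx * sin(th) - vy * cos(th); dRy <- vx * cos(th) - vy * sin(th)
    add_pivot <- function(comp, vc, Rc, dRc) {
      g <- vc - Rc                               # d2Rc/dtheta2 = -Rc
      g1 <- -thd * dRc
      g2 <- -thdd * dRc + thd^2 * Rc
      comp$v <- comp$v + fade$v * g
      comp$d1 <- comp$d1 + fade$d1 * g + fade$v * g1
      comp$d2 <- comp$d2 + fade$d2 * g + 2 * fade$d1 * g1 + fade$v * g2
      comp
    }
    x <- add_pivot(x, vx, Rx, dRx)
    y <- add_pivot(y, vy, Ry, dRy)
    # out-of-plane wobble spans push-off through landing (wrapping the cycle
    # boundary, zero with two vanishing derivatives on the foot-flat interval)
    # so the swing phase is never simultaneously quiet on all three gyro axes
    wobble <- function(amp) {
      w <- .curve_add(.windowed(u_foot, d - r, 1 + r, .bump, amp),
                      .windowed(u_foot + 1, d - r, 1 + r, .bump, amp))
      .to_time(w, T)
    }
    wobble_x <- wobble(0.03)
    wobble_y <- wobble(0.02)
    q <- quat_multiply(
      quat_multiply(quat_from_axis_angle(c(0, 0, 1), pitch$v),
                    quat_from_axis_angle(c(1, 0, 0), wobble_x$v)),
      quat_from_axis_angle(c(0, 1, 0), wobble_y$v))
    c(.point(x, y, z), list(quat = q, pitch = pitch))
  }

  z_imp <- 0.09 * s; z_contra <- -0.09 * s
  foot_imp <- make_foot(u, ut, 0, z_imp)
  ut_c <- ut + 0.5
  u_c <- ut_c - floor(ut_c)
  # contralateral IC at t = T/2 lands half a step (L/2) ahead of the impaired
  # foot; with k = floor(ut + 0.5) already 1 at that instant, x0 = -L/2
  foot_contra <- make_foot(u_c, ut_c, -0.5 * L, z_contra)

  # pelvis: advances at walking_speed with small periodic oscillations
  pel_x <- .curve_sin(ut, 2, 0.7, 0.012)
  pel_x$v <- pel_x$v + config$walking_speed * t
  pel_x$d1 <- pel_x$d1 / T + config$walking_speed
  pel_x$d2 <- pel_x$d2 / T^2
  pel_y <- .to_time(.curve_sin(ut, 2, 2.1, 0.02, 0.95 * s), T)
  pel_z <- .to_time(.curve_sin(ut, 1, 0.0, 0.02), T)
  pelvis <- .point(pel_x, pel_y, pel_z)
  theta_p <- .to_time(.curve_sin(ut, 2, 0.3, 0.04), T)
  pelvis$quat <- quat_from_axis_angle(c(0, 0, 1), theta_p$v)

  # impaired-leg chain: shank angle smooth periodic, knee profile sets thigh,
  # truth ankle angle is foot pitch minus shank angle
  theta_s <- .to_time(.curve_sin(ut, 1, 1.0, 0.30, 0.05), T)
  knee <- .to_time(.knee_curve(u), T)
  theta_t <- list(v = theta_s$v - knee$v, d1 = theta_s$d1 - knee$d1,
                  d2 = theta_s$d2 - knee$d2)

  hip <- .attach_point(pelvis, theta_p, c(0, -0.10, 0.09) * s)
  l_thigh <- 0.40 * s; l_shank <- 0.43 * s
  thigh <- .attach_point(hip, theta_t, c(0, -0.433 * l_thigh, 0))
  thigh$quat <- quat_from_axis_angle(c(0, 0, 1), theta_t$v)
  knee_pt <- .attach_point(hip, theta_t, c(0, -l_thigh, 0))
  shank <- .attach_point(knee_pt, theta_s, c(0, -0.433 * l_shank, 0))
  shank$quat <- quat_from_axis_angle(c(0, 0, 1), theta_s$v)

  ankle_angle <- foot_imp$pitch$v - theta_s$v
  knee_angle <- knee$v

  # event lattice, including events of the partial contralateral stance that
  # starts before t = 0; intervals are clipped to the trial
  dur <- config$n_cycles * T
  cyc <- seq(-1L, config$n_cycles)
  in_trial <- function(x) x[x >= 0 & x < dur]
  clip <- function(a, b) {
    keep <- b > 0 & a < dur
    cbind(start = pmax(a[keep], 0), end = pmin(b[keep], dur))
  }
  events <- list(
    ic_imp = in_trial(cyc * T),
    tc_imp = in_trial((cyc + d) * T),
    ic_contra = in_trial((cyc + 0.5) * T),
    tc_contra = in_trial((cyc + 0.5 + d) * T),
    ff_imp = clip((cyc + r) * T, (cyc + d - r) * T),
    ff_contra = clip((cyc + 0.5 + r) * T, (cyc + 0.5 + d - r) * T),
    stance_imp = clip(cyc * T, (cyc + d) * T),
    stance_contra = clip((cyc + 0.5) * T, (cyc + 0.5 + d) * T)
  )

  segments <- list(
    pelvis = pelvis[c("pos", "vel", "acc", "quat")],
    thigh = thigh[c("pos", "vel", "acc", "quat")],
    shank = shank[c("pos", "vel", "acc", "quat")],
    foot_imp = foot_imp[c("pos", "vel", "acc", "quat")],
    foot_contra = foot_contra[c("pos", "vel", "acc", "quat")]
  )
  structure(
    list(time = t, rate = rate, segments = segments, config = config,
         truth = list(events = events, phase = u,
                      knee_angle = knee_angle, ankle_angle = ankle_angle,
                      foot_pitch_imp = foot_imp$pitch)),
    class = "SegmentPoseSeries")
}

#' Generate a static (quiet standing) trial
#'
#' All segments at the model default pose (identity orientation in the model
#' frame), zero motion. Used for sensor-to-segment registration.
#'
#' @param config a [synthetic_config()].
#' @param duration trial duration, s.
#' @param pose optional named list of static joint angles (rad):
#'   `knee`, `ankle` deviations from the default pose.
#' @return `"SegmentPoseSeries"` object.
#' @export
generate_static_trial <- function(config, duration = 10, pose = list()) {
  rate <- config$imu_rate
  n <- round(duration * rate)
  t <- seq(0, length.out = n, by = 1 / rate)
  s <- config$height / GENERIC_HEIGHT
  knee0 <- if (is.null(pose$knee)) 0 else pose$knee
  ankle0 <- if (is.null(pose$ankle)) 0 else pose$ankle
  zero3 <- matrix(0, n, 3)
  seg <- function(x, y, z, angle) {
    list(pos = cbind(rep(x, n), rep(y, n), rep(z, n)), vel = zero3, acc = zero3,
         quat = quat_from_axis_angle(c(0, 0, 1), rep(angle, n)))
  }
  thigh_a <- -knee0         # knee = shank angle - thigh angle, shank upright
  foot_a <- ankle0          # ankle = foot pitch - shank angle
  segments <- list(
    pelvis = seg(0, 0.95 * s, 0, 0),
    thigh = seg(0, 0.68 * s, 0.09 * s, thigh_a),
    shank = seg(0, 0.32 * s, 0.09 * s, 0),
    foot_imp = seg(0.05, 0.05 * s, 0.09 * s, foot_a),
    foot_contra = seg(0.05, 0.05 * s, -0.09 * s, 0)
  )
  structure(list(time = t, rate = rate, segments = segments, config = config,
                 truth = list(static = TRUE, knee = knee0, ankle = ankle0)),
            class = "SegmentPoseSeries")
}

#' Derive inertial sensor signals from segment kinematics
#'
#' For each of the five sensors: orientation is the segment orientation
#' (expressed in the sensor-convention global frame, z up) composed with the
#' fixed mount offset; the accelerometer reads the specific force (segment
#' acceleration minus gravity) in the sensor frame; the gyroscope reads the
#' body-frame angular velocity obtained by quaternion differentiation.
#' Gaussian noise with the configured standard deviations is added, seeded.
#'
#' @param poses a `"SegmentPoseSeries"`.
#' @param config a [synthetic_config()]; noise and mount offsets are read
#'   from here.
#' @return object of class `"ImuTrial"`: `time`, `rate`, and per-sensor
#'   `quat` (n x 4), `acc` (n x 3, m/s^2, sensor frame, includes gravity
#'   reaction), `gyro` (n x 3, rad/s, sensor frame).
#' @export
derive_imu_signals <- function(poses, config = poses$config) {
  stopifnot(inherits(poses, "SegmentPoseSeries"))
  dt <- diff(poses$time)
  if (max(abs(dt - dt[1])) > 1e-9) stop("pose series must be uniformly sampled")
  set.seed(config$rng_seed + 17L)
  g <- GRAVITY
  qrm_inv <- quat_conjugate(MODEL_FRAME_QUAT)
  sensors <- lapply(names(poses$segments), function(nm) {
    seg <- poses$segments[[nm]]
    mount <- config$mount_offsets[[nm]]
    if (is.null(mount)) mount <- quat(1)
    q_sensor <- quat_multiply(quat_multiply(qrm_inv, seg$quat), mount)
    f_model <- sweep(seg$acc, 2, g)               # specific force, model frame
    f_global <- quat_rotate(qrm_inv, f_model)
    acc_local <- quat_rotate(quat_conjugate(q_sensor), f_global)
    gyro <- quat_angular_velocity(q_sensor, poses$rate)
    n <- nrow(acc_local)
    if (config$imu_noise_sd_acc > 0)
      acc_local <- acc_local + matrix(stats::rnorm(3 * n, 0, config$imu_noise_sd_acc), n, 3)
    if (config$imu_noise_sd_gyro > 0)
      gyro <- gyro + matrix(stats::rnorm(3 * n, 0, config$imu_noise_sd_gyro), n, 3)
    list(quat = q_sensor, acc = acc_local, gyro = gyro)
  })
  names(sensors) <- names(poses$segments)
  structure(list(time = poses$time, rate = poses$rate, sensors = sensors,
                 labels = stats::setNames(names(poses$segments), names(poses$segments))),
            class = "ImuTrial")
}

#' Generate a 64-channel synthetic EMG recording
#'
#' Each grid channel assigned to a muscle carries that muscle's gait-phase-
#' locked activation envelope amplitude-modulating zero-mean band-limited
#' (20-450 Hz) noise; channels labelled `"noisy"` additionally carry large
#' low-frequency movement artifacts. Seeded and deterministic.
#'
#' @param config a [synthetic_config()].
#' @param events ground-truth event list (needs `ic_imp`) or a `GroundTruth`
#'   object from [truth_loads()]; sets the phase locking.
#' @return object of class `"EmgRecording"`: `time`, `rate`, `signals`
#'   (n x 64 matrix), `channel_map`, `gain` (23, as applied by the front-end),
#'   and the generating `envelopes` (n x 7, the oracle for envelope recovery).
#' @export
generate_emg <- function(config, events) {
  if (inherits(events, "GroundTruth")) events <- events$events
  if (length(config$channel_map) != 64)
    stop("channel_map must cover 64 channels")
  T <- config$stride_period
  dur <- config$n_cycles * T
  rate <- config$emg_rate
  n <- round(dur * rate)
  t <- seq(0, length.out = n, by = 1 / rate)
  u <- (t - events$ic_imp[1]) / T
  u <- u - floor(u)
  set.seed(config$rng_seed + 29L)
  env <- sapply(MUSCLES, function(m) eval_profile(config$envelope_profiles[[m]], u))
  bandnoise <- function() {
    x <- stats::rnorm(n)
    x <- butterworth_zero_lag(x, rate = rate, cutoff = 20, kind = "high")
    x <- butterworth_zero_lag(x, rate = rate, cutoff = 450, kind = "low")
    x / stats::sd(x)
  }
  lownoise <- function() {
    x <- butterworth_zero_lag(stats::rnorm(n), rate = rate, cutoff = 3, kind = "low")
    x / stats::sd(x)
  }
  amp <- 0.2e-3  # V, typical surface EMG scale before amplification
  sig <- matrix(0, n, 64)
  for (ch in seq_len(64)) {
    lab <- config$channel_map[ch]
    if (lab == "noisy") {
      sig[, ch] <- 50 * amp * lownoise() + amp * bandnoise()
    } else {
      sig[, ch] <- amp * env[, lab] * bandnoise()
    }
  }
  structure(list(time = t, rate = rate, signals = sig,
                 channel_map = config$channel_map, gain = 23,
                 envelopes = env),
            class = "EmgRecording")
}

# smooth load share of the impaired foot at cycle phase u (cosine STA ramp)
.truth_share_imp <- function(u, d, transition = sta_cosine) {
  ds <- d - 0.5
  share <- numeric(length(u))
  i1 <- u < ds                      # double stance 1, impaired leading
  share[i1] <- 1 - transition(u[i1] / ds)
  i2 <- u >= ds & u < 0.5           # impaired single stance
  share[i2] <- 1
  i3 <- u >= 0.5 & u < d            # double stance 2, impaired trailing
  share[i3] <- transition((u[i3] - 0.5) / ds)
  share                             # swing: 0
}

#' Ground-truth loads, centre of pressure and ankle torque
#'
#' Computes the total ground reaction force by direct Newton summation of the
#' analytic segment accelerations, splits it between feet with the smooth
#' cosine load-sharing function evaluated at the *true* phase (exclusive
#' single-leg support, zero force throughout swing), lays the centre of
#' pressure along the prescribed heel -> calcaneus CoM -> toe roll-over, and
#' evaluates the sagittal ankle torque from the closed-form planar free-body
#' of the impaired foot.
#'
#' @param poses `"SegmentPoseSeries"` from [generate_segment_kinematics()].
#' @param body a [scale_body_model()] result (defaults to the configured
#'   height/mass).
#' @param config a [synthetic_config()].
#' @return object of class `"GroundTruth"`.
#' @export
truth_loads <- function(poses, body = NULL,
                        config = poses$config) {
  stopifnot(inherits(poses, "SegmentPoseSeries"))
  if (is.null(body)) body <- scale_body_model(config$height, config$mass)
  t <- poses$time
  u <- poses$truth$phase
  d <- config$duty_factor
  g <- GRAVITY
  segs <- poses$segments
  masses <- c(pelvis = body$masses[["pelvis_lump"]], thigh = body$masses[["thigh"]],
              shank = body$masses[["shank"]], foot_imp = body$masses[["foot"]],
              foot_contra = body$masses[["foot"]])
  total <- Reduce(`+`, lapply(names(segs), function(nm) {
    masses[[nm]] * sweep(segs[[nm]]$acc, 2, g)
  }))
  share_imp <- .truth_share_imp(u, d)
  u_c <- u + 0.5; u_c <- u_c - floor(u_c)
  grf_imp <- total * share_imp
  grf_contra <- total - grf_imp

  # CoP: heel -> calcaneus CoM over [IC, TC_contra], calc -> toe over
  # [TC_contra, TC]; true-phase interpolation, vertical coordinate zero
  cop_foot <- function(uf, seg) {
    heel <- quat_rotate(seg$quat, body$heel_offset) + seg$pos
    calc <- quat_rotate(seg$quat, body$foot_com_offset) + seg$pos
    toe <- quat_rotate(seg$quat, body$toe_offset) + seg$pos
    cop <- matrix(NA_real_, length(uf), 3)
    ds <- d - 0.5
    p1 <- uf < ds
    a <- uf[p1] / ds
    cop[p1, ] <- (1 - a) * heel[p1, , drop = FALSE] + a * calc[p1, , drop = FALSE]
    p2 <- uf >= ds & uf < d
    b <- (uf[p2] - ds) / (d - ds)
    cop[p2, ] <- (1 - b) * calc[p2, , drop = FALSE] + b * toe[p2, , drop = FALSE]
    cop[, 2] <- ifelse(is.na(cop[, 1]), NA_real_, 0)
    cop
  }
  cop_imp <- cop_foot(u, segs$foot_imp)
  cop_contra <- cop_foot(u_c, segs$foot_contra)

  # planar ankle free-body of the impaired foot (closed form)
  foot <- segs$foot_imp
  p_ankle <- quat_rotate(foot$quat, body$ankle_offset) + foot$pos
  p_com <- quat_rotate(foot$quat, body$foot_com_offset) + foot$pos
  a_com <- foot$acc
  alpha <- poses$truth$foot_pitch_imp$d2
  mz <- function(a, b) a[, 1] * b[, 2] - a[, 2] * b[, 1]
  fgrav_term <- mz(p_com - p_ankle, body$masses[["foot"]] * sweep(a_com, 2, g))
  grf_term <- mz(cop_imp - p_ankle, grf_imp)
  grf_term[is.na(grf_term)] <- 0
  torque <- body$foot_inertia_zz * alpha + fgrav_term - grf_term

  act <- sapply(MUSCLES, function(m) eval_profile(config$envelope_profiles[[m]], u))
  structure(list(
    time = t, phase = u, events = poses$truth$events,
    grf = list(total = total, imp = grf_imp, contra = grf_contra),
    cop = list(imp = cop_imp, contra = cop_contra),
    knee_angle = poses$truth$knee_angle,
    ankle_angle = poses$truth$ankle_angle,
    ankle_torque = torque,
    ankle_torque_per_kg = torque / body$mass,
    activations = act, body = body
  ), class = "GroundTruth")
}
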