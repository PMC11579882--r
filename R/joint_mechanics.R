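#' Joint kinematics and dynamics
#'
#' Static sensor-to-segment registration, sagittal knee and ankle angles from
#' relative sensor orientations, planar ankle inverse dynamics on the foot
#' free body, gait-cycle time normalisation, and the R^2 / RMSE agreement
#' metrics used to compare estimated and reference curves.
#'
#' The full weighted-least-squares orientation inverse kinematics of
#' lab-grade tooling reduces, for a sagittal chain with one sensor per
#' segment, to direct relative-orientation decomposition; that equivalent is
#' what is implemented here.
#'
#' @name joint_mechanics
NULL

#' Register sensors to segments from a static pose
#'
#' The mean sensor orientation over a quiet-standing trial is compared with
#' each segment's known default-pose orientation; the fixed rotation between
#' them is the sensor-to-segment registration applied to all subsequent
#' trials. The participant is assumed to hold the model's neutral pose: any
#' systematic deviation (e.g. a flexed knee, common post-stroke) biases the
#' downstream joint angles by exactly that deviation.
#'
#' @param static_trial an `"ImuTrial"` of a quiet standing pose (>= 2 s).
#' @param default_pose named list of default-pose segment angles (rad) in
#'   the model frame; default all zero (neutral upright).
#' @param max_gyro_rms motion threshold, rad/s; the trial is rejected above.
#' @return object of class `"SensorRegistration"`: per-sensor registration
#'   quaternions and the rotation angle (rad) of each.
#' @export
register_sensors_static <- function(static_trial, default_pose = NULL,
                                    max_gyro_rms = 0.2) {
  stopifnot(inherits(static_trial, "ImuTrial"))
  if (utils::tail(static_trial$time, 1) - static_trial$time[1] < 2)
    stop("static trial must be at least 2 s long")
  qrm_inv <- quat_conjugate(MODEL_FRAME_QUAT)
  regs <- lapply(names(static_trial$sensors), function(nm) {
    s <- static_trial$sensors[[nm]]
    rms <- sqrt(mean(s$gyro^2))
    if (rms > max_gyro_rms)
      stop("static trial rejected: sensor '", nm, "' gyro RMS ",
           signif(rms, 3), " rad/s exceeds ", max_gyro_rms)
    q_static <- quat_mean(s$quat)
    ang <- if (!is.null(default_pose[[nm]])) default_pose[[nm]] else 0
    q_default_global <- quat_multiply(qrm_inv, quat_from_axis_angle(c(0, 0, 1), ang))
    quat_multiply(quat_conjugate(q_static), q_default_global)
  })
  names(regs) <- names(static_trial$sensors)
  angles <- vapply(regs, function(q) 2 * acos(pmin(1, abs(q[1, 1]))), 0)
  structure(list(rotations = regs, angles = angles),
            class = "SensorRegistration")
}

#' Apply a registration to sensor orientations
#'
#' @param trial an `"ImuTrial"`.
#' @param reg a `"SensorRegistration"`.
#' @return named list of n x 4 segment orientation quaternions expressed in
#'   the model frame.
#' @export
registered_orientations <- function(trial, reg) {
  out <- lapply(names(trial$sensors), function(nm) {
    q <- quat_multiply(trial$sensors[[nm]]$quat, reg$rotations[[nm]])
    quat_multiply(MODEL_FRAME_QUAT, q)
  })
  names(out) <- names(trial$sensors)
  out
}

#' Sagittal knee and ankle angles from registered orientations
#'
#' Knee flexion (positive) is the sagittal (z-twist) component of the thigh
#' to shank relative rotation; ankle dorsiflexion (positive) the sagittal
#' component of shank to foot, minus the static-pose offset.
#'
#' @param trial an `"ImuTrial"` with thigh, shank and impaired-foot sensors.
#' @param reg a `"SensorRegistration"`.
#' @param static_offsets named list (`knee`, `ankle`) of static-pose joint
#'   angles to subtract, rad; default zero.
#' @return object of class `"JointAngleSeries"`: `time`, `knee`, `ankle`
#'   (rad).
#' @export
joint_angles <- function(trial, reg, static_offsets = list(knee = 0, ankle = 0)) {
  need <- c("thigh", "shank", "foot_imp")
  missing <- setdiff(need, names(trial$sensors))
  if (length(missing))
    stop("missing sensor stream(s): ", paste(missing, collapse = ", "))
  q <- registered_orientations(trial, reg)
  knee <- quat_twist_z(quat_multiply(quat_conjugate(q$thigh), q$shank)) -
    static_offsets$knee
  ankle <- quat_twist_z(quat_multiply(quat_conjugate(q$shank), q$foot_imp)) -
    static_offsets$ankle
  structure(list(time = trial$time, rate = trial$rate, knee = knee, ankle = ankle),
            class = "JointAngleSeries")
}

# first derivative by central differences
.ddt <- function(x, rate) {
  n <- length(x)
  d <- x
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  d
}

#' Planar ankle inverse dynamics (foot free body)
#'
#' Sagittal ankle torque from the impaired foot's free body:
#' `tau = I_f alpha_f + [(p_com - p_ankle) x m_f (a_com - g)]_z
#'       - [(p_cop - p_ankle) x F_grf]_z`.
#' The foot angular acceleration is obtained by twice differentiating the
#' sagittal foot orientation, each stage low-pass filtered at `filter_hz`
#' with the zero-lag Butterworth operator. During swing the external force
#' is zero and the CoP undefined, so the GRF moment vanishes.
#'
#' @param foot_pos,foot_quat n x 3 positions and n x 4 orientations of the
#'   foot origin (calcaneus CoM), model frame.
#' @param foot_acc n x 3 foot accelerations in the model frame,
#'   accelerometer convention (gravity reaction included), i.e. the output
#'   of [to_model_frame()]; `m_f (a - g)` is then `m_f` times this reading.
#' @param grf n x 3 impaired-side GRF, N.
#' @param cop n x 3 impaired-side CoP (NA during swing).
#' @param body a `"BodyModel"`.
#' @param rate sampling rate, Hz.
#' @param filter_hz corner for the orientation differentiation, Hz.
#' @return object of class `"TorqueSeries"`: `time` implied by rate, `nm`
#'   (N m), `nm_per_kg`, `provenance = "ID-IMU"`.
#' @export
ankle_inverse_dynamics <- function(foot_pos, foot_quat, foot_acc, grf, cop,
                                   body, rate, filter_hz = 3) {
  n <- nrow(foot_pos)
  if (nrow(grf) != n || nrow(cop) != n || nrow(foot_acc) != n)
    stop("misaligned series: kinematics and loads must share the time base")
  theta <- quat_twist_z(foot_quat)
  theta <- .unwrap(theta)
  omega <- butterworth_zero_lag(.ddt(theta, rate), rate, filter_hz, "low")
  alpha <- butterworth_zero_lag(.ddt(omega, rate), rate, filter_hz, "low")
  p_ankle <- quat_rotate(foot_quat, body$ankle_offset) + foot_pos
  p_com <- quat_rotate(foot_quat, body$foot_com_offset) + foot_pos
  mz <- function(a, b) a[, 1] * b[, 2] - a[, 2] * b[, 1]
  grav_term <- mz(p_com - p_ankle, body$masses[["foot"]] * foot_acc)
  grf_term <- mz(cop - p_ankle, grf)
  grf_term[is.na(grf_term)] <- 0
  tau <- body$foot_inertia_zz * alpha + grav_term - grf_term
  torque_series(tau, rate, body$mass, provenance = "ID-IMU")
}

.unwrap <- function(theta) {
  d <- diff(theta)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  theta - 2 * pi * jumps
}

#' Construct a torque series
#'
#' @param nm torque, N m.
#' @param rate sampling rate, Hz.
#' @param mass body mass, kg (for the mass-normalised representation).
#' @param provenance one of `"ID-reference"`, `"ID-IMU"`, `"EMG-driven"`,
#'   `"truth"`.
#' @return `"TorqueSeries"` object.
#' @export
torque_series <- function(nm, rate, mass, provenance = "ID-IMU") {
  structure(list(time = (seq_along(nm) - 1) / rate, rate = rate,
                 nm = nm, nm_per_kg = nm / mass, mass = mass,
                 provenance = provenance),
            class = "TorqueSeries")
}

#' Time-normalise a series over gait cycles
#'
#' Each impaired IC-to-IC cycle is linearly resampled to `npoints` points
#' (0-100 % of the cycle); the ensemble mean and standard deviation across
#' cycles are returned with the per-cycle matrix.
#'
#' @param x numeric vector, one sample per time step.
#' @param phases a `"GaitPhaseTable"`.
#' @param npoints points per normalised cycle (101 = every 1 %).
#' @return list with `cycles` (n_cycles x npoints matrix), `mean`, `sd`,
#'   and `pct` (0..100).
#' @export
normalize_cycles <- function(x, phases, npoints = 101) {
  if (nrow(phases) < 1) stop("no complete cycles")
  mat <- t(apply(phases, 1, function(p) {
    idx <- p[["ic_imp"]]:p[["ic_next"]]
    stats::approx(seq(0, 1, length.out = length(idx)), x[idx],
                  xout = seq(0, 1, length.out = npoints))$y
  }))
  list(cycles = mat, mean = colMeans(mat),
       sd = apply(mat, 2, stats::sd),
       pct = seq(0, 100, length.out = npoints))
}

#' Agreement metrics between a reference and an estimate
#'
#' R^2 is the squared Pearson correlation (shape similarity — invariant to
#' positive affine transforms of either series); RMSE is the root mean
#' squared difference (amplitude similarity). An SSE-based coefficient of
#' determination `1 - SSE/SST` is available via `variant`.
#'
#' @param reference,estimate equal-length numeric vectors (>= 3 finite
#'   values).
#' @param mass optional body mass, kg: adds `rmse_per_kg`.
#' @param variant `"pearson"` (default) or `"sse"`.
#' @return list with `r2`, `rmse` (and `rmse_per_kg` if `mass` given). `r2`
#'   is NA with a warning when either input has zero variance.
#' @export
agreement_metrics <- function(reference, estimate, mass = NULL,
                              variant = c("pearson", "sse")) {
  variant <- match.arg(variant)
  keep <- is.finite(reference) & is.finite(estimate)
  reference <- reference[keep]; estimate <- estimate[keep]
  if (length(reference) < 3) stop("need at least 3 finite paired samples")
  rmse <- sqrt(mean((reference - estimate)^2))
  if (stats::sd(reference) == 0 || stats::sd(estimate) == 0) {
    warning("zero-variance input: R^2 undefined")
    r2 <- NA_real_
  } else if (variant == "pearson") {
    r2 <- stats::cor(reference, estimate)^2
  } else {
    r2 <- 1 - sum((reference - estimate)^2) / sum((reference - mean(reference))^2)
  }
  out <- list(r2 = r2, rmse = rmse)
  if (!is.null(mass)) out$rmse_per_kg <- rmse / mass
  out
}
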