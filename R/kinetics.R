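#' Whole-body kinetics from wearable sensors
#'
#' Scaling of the generic body model, transformation of sensor accelerations
#' into the model frame, Newton estimation of the total ground reaction
#' force, the smooth-transition-assumption (STA) split between feet, foot
#' landmark point kinematics, and the heel-to-toe centre-of-pressure
#' progression model.
#'
#' Model frame: x anterior, y vertical (up), z to the participant's right;
#' gravity is (0, -9.81, 0) m/s^2. The sensor-convention global frame has z
#' up; the fixed transform between the two is a -90 degree rotation about x,
#' mapping (x, y, z) to (x, z, -y).
#'
#' @name kinetics
NULL

#' Scale the generic body model to a participant
#'
#' A single manual scale factor `s = height / 1.68` (the generic model is
#' 1.68 m tall) is applied to segment lengths and foot landmark offsets;
#' segment masses are generic mass fractions times the participant's mass.
#' The pelvis lump carries the mass of the entire body except the impaired
#' thigh, shank and foot and the contralateral foot. Foot inertia scales
#' with mass and the square of the length scale.
#'
#' @param height participant height, m.
#' @param mass participant mass, kg.
#' @param anthropometry generic table, see [generic_anthropometry()].
#' @return object of class `"BodyModel"`: `scale`, `masses` (kg, incl.
#'   `pelvis_lump`), `lengths` (m), scaled `heel_offset`/`toe_offset`/
#'   `foot_com_offset`/`ankle_offset` (m), `foot_inertia_zz` (kg m^2).
#' @export
scale_body_model <- function(height, mass, anthropometry = generic_anthropometry()) {
  if (height <= 0 || mass <= 0) stop("height and mass must be positive")
  a <- anthropometry
  s <- height / a$generic_height
  mf <- a$mass_fractions
  m_thigh <- mf[["thigh"]] * mass
  m_shank <- mf[["shank"]] * mass
  m_foot <- mf[["foot"]] * mass
  m_pelvis <- mass - (m_thigh + m_shank + m_foot) - m_foot
  masses <- c(pelvis_lump = m_pelvis, thigh = m_thigh, shank = m_shank,
              foot = m_foot)
  structure(list(
    height = height, mass = mass, scale = s,
    masses = masses,
    lengths = a$lengths * s,
    heel_offset = a$heel_offset * s,
    toe_offset = a$toe_offset * s,
    foot_com_offset = a$foot_com_offset * s,
    ankle_offset = a$ankle_offset * s,
    foot_inertia_zz = a$foot_inertia_zz * (mass / a$generic_mass) * s^2
  ), class = "BodyModel")
}

#' Rotate sensor-local accelerations into the model frame
#'
#' `a_model = R_model * R(q) * a_local`: the sensor orientation quaternion
#' takes the local reading to the sensor-convention global frame, then the
#' fixed -90 degree x-rotation maps the global frame onto the model frame.
#' The output keeps the accelerometer convention (gravity reaction included):
#' a sensor at rest yields (0, +9.81, 0).
#'
#' @param local_acc n x 3 sensor-local accelerations, m/s^2.
#' @param orientation n x 4 unit quaternions (sensor to global).
#' @param tol maximum allowed deviation of quaternion norms from 1.
#' @return n x 3 accelerations in the model frame.
#' @export
to_model_frame <- function(local_acc, orientation, tol = 1e-3) {
  orientation <- as_quat_matrix(orientation)
  bad <- abs(quat_norm(orientation) - 1) > tol
  if (any(bad))
    stop("non-unit quaternion(s) at sample(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  orientation <- quat_normalize(orientation)
  a_global <- quat_rotate(orientation, local_acc)
  a_global %*% t(MODEL_FRAME_ROTATION)
}

#' Total ground reaction force by Newton summation
#'
#' `F_total = sum_i m_i (a_i - g)` over the five instrumented segments
#' (pelvis lump, impaired thigh, shank, foot, contralateral foot), assuming
#' the feet are the only ground contact. With accelerometer-convention
#' inputs (gravity reaction included, the default) the subtraction of g has
#' already happened inside the sensor, so the masses multiply the readings
#' directly; set `includes_gravity = FALSE` for true segment accelerations.
#'
#' @param model_acc named list of n x 3 model-frame acceleration series, one
#'   per segment: `pelvis`, `thigh`, `shank`, `foot_imp`, `foot_contra`.
#' @param body a `"BodyModel"`.
#' @param includes_gravity whether `model_acc` already contains the gravity
#'   reaction (accelerometer convention).
#' @return n x 3 total GRF, N, model frame.
#' @export
total_grf <- function(model_acc, body, includes_gravity = TRUE) {
  missing <- setdiff(SEGMENTS, names(model_acc))
  if (length(missing))
    stop("missing segment acceleration stream(s): ", paste(missing, collapse = ", "))
  masses <- c(pelvis = body$masses[["pelvis_lump"]], thigh = body$masses[["thigh"]],
              shank = body$masses[["shank"]], foot_imp = body$masses[["foot"]],
              foot_contra = body$masses[["foot"]])
  Reduce(`+`, lapply(SEGMENTS, function(nm) {
    a <- model_acc[[nm]]
    if (!includes_gravity) a <- sweep(a, 2, GRAVITY)
    masses[[nm]] * a
  }))
}

#' Cosine smooth-transition ramp
#'
#' Default STA share function for the trailing foot during double support:
#' `s(tau) = (1 + cos(pi tau)) / 2`, smooth with `s(0) = 1` (continuity with
#' the single-stance load) and `s(1) = 0` (zero at the trailing foot's
#' terminal contact). The component-specific shapes of the literature can be
#' injected in its place.
#'
#' @param tau elapsed fraction of the double-support interval, in [0, 1].
#' @export
sta_cosine <- function(tau) (1 + cos(pi * tau)) / 2

#' Split the total GRF between feet (smooth transition assumption)
#'
#' During single stance the stance foot takes the whole load and the other
#' foot none; during double support the trailing foot's share falls from its
#' single-stance value to exactly zero at its terminal contact along the
#' `transition` ramp, and the leading foot takes the remainder, so the two
#' sides sum to the total exactly at every sample.
#'
#' @param total n x 3 total GRF series.
#' @param phases a `"GaitPhaseTable"` covering the series.
#' @param transition share function on [0, 1]; default [sta_cosine()].
#' @return object of class `"ExternalLoadSeries"` (without CoP): list with
#'   `total`, `imp`, `contra` (n x 3, N) and the impaired-side `share`
#'   vector; samples outside complete cycles are NA.
#' @export
split_grf_sta <- function(total, phases, transition = sta_cosine) {
  n <- nrow(total)
  if (max(phases$ic_next) > n)
    stop("phase table extends beyond the series")
  share <- rep(NA_real_, n)
  for (j in seq_len(nrow(phases))) {
    p <- phases[j, ]
    i1 <- p$ic_imp:(p$tc_contra - 1L)       # double stance 1: contra trailing
    share[i1] <- 1 - transition((i1 - p$ic_imp) / (p$tc_contra - p$ic_imp))
    i2 <- p$tc_contra:(p$ic_contra - 1L)    # impaired single stance
    share[i2] <- 1
    i3 <- p$ic_contra:(p$tc_imp - 1L)       # double stance 2: impaired trailing
    share[i3] <- transition((i3 - p$ic_contra) / (p$tc_imp - p$ic_contra))
    i4 <- p$tc_imp:(p$ic_next - 1L)         # impaired swing
    share[i4] <- 0
  }
  imp <- total * share
  structure(list(total = total, imp = imp, contra = total - imp, share = share),
            class = "ExternalLoadSeries")
}

#' Foot landmark trajectories (point kinematics)
#'
#' Global positions of the heel, calcaneus centre of mass and toe points:
#' `p(t) = p_foot(t) + R(q_foot(t)) * offset_scaled`.
#'
#' @param foot_pos n x 3 foot origin (calcaneus CoM) positions, model frame.
#' @param foot_quat n x 4 foot orientation quaternions, model frame.
#' @param body a `"BodyModel"` (provides the scaled offsets).
#' @return list of n x 3 matrices: `heel`, `calc`, `toe`.
#' @export
landmark_trajectories <- function(foot_pos, foot_quat, body) {
  foot_quat <- as_quat_matrix(foot_quat)
  n <- nrow(foot_pos)
  if (nrow(foot_quat) == 1L && n > 1L)
    foot_quat <- foot_quat[rep(1L, n), , drop = FALSE]
  list(heel = quat_rotate(foot_quat, body$heel_offset) + foot_pos,
       calc = quat_rotate(foot_quat, body$foot_com_offset) + foot_pos,
       toe = quat_rotate(foot_quat, body$toe_offset) + foot_pos)
}

#' Centre-of-pressure progression along the foot
#'
#' Within each stance the CoP starts at the heel point at IC, travels
#' linearly (in elapsed-time fraction) to the calcaneus CoM reached at the
#' contralateral TC, then from the calcaneus CoM to the toe point reached at
#' the foot's own TC. The vertical coordinate is set to zero; swing samples
#' are NA (the foot bears no load).
#'
#' @param stances data.frame with one row per stance: `ic`, `tc_other`
#'   (the contralateral TC inside the stance) and `tc` sample indices.
#' @param landmarks list from [landmark_trajectories()] for this foot.
#' @param n total series length.
#' @return n x 3 CoP matrix (model frame, y = 0 during stance, NA in swing).
#' @export
estimate_cop <- function(stances, landmarks, n) {
  cop <- matrix(NA_real_, n, 3)
  if (nrow(stances) == 0) stop("no stance with an interior contralateral TC")
  for (j in seq_len(nrow(stances))) {
    p <- stances[j, ]
    i1 <- p$ic:p$tc_other
    a <- (i1 - p$ic) / (p$tc_other - p$ic)
    cop[i1, ] <- (1 - a) * landmarks$heel[i1, , drop = FALSE] +
      a * landmarks$calc[i1, , drop = FALSE]
    i2 <- p$tc_other:p$tc
    b <- (i2 - p$tc_other) / (p$tc - p$tc_other)
    cop[i2, ] <- (1 - b) * landmarks$calc[i2, , drop = FALSE] +
      b * landmarks$toe[i2, , drop = FALSE]
  }
  cop[, 2] <- ifelse(is.na(cop[, 1]), NA_real_, 0)
  cop
}

#' Stance intervals with interior contralateral TC, for both feet
#'
#' Builds the per-foot stance tables consumed by [estimate_cop()] from a
#' phase table. Impaired stances run `ic_imp -> tc_imp` with `tc_contra`
#' interior; contralateral stances run `ic_contra -> tc_contra` (of the next
#' cycle) with `tc_imp`... strictly, with the impaired TC of the same cycle
#' interior. Stances lacking an interior contralateral TC are skipped with a
#' warning.
#'
#' @param phases a `"GaitPhaseTable"`.
#' @return list with data.frames `imp` and `contra` (columns `ic`,
#'   `tc_other`, `tc`).
#' @export
stance_tables <- function(phases) {
  imp <- data.frame(ic = phases$ic_imp, tc_other = phases$tc_contra,
                    tc = phases$tc_imp)
  contra <- NULL
  if (nrow(phases) >= 2) {
    contra <- data.frame(
      ic = phases$ic_contra[-nrow(phases)],
      tc_other = phases$tc_imp[-nrow(phases)],
      tc = phases$tc_contra[-1])
  } else {
    warning("fewer than two cycles: no complete contralateral stance")
    contra <- data.frame(ic = integer(), tc_other = integer(), tc = integer())
  }
  list(imp = imp, contra = contra)
}
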