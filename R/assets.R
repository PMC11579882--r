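#' Built-in model assets
#'
#' Generic anthropometry and muscle-tendon geometry shipped as in-code,
#' user-overridable defaults. Values mirror the gait2392-style generic
#' musculoskeletal model (1.68 m, 75.16 kg) and standard anthropometric
#' tables; they are generic defaults, not measured data.
#'
#' @name assets
NULL

GRAVITY <- c(0, -9.81, 0)                 # model frame, m/s^2
GENERIC_HEIGHT <- 1.68                    # m, height of the generic model

# fixed rotation global (IMU convention, z up) -> model frame (y up):
# a -90 deg rotation about x, mapping (x, y, z) -> (x, z, -y)
MODEL_FRAME_ROTATION <- matrix(c(
  1, 0, 0,
  0, 0, 1,
  0, -1, 0
), nrow = 3, byrow = TRUE)

MODEL_FRAME_QUAT <- matrix(c(cos(-pi / 4), sin(-pi / 4), 0, 0), nrow = 1,
                           dimnames = list(NULL, c("w", "x", "y", "z")))

SEGMENTS <- c("pelvis", "thigh", "shank", "foot_imp", "foot_contra")

MUSCLES <- c("tib_ant", "ext_hal_long", "med_gas", "lat_gas",
             "soleus", "per_brev", "per_long")

#' Generic anthropometry table
#'
#' Segment mass fractions, lengths at generic height, foot landmark offsets
#' relative to the calcaneus centre of mass, ankle joint-centre offset, and
#' foot sagittal inertia for the generic 1.68 m / 75.16 kg model. The
#' pelvis-lump entry is the remainder of the body (all mass except the
#' impaired leg and both feet's... strictly: except impaired thigh, shank,
#' foot and the contralateral foot), computed at scale time.
#'
#' @return named list, all values overridable via [scale_body_model()].
#' @export
generic_anthropometry <- function() {
  list(
    generic_height = GENERIC_HEIGHT,
    generic_mass = 75.16,
    # mass fractions of total body mass (gait2392-style)
    mass_fractions = c(thigh = 9.3014 / 75.16,
                       shank = 3.7075 / 75.16,
                       foot = 1.5666 / 75.16),
    # segment lengths at generic height, m
    lengths = c(thigh = 0.40, shank = 0.43, foot = 0.26, pelvis_height = 0.95),
    # foot landmarks relative to calcaneus CoM, model frame, m
    heel_offset = c(0.00363314, 0.00830251, -0.00715492),
    toe_offset = c(0.231826, -0.0107138, -0.0071549),
    foot_com_offset = c(0, 0, 0),          # foot origin is the calcaneus CoM
    ankle_offset = c(-0.05, 0.06, 0.008),  # ankle joint centre vs calcaneus CoM
    # sagittal (z) inertia of the whole foot about its CoM at generic size
    foot_inertia_zz = 0.0050               # kg m^2
  )
}

#' Generic muscle-tendon parameter and geometry table
#'
#' Seven shank muscles acting about the ankle. `lmt` is modelled per muscle
#' as a polynomial in the ankle angle (dorsiflexion positive, rad) plus a
#' linear knee-flexion term for the bi-articular gastrocnemii:
#' `lmt = c0 + c1*theta_a + c2*theta_a^2 + ck*theta_k`.
#' The sagittal ankle moment arm is `-d(lmt)/d(theta_a) = -(c1 + 2 c2 theta_a)`,
#' positive for dorsiflexors (tibialis anterior, extensor hallucis longus)
#' and negative for plantar flexors.
#'
#' @return data.frame with one row per muscle: `f_max` (N), `l_om` (m),
#'   `l_st` (m), `penn0` (rad), polynomial coefficients `c0, c1, c2, ck`,
#'   and the angle validity range `theta_min`/`theta_max` (rad).
#' @export
generic_mtu_table <- function() {
  tab <- data.frame(
    muscle = MUSCLES,
    f_max = c(905, 108, 1558, 683, 3549, 435, 943),
    l_om  = c(0.098, 0.111, 0.060, 0.064, 0.050, 0.050, 0.049),
    l_st  = c(0.223, 0.305, 0.390, 0.365, 0.250, 0.161, 0.345),
    penn0 = c(5, 6, 17, 8, 25, 5, 10) * pi / 180,
    # neutral-angle moment arms, m (dorsiflexors positive)
    arm0  = c(0.042, 0.030, -0.048, -0.046, -0.050, -0.018, -0.022),
    # arm change per rad of dorsiflexion (curvature of lmt)
    arm1  = c(-0.008, -0.006, 0.010, 0.010, 0.012, 0.004, 0.005),
    # knee-flexion term, m/rad (gastrocnemii shorten with knee flexion)
    ck    = c(0, 0, -0.020, -0.018, 0, 0, 0),
    theta_min = -0.8, theta_max = 0.8,
    stringsAsFactors = FALSE
  )
  tab$c0 <- tab$l_st + tab$l_om * cos(tab$penn0)
  tab$c1 <- -tab$arm0
  tab$c2 <- -tab$arm1 / 2
  tab
}

#' Default gait-phase-locked activation profiles
#'
#' Per-muscle activation envelopes over the gait cycle (0-1 of the impaired
#' stride, impaired IC at 0), each a sum of wrapped Gaussian bumps
#' `amp * exp(-(u - centre)^2 / (2 width^2))`. Timing follows textbook EMG
#' during walking: tibialis anterior / extensor hallucis longus active at
#' loading response and through swing, triceps surae and peroneals in late
#' stance (push-off precedes terminal contact at `duty` of the cycle).
#'
#' @return named list (one entry per muscle) of data.frames with columns
#'   `centre`, `width`, `amp`.
#' @export
default_envelope_profiles <- function() {
  bump <- function(centre, width, amp) data.frame(centre = centre, width = width, amp = amp)
  list(
    tib_ant      = bump(c(0.02, 0.78), c(0.05, 0.10), c(0.80, 0.55)),
    ext_hal_long = bump(c(0.03, 0.80), c(0.05, 0.10), c(0.45, 0.35)),
    med_gas      = bump(0.45, 0.10, 0.90),
    lat_gas      = bump(0.45, 0.10, 0.70),
    soleus       = bump(0.47, 0.11, 0.95),
    per_brev     = bump(0.40, 0.12, 0.55),
    per_long     = bump(0.42, 0.12, 0.60)
  )
}

#' Evaluate an activation profile at gait-cycle phases
#'
#' @param profile data.frame with `centre`, `width`, `amp` (wrapped Gaussian
#'   bumps), as in [default_envelope_profiles()].
#' @param u gait-cycle phase in `[0, 1)`.
#' @return numeric vector of activations, clipped to `[0, 1]`.
#' @export
eval_profile <- function(profile, u) {
  out <- numeric(length(u))
  for (i in seq_len(nrow(profile))) {
    for (k in -1:1) {
      out <- out + profile$amp[i] *
        exp(-(u - profile$centre[i] + k)^2 / (2 * profile$width[i]^2))
    }
  }
  pmin(out, 1)
}

#' Default 64-channel grid assignment
#'
#' Eight channels per muscle (7 muscles, 56 channels) plus eight channels
#' labelled `"noisy"`, emulating a muscle-localisation output on a 64-channel
#' EMG garment grid.
#'
#' @return character vector of length 64 (labels per channel).
#' @export
default_channel_map <- function() {
  c(rep(MUSCLES, each = 8), rep("noisy", 8))
}
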