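#' EMG-driven Hill-type musculoskeletal model of the ankle
#'
#' Seven shank muscles drive a rigid-tendon Hill-type model: normalised EMG
#' envelopes pass through a nonlinear excitation-to-activation shaping, the
#' muscle-tendon kinematics follow polynomial length/moment-arm geometry, and
#' each muscle produces force along its tendon via active force-length,
#' force-velocity and passive-elastic curves. The sagittal ankle torque is
#' the moment-arm-weighted sum of the muscle forces. Person-specific
#' calibration optimises, per muscle, the optimal fiber length, tendon slack
#' length, strength coefficient and shape factor to reproduce a reference
#' torque over one gait cycle; the calibrated model then estimates torque on
#' novel trials from envelopes and joint angles alone.
#'
#' @name mtu_model
NULL

#' Scale the muscle-tendon geometry to a participant
#'
#' Muscle-tendon lengths scale linearly with the height scale factor, so all
#' polynomial coefficients are multiplied by `s`.
#'
#' @param geometry generic table from [generic_mtu_table()].
#' @param s length scale factor (height / 1.68).
#' @return scaled geometry table.
#' @export
scale_mtu_geometry <- function(geometry = generic_mtu_table(), s = 1) {
  geometry[, c("c0", "c1", "c2", "ck")] <- geometry[, c("c0", "c1", "c2", "ck")] * s
  geometry
}

#' Initial muscle parameters from pre-calibration
#'
#' Chooses each muscle's optimal fiber length and tendon slack length so that
#' its normalised fiber length over a grid of ankle angles reproduces the
#' generic model's curve (least squares over the grid) — the person-specific
#' starting point that the torque calibration then refines within narrow
#' bounds. For uniformly scaled geometry the solution is the uniformly
#' scaled pair, recovered here numerically.
#'
#' @param geometry scaled geometry table (see [scale_mtu_geometry()]).
#' @param s the length scale factor used for the geometry.
#' @param generic generic table from [generic_mtu_table()].
#' @param grid ankle angle grid, rad.
#' @return `"MtuParams"` data.frame: per muscle `l_om`, `l_st` (m),
#'   `strength` (1), `shape_A` (-1.5), `f_max` (N, generic), `penn0` (rad).
#' @export
precalibrate_lom_lst <- function(geometry, s = 1, generic = generic_mtu_table(),
                                 grid = seq(-0.4, 0.4, length.out = 17)) {
  if (s <= 0) stop("scale factor must be positive")
  norm_fiber <- function(lmt, l_om, l_st, penn0) {
    w <- l_om * sin(penn0)
    sqrt(pmax(lmt - l_st, 0)^2 + w^2) / l_om
  }
  pars <- lapply(seq_len(nrow(generic)), function(i) {
    gen <- generic[i, ]
    sc <- geometry[i, ]
    lmt_gen <- gen$c0 + gen$c1 * grid + gen$c2 * grid^2
    lmt_sc <- sc$c0 + sc$c1 * grid + sc$c2 * grid^2
    if (any(lmt_sc <= 0)) stop("invalid geometry for ", gen$muscle)
    target <- norm_fiber(lmt_gen, gen$l_om, gen$l_st, gen$penn0)
    obj <- function(p) sum((norm_fiber(lmt_sc, p[1], p[2], gen$penn0) - target)^2)
    fit <- stats::optim(c(gen$l_om * s, gen$l_st * s), obj, method = "L-BFGS-B",
                        lower = 0.5 * c(gen$l_om, gen$l_st) * s,
                        upper = 2.0 * c(gen$l_om, gen$l_st) * s)
    c(l_om = fit$par[1], l_st = fit$par[2])
  })
  out <- data.frame(
    muscle = generic$muscle,
    do.call(rbind, pars),
    strength = 1, shape_A = -1.5,
    f_max = generic$f_max, penn0 = generic$penn0,
    stringsAsFactors = FALSE)
  class(out) <- c("MtuParams", "data.frame")
  out
}

#' Nonlinear excitation-to-activation shaping
#'
#' `a = (exp(A u) - 1) / (exp(A) - 1)` with shape factor `A in [-3, 0)`:
#' monotone, fixed endpoints (0 -> 0, 1 -> 1), approaching the identity as
#' `A -> 0^-`.
#'
#' @param u normalised excitation (EMG envelope), clipped to [0, 1].
#' @param A shape factor in `[-3, 0)`.
#' @return activation in [0, 1].
#' @export
excitation_to_activation <- function(u, A) {
  if (any(A < -3 | A >= 0)) stop("shape factor A must lie in [-3, 0)")
  u <- pmin(pmax(u, 0), 1)
  (exp(A * u) - 1) / (exp(A) - 1)
}

#' Muscle-tendon lengths and ankle moment arms
#'
#' Evaluates the per-muscle length polynomials
#' `lmt = c0 + c1 th_a + c2 th_a^2 + ck th_k` and the analytic sagittal
#' ankle moment arm `-d(lmt)/d(th_a) = -(c1 + 2 c2 th_a)`. Angles outside
#' the validity range are clamped with a warning.
#'
#' @param angles a `"JointAngleSeries"` (or list with `knee`, `ankle`, rad).
#' @param geometry scaled geometry table.
#' @return list of n x 7 matrices `lmt` (m) and `arm` (m, dorsiflexors
#'   positive).
#' @export
mtu_length_and_arm <- function(angles, geometry) {
  th_a <- angles$ankle; th_k <- angles$knee
  out_of_range <- th_a < min(geometry$theta_min) | th_a > max(geometry$theta_max)
  if (any(out_of_range))
    warning(sum(out_of_range), " sample(s) outside the geometry validity range; clamped")
  lmt <- arm <- matrix(NA_real_, length(th_a), nrow(geometry),
                       dimnames = list(NULL, geometry$muscle))
  for (i in seq_len(nrow(geometry))) {
    g <- geometry[i, ]
    a <- pmin(pmax(th_a, g$theta_min), g$theta_max)
    lmt[, i] <- g$c0 + g$c1 * a + g$c2 * a^2 + g$ck * th_k
    arm[, i] <- -(g$c1 + 2 * g$c2 * a)
  }
  list(lmt = lmt, arm = arm)
}

# Hill-curve primitives (normalised)
.f_active_length <- function(l) exp(-(l - 1)^2 / 0.45)
.f_velocity <- function(v) {
  v <- pmax(pmin(v, 1), -1)
  ifelse(v < 0,
         (1 + v) / (1 - v / 0.25),
         1.8 - 0.8 * (1 - v) / (1 + 7.56 * v / 0.25))
}
.f_passive <- function(l) ifelse(l > 1, expm1(4 * (l - 1) / 0.6) / expm1(4), 0)

#' Rigid-tendon Hill-type muscle force
#'
#' With a rigid tendon the fiber length follows from the muscle-tendon
#' length and the constant-thickness pennation relation
#' `l_m = sqrt((lmt - l_st)^2 + (l_om sin penn0)^2)`; fiber velocity is the
#' tendon-projected muscle-tendon velocity. Force along the tendon is
#' `F = strength * f_max * (a f_l(l) f_v(v) + f_p(l)) * cos(penn)`, clamped
#' non-negative; a slack muscle-tendon unit (`lmt <= l_st`) produces no
#' active force.
#'
#' @param a n x m activation matrix (columns = muscles).
#' @param lmt,vmt n x m muscle-tendon lengths (m) and velocities (m/s).
#' @param params `"MtuParams"` data.frame (m rows).
#' @return n x m matrix of tendon forces, N; attribute `"slack"` counts
#'   slack samples per muscle.
#' @export
hill_mtu_force <- function(a, lmt, vmt, params) {
  a <- pmin(pmax(a, 0), 1)
  F <- matrix(NA_real_, nrow(lmt), ncol(lmt), dimnames = dimnames(lmt))
  slack <- integer(ncol(lmt))
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    w <- p$l_om * sin(p$penn0)
    ext <- pmax(lmt[, i] - p$l_st, 0)
    slack[i] <- sum(lmt[, i] <= p$l_st)
    lm <- sqrt(ext^2 + w^2)
    cosp <- ext / lm
    lnorm <- lm / p$l_om
    vnorm <- cosp * vmt[, i] / (10 * p$l_om)
    F[, i] <- pmax(p$strength * p$f_max *
                     (a[, i] * .f_active_length(lnorm) * .f_velocity(vnorm) +
                        .f_passive(lnorm)) * cosp, 0)
  }
  attr(F, "slack") <- slack
  F
}

#' Ankle torque from muscle forces and moment arms
#'
#' `tau = sum_m F_m r_m`; plantar flexors (negative arms) contribute
#' plantar-flexion (negative) torque.
#'
#' @param forces,arms n x m matrices with matching muscle columns.
#' @param rate sampling rate, Hz.
#' @param mass body mass, kg.
#' @param provenance label for the resulting series.
#' @return `"TorqueSeries"`.
#' @export
ankle_torque_from_mtus <- function(forces, arms, rate, mass,
                                   provenance = "EMG-driven") {
  if (!identical(colnames(forces), colnames(arms)))
    stop("mismatched muscle sets between forces and moment arms")
  torque_series(rowSums(forces * arms), rate, mass, provenance)
}

# precompute everything that does not depend on the calibrated parameters
.mtu_precompute <- function(envelopes, angles, geometry, rate) {
  env <- if (inherits(envelopes, "EnvelopeSet")) envelopes$envelopes else envelopes
  stopifnot(ncol(env) == nrow(geometry))
  ka <- mtu_length_and_arm(angles, geometry)
  vmt <- apply(ka$lmt, 2, .ddt, rate = rate)
  list(env = env, lmt = ka$lmt, arm = ka$arm, vmt = vmt)
}

.mtu_torque_from_pre <- function(pre, params) {
  act <- sapply(seq_len(nrow(params)),
                function(i) excitation_to_activation(pre$env[, i], params$shape_A[i]))
  F <- hill_mtu_force(act, pre$lmt, pre$vmt, params)
  rowSums(F * pre$arm)
}

.params_to_vector <- function(params) {
  as.numeric(t(as.matrix(params[, c("l_om", "l_st", "strength", "shape_A")])))
}

.vector_to_params <- function(x, template) {
  m <- matrix(x, ncol = 4, byrow = TRUE)
  template$l_om <- m[, 1]; template$l_st <- m[, 2]
  template$strength <- m[, 3]; template$shape_A <- m[, 4]
  template
}

# seeded differential evolution (rand/1/bin) over box bounds
.de_optim <- function(obj, lower, upper, init = NULL,
                      pop = 40, gens = 120, F = 0.7, CR = 0.9) {
  d <- length(lower)
  P <- t(replicate(pop, stats::runif(d, lower, upper)))
  if (!is.null(init)) P[1, ] <- pmin(pmax(init, lower), upper)
  cost <- apply(P, 1, obj)
  trace <- numeric(gens)
  for (g in seq_len(gens)) {
    for (i in seq_len(pop)) {
      idx <- sample(setdiff(seq_len(pop), i), 3)
      v <- P[idx[1], ] + F * (P[idx[2], ] - P[idx[3], ])
      v <- pmin(pmax(v, lower), upper)
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1)] <- TRUE
      u <- ifelse(cross, v, P[i, ])
      cu <- obj(u)
      if (cu <= cost[i]) { P[i, ] <- u; cost[i] <- cu }
    }
    trace[g] <- min(cost)
  }
  best <- which.min(cost)
  list(par = P[best, ], value = cost[best], trace = trace)
}

#' Calibrate the EMG-driven model to a reference torque
#'
#' Bounded, seeded global optimisation (differential evolution followed by an
#' L-BFGS-B polish) of all per-muscle parameters — optimal fiber length and
#' tendon slack length within +/- `length_bound_frac` of their
#' pre-calibrated values, strength coefficient and shape factor within their
#' configured ranges — minimising the mean squared error between the
#' EMG-driven and reference torques normalised by the variance of the
#' reference torque over the calibration cycle.
#'
#' @param envelopes `"EnvelopeSet"` (7 muscles) or n x 7 matrix, calibration
#'   cycle only.
#' @param angles `"JointAngleSeries"` over the same samples.
#' @param ref_torque numeric vector (N m) or `"TorqueSeries"`.
#' @param geometry scaled geometry table.
#' @param init `"MtuParams"` starting point (pre-calibrated).
#' @param rate sampling rate, Hz.
#' @param length_bound_frac half-width of the l_om / l_st bounds, fraction
#'   of the initial values (0.05 = +/- 5 %).
#' @param strength_bounds,shape_bounds boxes for the remaining parameters.
#' @param seed integer seed (global search is stochastic but reproducible).
#' @param control list: `pop`, `gens` for the evolutionary stage.
#' @return object of class `"CalibrationResult"`: optimized `params`,
#'   objective `trace`, `objective_init`/`objective_final`, calibration-cycle
#'   `metrics` (R^2, RMSE), `seed`, `bounds`.
#' @export
calibrate_mtu <- function(envelopes, angles, ref_torque, geometry, init,
                          rate, length_bound_frac = 0.05,
                          strength_bounds = c(0.5, 2.0),
                          shape_bounds = c(-3, -0.01),
                          seed = 1L, control = list(pop = 40, gens = 120)) {
  if (inherits(ref_torque, "TorqueSeries")) ref_torque <- ref_torque$nm
  v_ref <- stats::var(ref_torque)
  if (v_ref == 0) stop("reference torque has zero variance")
  pre <- .mtu_precompute(envelopes, angles, geometry, rate)
  if (nrow(pre$env) != length(ref_torque))
    stop("envelopes/angles and reference torque lengths differ")
  x0 <- .params_to_vector(init)
  lower <- upper <- x0
  per <- matrix(seq_along(x0), ncol = 4, byrow = TRUE)
  lower[per[, 1:2]] <- x0[per[, 1:2]] * (1 - length_bound_frac)
  upper[per[, 1:2]] <- x0[per[, 1:2]] * (1 + length_bound_frac)
  lower[per[, 3]] <- strength_bounds[1]; upper[per[, 3]] <- strength_bounds[2]
  lower[per[, 4]] <- shape_bounds[1]; upper[per[, 4]] <- shape_bounds[2]
  obj <- function(x) {
    p <- .vector_to_params(x, init)
    mean((.mtu_torque_from_pre(pre, p) - ref_torque)^2) / v_ref
  }
  j0 <- obj(x0)
  set.seed(seed)
  de <- .de_optim(obj, lower, upper, init = x0,
                  pop = control$pop, gens = control$gens)
  polish <- stats::optim(de$par, obj, method = "L-BFGS-B",
                         lower = lower, upper = upper,
                         control = list(maxit = 200, factr = 1e7))
  best <- if (polish$value <= de$value) polish$par else de$par
  j1 <- min(polish$value, de$value)
  if (polish$convergence != 0)
    message("local polish did not fully converge (code ", polish$convergence,
            "); best-so-far returned")
  params <- .vector_to_params(best, init)
  tau <- .mtu_torque_from_pre(pre, params)
  metrics <- agreement_metrics(ref_torque, tau)
  structure(list(params = params, trace = c(j0, de$trace, j1),
                 objective_init = j0, objective_final = j1,
                 metrics = metrics, seed = seed,
                 bounds = list(lower = lower, upper = upper)),
            class = "CalibrationResult")
}

#' Estimate ankle torque on a novel trial
#'
#' Runs the full forward chain — excitation shaping, muscle-tendon
#' kinematics, Hill-type force, moment-arm-weighted torque — from envelopes
#' and joint angles only; no reference torque is consumed.
#'
#' @param params calibrated `"MtuParams"` (or a `"CalibrationResult"`).
#' @param envelopes `"EnvelopeSet"` or n x 7 matrix.
#' @param angles `"JointAngleSeries"`.
#' @param geometry scaled geometry table.
#' @param rate sampling rate, Hz.
#' @param mass body mass, kg.
#' @return list with `torque` (`"TorqueSeries"`, provenance "EMG-driven"),
#'   `passive_torque` (N m, zero-activation component), `forces` and
#'   `activations` (n x 7).
#' @export
estimate_torque <- function(params, envelopes, angles, geometry, rate, mass) {
  if (inherits(params, "CalibrationResult")) params <- params$params
  pre <- .mtu_precompute(envelopes, angles, geometry, rate)
  act <- sapply(seq_len(nrow(params)),
                function(i) excitation_to_activation(pre$env[, i], params$shape_A[i]))
  colnames(act) <- params$muscle
  F <- hill_mtu_force(act, pre$lmt, pre$vmt, params)
  F0 <- hill_mtu_force(act * 0, pre$lmt, pre$vmt, params)
  list(torque = ankle_torque_from_mtus(F, pre$arm, rate, mass),
       passive_torque = rowSums(F0 * pre$arm),
       forces = F, activations = act)
}
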