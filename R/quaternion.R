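#' Quaternion utilities
#'
#' Minimal scalar-first (w, x, y, z) unit-quaternion algebra used throughout
#' the package. Quaternion series are stored as n x 4 numeric matrices; all
#' operations are vectorised over rows. The model frame is x anterior, y up,
#' z to the participant's right; a positive rotation about +z therefore tilts
#' the anterior axis upward (dorsiflexion for a foot pointing along +x).
#'
#' @name quaternion
#' @keywords internal
NULL

#' Build a quaternion matrix
#'
#' @param w,x,y,z numeric vectors (recycled to common length).
#' @return n x 4 matrix with columns w, x, y, z.
#' @export
quat <- function(w, x = 0, y = 0, z = 0) {
  m <- cbind(unname(w), unname(x), unname(y), unname(z))
  dimnames(m) <- list(NULL, c("w", "x", "y", "z"))
  m
}

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  stopifnot(ncol(q) == 4)
  q
}

#' Hamilton product of two quaternion series
#'
#' @param q1,q2 n x 4 quaternion matrices (either may have a single row,
#'   which is recycled).
#' @return n x 4 quaternion matrix `q1 * q2`.
#' @export
quat_multiply <- function(q1, q2) {
  q1 <- as_quat_matrix(q1); q2 <- as_quat_matrix(q2)
  n <- max(nrow(q1), nrow(q2))
  if (nrow(q1) == 1L && n > 1L) q1 <- q1[rep(1L, n), , drop = FALSE]
  if (nrow(q2) == 1L && n > 1L) q2 <- q2[rep(1L, n), , drop = FALSE]
  w1 <- q1[, 1]; x1 <- q1[, 2]; y1 <- q1[, 3]; z1 <- q1[, 4]
  w2 <- q2[, 1]; x2 <- q2[, 2]; y2 <- q2[, 3]; z2 <- q2[, 4]
  quat(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2
  )
}

#' Quaternion conjugate (inverse for unit quaternions)
#' @param q n x 4 quaternion matrix.
#' @export
quat_conjugate <- function(q) {
  q <- as_quat_matrix(q)
  quat(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

#' Row-wise quaternion norms
#' @param q n x 4 quaternion matrix.
#' @export
quat_norm <- function(q) {
  q <- as_quat_matrix(q)
  sqrt(rowSums(q^2))
}

#' Normalise quaternions to unit length
#' @param q n x 4 quaternion matrix.
#' @export
quat_normalize <- function(q) {
  q <- as_quat_matrix(q)
  q / quat_norm(q)
}

#' Quaternion from axis-angle
#'
#' @param axis length-3 unit axis (normalised internally).
#' @param angle rotation angle(s), rad.
#' @return n x 4 quaternion matrix (n = length(angle)).
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  h <- angle / 2
  quat(cos(h), sin(h) * axis[1], sin(h) * axis[2], sin(h) * axis[3])
}

#' Rotate 3-vectors by quaternions
#'
#' Active rotation: `v' = q v q*`.
#'
#' @param q n x 4 quaternion matrix (or single row).
#' @param v n x 3 matrix of vectors (or single row).
#' @return n x 3 matrix of rotated vectors.
#' @export
quat_rotate <- function(q, v) {
  q <- as_quat_matrix(q)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1L && n > 1L) q <- q[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L && n > 1L) v <- v[rep(1L, n), , drop = FALSE]
  w <- q[, 1]; qv <- q[, 2:4, drop = FALSE]
  # v' = v + 2 w (qv x v) + 2 qv x (qv x v)
  cross <- function(a, b) {
    cbind(
      a[, 2] * b[, 3] - a[, 3] * b[, 2],
      a[, 3] * b[, 1] - a[, 1] * b[, 3],
      a[, 1] * b[, 2] - a[, 2] * b[, 1]
    )
  }
  t1 <- cross(qv, v)
  out <- v + 2 * w * t1 + 2 * cross(qv, t1)
  dimnames(out) <- NULL
  out
}

#' Rotation matrix of a single quaternion
#' @param q length-4 quaternion (or 1 x 4 matrix).
#' @export
quat_to_matrix <- function(q) {
  q <- as.numeric(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Sagittal (z-axis twist) angle of quaternions
#'
#' Decomposes each quaternion into twist about +z times residual swing and
#' returns the twist angle. For purely planar rotations this is the plane
#' angle itself.
#'
#' @param q n x 4 quaternion matrix.
#' @return numeric vector of angles in rad, in (-pi, pi].
#' @export
quat_twist_z <- function(q) {
  q <- as_quat_matrix(q)
  2 * atan2(q[, 4], q[, 1])
}

#' Chordal mean of a quaternion cluster
#'
#' Sign-aligns all rows to the first and renormalises the average. Adequate
#' for tightly clustered orientations such as a static pose.
#'
#' @param q n x 4 quaternion matrix.
#' @return 1 x 4 unit quaternion.
#' @export
quat_mean <- function(q) {
  q <- as_quat_matrix(q)
  s <- sign(q %*% q[1, ])
  s[s == 0] <- 1
  quat_normalize(matrix(colSums(q * as.numeric(s)), nrow = 1))
}

#' Body-frame angular velocity from a quaternion series
#'
#' Central-difference quaternion differentiation: `omega_body = 2 q* dq/dt`
#' (vector part).
#'
#' @param q n x 4 unit-quaternion series.
#' @param rate sampling rate, Hz.
#' @return n x 3 matrix of body-frame angular velocity, rad/s.
#' @export
quat_angular_velocity <- function(q, rate) {
  q <- as_quat_matrix(q)
  n <- nrow(q)
  stopifnot(n >= 3)
  # align hemispheres so finite differences are meaningful
  flip <- cumprod(c(1, ifelse(rowSums(q[-1, , drop = FALSE] * q[-n, , drop = FALSE]) < 0, -1, 1)))
  q <- q * flip
  dq <- q
  dq[2:(n - 1), ] <- (q[3:n, ] - q[1:(n - 2), ]) * (rate / 2)
  dq[1, ] <- (q[2, ] - q[1, ]) * rate
  dq[n, ] <- (q[n, ] - q[n - 1, ]) * rate
  om <- quat_multiply(quat_conjugate(q), dq)
  2 * om[, 2:4, drop = FALSE]
}
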