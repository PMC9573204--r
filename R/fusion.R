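# Attitude estimation and joint angles.
#
# Quaternions are length-4 numeric vectors c(w, x, y, z), Hamilton convention,
# unit-norm, rotating sensor-frame vectors into the world frame. The world
# frame is z-up; a resting accelerometer therefore reads +1 g along the world
# z axis rotated into the sensor frame.
#
# Attitude is propagated by gyro integration with a bounded complementary
# correction: the measured gravity and magnetic-field directions are compared
# against the directions the current attitude predicts, and the error (a
# cross product, in rad) is fed back into the angular rate with configurable
# gains. No optimiser, fully deterministic.

#' @rdname quaternions
#' @export
quat <- function(w, x, y, z) c(w, x, y, z)

#' Quaternion primitives
#'
#' Small set of Hamilton-quaternion helpers used by the attitude filter and
#' the signal generator.
#'
#' @param q,q1,q2 quaternions as `c(w, x, y, z)`
#' @param v 3-vector in the sensor frame
#' @name quaternions
NULL

#' @rdname quaternions
#' @export
quat_mul <- function(q1, q2) {
  c(q1[1] * q2[1] - q1[2] * q2[2] - q1[3] * q2[3] - q1[4] * q2[4],
    q1[1] * q2[2] + q1[2] * q2[1] + q1[3] * q2[4] - q1[4] * q2[3],
    q1[1] * q2[3] - q1[2] * q2[4] + q1[3] * q2[1] + q1[4] * q2[2],
    q1[1] * q2[4] + q1[2] * q2[3] - q1[3] * q2[2] + q1[4] * q2[1])
}

#' @rdname quaternions
#' @export
quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' @rdname quaternions
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalise a zero quaternion")
  q / n
}

#' @rdname quaternions
#' @export
quat_rotate <- function(q, v) {
  # sensor -> world
  qv <- quat_mul(quat_mul(q, c(0, v)), quat_conj(q))
  qv[2:4]
}

#' @rdname quaternions
#' @export
quat_rotate_inv <- function(q, v) quat_rotate(quat_conj(q), v)

#' Quaternion for a rotation about an axis
#' @param axis 3-vector (normalised internally)
#' @param angle_deg rotation angle, degrees
#' @return unit quaternion
#' @export
axis_angle_quat <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(c(1, 0, 0, 0))
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * axis / n)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Euler angles (intrinsic Z-Y-X) from a quaternion
#'
#' Convention: yaw about world z, then pitch about the intermediate y, then
#' roll about the body x — the aerospace yaw-pitch-roll sequence. The inverse
#' of [euler_to_quat()] away from gimbal lock. When the pitch comes within
#' 0.5 degrees of +/-90, roll and yaw are no longer separately identifiable
#' and the result carries attribute `gimbal_lock = TRUE`.
#'
#' @param q unit quaternion
#' @return named vector `c(roll, pitch, yaw)` in degrees
#' @export
quat_to_euler <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  s <- 2 * (w * y - z * x)
  s <- max(-1, min(1, s))
  pitch <- asin(s)
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
  out <- c(roll = roll, pitch = pitch, yaw = yaw) * 180 / pi
  if (abs(abs(out[["pitch"]]) - 90) < 0.5) attr(out, "gimbal_lock") <- TRUE
  out
}

#' Quaternion from intrinsic Z-Y-X Euler angles
#' @param roll,pitch,yaw degrees
#' @return unit quaternion
#' @export
euler_to_quat <- function(roll, pitch, yaw) {
  quat_mul(quat_mul(axis_angle_quat(c(0, 0, 1), yaw),
                    axis_angle_quat(c(0, 1, 0), pitch)),
           axis_angle_quat(c(1, 0, 0), roll))
}

#' One complementary-filter attitude update
#'
#' Propagates the attitude with the gyro reading and applies a bounded
#' correction from the accelerometer (gravity direction) and magnetometer
#' (heading). If the accelerometer or magnetometer reading has zero norm that
#' correction is skipped for the step and the result carries attribute
#' `gyro_only = TRUE`.
#'
#' @param q_prev unit quaternion at the previous tick
#' @param acc calibrated 3-axis acceleration, g
#' @param gyro calibrated 3-axis angular velocity, deg/s
#' @param mag calibrated 3-axis magnetic field, uT (set `k_mag = 0` to
#'   ignore heading)
#' @param dt time step, seconds
#' @param k_acc,k_mag feedback gains, rad/s per unit direction error
#' @return unit quaternion (renormalised)
#' @export
update_attitude <- function(q_prev, acc, gyro, mag, dt,
                            k_acc = 1, k_mag = 0.5) {
  stopifnot(dt > 0)
  q <- quat_normalize(q_prev)
  w <- gyro * pi / 180
  err <- c(0, 0, 0)
  gyro_only <- FALSE
  na <- sqrt(sum(acc^2)); nm <- sqrt(sum(mag^2))
  if (k_acc > 0 && na > 0) {
    v_hat <- quat_rotate_inv(q, c(0, 0, 1))       # predicted gravity direction
    err <- err + k_acc * .cross3(acc / na, v_hat)
  } else if (k_acc > 0) gyro_only <- TRUE
  if (k_mag > 0 && nm > 0) {
    h <- quat_rotate(q, mag / nm)                 # field in world frame
    b <- c(sqrt(h[1]^2 + h[2]^2), 0, h[3])        # reference: horizontal + down
    w_hat <- quat_rotate_inv(q, b)
    err <- err + k_mag * .cross3(mag / nm, w_hat)
  } else if (k_mag > 0) gyro_only <- TRUE
  wc <- w + err
  ang <- sqrt(sum(wc^2)) * dt
  dq <- if (ang > 0) c(cos(ang / 2), sin(ang / 2) * wc * dt / ang) else c(1, 0, 0, 0)
  out <- quat_normalize(quat_mul(q, dq))
  if (gyro_only) attr(out, "gyro_only") <- TRUE
  out
}

#' Angle between two sensor attitudes
#'
#' The scalar angle of the relative rotation `q_a^-1 q_b`, i.e. the total
#' rotation separating two adjacent IMUs — the per-joint quantity shown on
#' the clinician display.
#' @param q_a,q_b unit quaternions
#' @return angle in degrees, in `[0, 180]`
#' @export
joint_angle <- function(q_a, q_b) {
  rel <- quat_mul(quat_conj(quat_normalize(q_a)), quat_normalize(q_b))
  2 * acos(min(1, abs(rel[1]))) * 180 / pi
}

#' Sensor placement map and joint adjacency
#'
#' The index convention for the 19 IMUs: 0 is the hand-dorsum mainboard unit;
#' 1-15 are the finger segments, proximal to distal, thumb through little
#' finger; 16 and 17 sit on the radial and ulnar sides of the palm; 18 is the
#' upper-arm unit, so the elbow joint is the (0, 18) pair.
#' @return data.frame with columns `joint`, `imu_a`, `imu_b`
#' @export
joint_table <- function() {
  fingers <- c("thumb", "index", "middle", "ring", "little")
  rows <- list()
  for (f in seq_along(fingers)) {
    base <- (f - 1L) * 3L + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      joint = paste0(fingers[f], c("_mcp", "_pip", "_dip")),
      imu_a = c(0L, base, base + 1L),
      imu_b = c(base, base + 1L, base + 2L))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    joint = c("palm_radial", "palm_ulnar", "elbow"),
    imu_a = c(0L, 0L, 0L), imu_b = c(16L, 17L, 18L))
  do.call(rbind, rows)
}

#' Attitude track of one IMU over a session
#'
#' Runs [update_attitude()] over every frame of a session for one IMU.
#' @param session a `glove_session`
#' @param imu IMU index, 0-18
#' @param q0 initial attitude (default identity)
#' @param k_acc,k_mag filter gains, passed to [update_attitude()]
#' @return n x 4 matrix of unit quaternions, one row per frame
#' @export
estimate_attitude <- function(session, imu, q0 = c(1, 0, 0, 0),
                              k_acc = 1, k_mag = 0.5) {
  fr <- session$frames
  n <- nrow(fr)
  acc <- as.matrix(fr[imu_cols(imu, "acc")])
  gyr <- as.matrix(fr[imu_cols(imu, "gyro")])
  mag <- as.matrix(fr[imu_cols(imu, "mag")])
  dt <- 1 / session$sample_rate_hz
  out <- matrix(NA_real_, n, 4)
  q <- quat_normalize(q0)
  for (i in seq_len(n)) {
    q <- update_attitude(q, acc[i, ], gyr[i, ], mag[i, ], dt,
                         k_acc = k_acc, k_mag = k_mag)
    out[i, ] <- q
  }
  out
}

#' Joint-angle series for all mapped joints
#'
#' @param attitudes list of n x 4 quaternion matrices indexed by IMU number
#'   (names `"0"` ... `"18"`), e.g. from [estimate_attitude()] per IMU
#' @param joints adjacency table, default [joint_table()]
#' @return data.frame, one column per joint, angles in degrees
#' @export
joint_angle_series <- function(attitudes, joints = joint_table()) {
  out <- lapply(seq_len(nrow(joints)), function(j) {
    qa <- attitudes[[as.character(joints$imu_a[j])]]
    qb <- attitudes[[as.character(joints$imu_b[j])]]
    vapply(seq_len(nrow(qa)), function(i) joint_angle(qa[i, ], qb[i, ]),
           numeric(1))
  })
  stats::setNames(as.data.frame(out), joints$joint)
}
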