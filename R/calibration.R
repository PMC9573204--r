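# Sensor calibration: pressure-ball offset and hardness check, min/max
# hard/soft-iron magnetometer calibration, and stationary accel/gyro bias.

#' Pressure-ball calibration reference
#'
#' Before a ball-squeezing task the sensor needle is exposed to air to read
#' the ambient atmospheric pressure `p_a`; every subsequent ball reading is
#' reported as an offset from it. The ball hardness is acceptable while the
#' offset stays within `threshold_frac * p_a` of zero.
#'
#' @param p_a ambient atmospheric pressure, Pa
#' @param threshold_frac hardness tolerance as a fraction of `p_a`
#'   (default 0.005, i.e. +/-0.5 %)
#' @return a `pressure_calibration` object
#' @export
pressure_calibration <- function(p_a, threshold_frac = 0.005) {
  stopifnot(p_a > 0, threshold_frac > 0)
  structure(list(p_a = p_a, threshold_frac = threshold_frac),
            class = "pressure_calibration")
}

#' Ball pressure offset from ambient
#'
#' `p' = p - p_a`, the in-ball pressure relative to the ambient reference.
#' @param p raw pressure reading(s), Pa (vectorised)
#' @param cal a [pressure_calibration()]
#' @return offset pressure p', Pa
#' @export
pressure_offset <- function(p, cal) p - cal$p_a

#' Classify pressure-ball hardness
#'
#' Too soft when p' falls below -0.5 % of ambient (more air needed), too hard
#' above +0.5 % (air must be released); values on the boundary count as ok.
#' @param p_prime offset pressure(s) from [pressure_offset()], Pa
#' @param cal a [pressure_calibration()]
#' @return character vector in `{"too_soft", "ok", "too_hard"}`
#' @export
classify_ball_hardness <- function(p_prime, cal) {
  thr <- cal$threshold_frac * cal$p_a
  ifelse(p_prime < -thr, "too_soft", ifelse(p_prime > thr, "too_hard", "ok"))
}

#' Fit hard/soft-iron magnetometer calibration from a rotation sweep
#'
#' The glove is rotated in a figure-8 so each magnetometer axis sweeps its
#' full range; the first 2000 samples (by default) form the calibration
#' buffer. Per axis, the hard-iron bias is the midpoint of the observed
#' range, `alpha = (max + min) / 2`; the half-range (max chord half-length)
#' is `sigma = (max - min) / 2`; and the soft-iron scale factor
#' `beta = mean(sigma) / sigma` rescales each axis so all three share the
#' common radius `mean(sigma)`.
#'
#' @param buf n x 3 matrix (or data.frame) of magnetometer samples, uT;
#'   typically the warm-up segment of a session
#' @param expected_n warn when the buffer is shorter than this (default the
#'   2000-sample acquisition convention)
#' @return a `mag_calibration` object with fields `alpha`, `sigma`, `beta`
#'   (3-vectors)
#' @export
fit_mag_calibration <- function(buf, expected_n = 2000L) {
  buf <- as.matrix(buf)
  stopifnot(ncol(buf) == 3, nrow(buf) >= 2)
  if (nrow(buf) < expected_n)
    warning("magnetometer buffer has ", nrow(buf), " samples (expected >= ",
            expected_n, "); calibration may not attain the axis extremes")
  mx <- apply(buf, 2, max); mn <- apply(buf, 2, min)
  if (any(mx == mn))
    stop("degenerate magnetometer buffer: no range on axis ",
         paste(c("x", "y", "z")[mx == mn], collapse = ", "))
  alpha <- (mx + mn) / 2
  sigma <- (mx - mn) / 2
  beta <- mean(sigma) / sigma
  structure(list(alpha = unname(alpha), sigma = unname(sigma),
                 beta = unname(beta)),
            class = "mag_calibration")
}

#' Apply magnetometer calibration
#'
#' Per axis, `m' = beta * (m - alpha)`: subtract the hard-iron bias, then
#' rescale so the three axes share a common radius.
#' @param m 3-vector or n x 3 matrix of raw readings, uT
#' @param params a `mag_calibration` from [fit_mag_calibration()]
#' @return calibrated readings, same shape as `m`
#' @export
apply_mag_calibration <- function(m, params) {
  stopifnot(inherits(params, "mag_calibration"))
  if (is.matrix(m) || is.data.frame(m)) {
    m <- as.matrix(m)
    sweep(sweep(m, 2, params$alpha, "-"), 2, params$beta, "*")
  } else {
    params$beta * (m - params$alpha)
  }
}

#' Accelerometer/gyroscope bias from a stationary window
#'
#' When the glove is switched on lying on the desk, the gyroscope should read
#' zero and the accelerometer should read 1 g along gravity; the per-axis
#' means over that window give the gyro bias and the gravity reference
#' direction. The window is rejected as not stationary if the mean
#' acceleration norm strays more than `grav_tol` from 1 g.
#'
#' @param acc n x 3 matrix of acceleration, g
#' @param gyro n x 3 matrix of angular velocity, deg/s
#' @param sample_rate_hz sampling rate, used for the minimum-duration check
#' @param grav_tol relative tolerance on the gravity norm (default 0.1)
#' @return an `imu_bias` object with `gyro_bias` (deg/s) and
#'   `accel_gravity_ref` (g)
#' @export
fit_imu_bias <- function(acc, gyro, sample_rate_hz = 50, grav_tol = 0.1) {
  acc <- as.matrix(acc); gyro <- as.matrix(gyro)
  stopifnot(ncol(acc) == 3, ncol(gyro) == 3, nrow(acc) == nrow(gyro))
  if (nrow(acc) < sample_rate_hz)
    stop("need at least 1 s of stationary frames (", sample_rate_hz,
         " at ", sample_rate_hz, " Hz), got ", nrow(acc))
  g_ref <- colMeans(acc)
  nrm <- sqrt(sum(g_ref^2))
  if (abs(nrm - 1) > grav_tol)
    stop(sprintf("window is not stationary: mean acceleration norm %.3f g deviates more than %.0f%% from 1 g",
                 nrm, 100 * grav_tol))
  structure(list(gyro_bias = unname(colMeans(gyro)),
                 accel_gravity_ref = unname(g_ref)),
            class = "imu_bias")
}

#' Detect a stationary window by gyro magnitude
#'
#' The acquisition convention gives no explicit stationarity marker; a window
#' counts as stationary while the gyro magnitude stays below a threshold.
#' @param gyro n x 3 matrix, deg/s
#' @param threshold_dps magnitude threshold (default 1 deg/s)
#' @return logical vector, one element per row
#' @export
is_stationary <- function(gyro, threshold_dps = 1) {
  sqrt(rowSums(as.matrix(gyro)^2)) < threshold_dps
}

#' Calibrate every IMU of a session in place
#'
#' Fits, per IMU, the magnetometer calibration on the figure-8 warm-up
#' segment and the gyro bias on the leading stationary segment, then applies
#' both to the whole frame table (magnetometer rescaled, gyro bias
#' subtracted; the accelerometer is left untouched beyond the recorded
#' gravity reference).
#'
#' @param session a `glove_session` whose `stationary_frames` and
#'   `warmup_frames` are set (as produced by the simulator)
#' @return list with `session` (calibrated) and `params` (per-IMU list of
#'   `mag` and `bias` fits)
#' @export
calibrate_session <- function(session) {
  ns <- session$stationary_frames
  nw <- session$warmup_frames
  if (nw < 2) stop("session has no magnetometer warm-up segment")
  warm <- (ns + 1L):(ns + nw)
  fr <- session$frames
  params <- vector("list", N_IMUS)
  for (imu in 0:(N_IMUS - 1L)) {
    mc <- imu_cols(imu, "mag"); gc <- imu_cols(imu, "gyro"); ac <- imu_cols(imu, "acc")
    mag_fit <- fit_mag_calibration(fr[warm, mc], expected_n = min(2000L, nw))
    bias <- if (ns >= session$sample_rate_hz)
      fit_imu_bias(fr[1:ns, ac], fr[1:ns, gc], session$sample_rate_hz)
    else NULL
    fr[mc] <- apply_mag_calibration(fr[mc], mag_fit)
    if (!is.null(bias))
      fr[gc] <- sweep(as.matrix(fr[gc]), 2, bias$gyro_bias, "-")
    params[[imu + 1L]] <- list(mag = mag_fit, bias = bias)
  }
  session$frames <- fr
  list(session = session, params = params)
}

#' @export
print.mag_calibration <- function(x, ...) {
  cat("<mag_calibration>\n")
  cat("  alpha (uT):", format(x$alpha, digits = 4), "\n")
  cat("  sigma (uT):", format(x$sigma, digits = 4), "\n")
  cat("  beta      :", format(x$beta, digits = 4), "\n")
  invisible(x)
}
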