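# Synthetic session generator.
#
# Emulates the statistical structure of glove recordings so every downstream
# stage is testable without hardware: smooth raised-cosine flexion cycles per
# finger segment, gyro as the analytic derivative of orientation plus bias
# and noise, accelerometer as gravity rotated into the sensor frame plus a
# small motion term, magnetometer as the rotated reference field under
# hard-iron (additive) and soft-iron (per-axis scale) distortion, and a
# baseline-plus-pulses pressure trace for the ball-squeezing tasks. Each
# session opens with a stationary desk segment (accel/gyro bias window) and
# a figure-8 orientation sweep of >= 2000 frames (magnetometer calibration
# buffer).

#' Task waveform template
#'
#' Defaults encode the movement protocols: 50 repetition cycles per task,
#' slow tasks near 1 Hz and fast tasks faster, ball squeezing with one
#' pressure pulse per cycle. Cone stacking has no prescribed repetition
#' count; it is modelled as 20 transport cycles.
#'
#' @param task task code
#' @param n_cycles repetition count
#' @param cycle_rate_hz movement pace, cycles per second
#' @param amplitude_profile per-IMU angular excursion, degrees (length 19);
#'   default scales from large finger-segment excursions down to a small
#'   upper-arm sway
#' @param pressure_pulse_pa squeeze pulse height above baseline, Pa
#'   (ball-squeezing tasks only)
#' @return a `task_template` object
#' @export
task_template <- function(task = "S-FE",
                          n_cycles = NULL,
                          cycle_rate_hz = NULL,
                          amplitude_profile = NULL,
                          pressure_pulse_pa = 2000) {
  stopifnot(task %in% TASKS)
  defaults <- list(
    "CS"   = list(n_cycles = 20L, rate = 0.4),
    "S-FE" = list(n_cycles = 50L, rate = 1.0),
    "F-FE" = list(n_cycles = 50L, rate = 2.5),
    "S-BS" = list(n_cycles = 50L, rate = 0.5),
    "F-BS" = list(n_cycles = 50L, rate = 1.5))[[task]]
  if (is.null(n_cycles)) n_cycles <- defaults$n_cycles
  if (is.null(cycle_rate_hz)) cycle_rate_hz <- defaults$rate
  if (is.null(amplitude_profile)) {
    # dorsum, 5 fingers x (proximal, middle, distal), 2 palm units, upper arm
    amplitude_profile <- c(12, rep(c(55, 65, 45), 5), 10, 10, 6)
  }
  stopifnot(n_cycles >= 1, cycle_rate_hz > 0,
            length(amplitude_profile) == N_IMUS, pressure_pulse_pa > 0)
  structure(list(task = task, n_cycles = as.integer(n_cycles),
                 cycle_rate_hz = cycle_rate_hz,
                 amplitude_profile = amplitude_profile,
                 pressure_pulse_pa = pressure_pulse_pa),
            class = "task_template")
}

#' Spasticity effect on voluntary movement
#'
#' Spastic fingers move slower, over a smaller range, and less smoothly; the
#' generator models exactly that and nothing more. `velocity_scale`
#' multiplies the angular excursion (hence the angular-velocity magnitude at
#' fixed pace) and the squeeze-force pulse, `rate_scale` multiplies the
#' movement pace, and `tremor_noise_sd` adds extra angular-rate noise. The
#' per-MAS defaults are generator assumptions chosen to give a monotone,
#' clearly separated group structure; they are not clinical measurements.
#'
#' @param mas_score MAS level 0, 1 or 2; level 0 maps to the identity effect
#' @param velocity_scale,rate_scale,tremor_noise_sd override the per-MAS
#'   defaults (`velocity_scale` 1/0.7/0.45, `rate_scale` 1/0.85/0.7,
#'   `tremor_noise_sd` 0/3/6 deg/s for MAS 0/1/2)
#' @return a `spasticity_effect` object
#' @export
spasticity_effect <- function(mas_score = 0L,
                              velocity_scale = NULL,
                              rate_scale = NULL,
                              tremor_noise_sd = NULL) {
  stopifnot(mas_score %in% 0:2)
  i <- mas_score + 1L
  if (is.null(velocity_scale)) velocity_scale <- c(1, 0.7, 0.45)[i]
  if (is.null(rate_scale)) rate_scale <- c(1, 0.85, 0.7)[i]
  if (is.null(tremor_noise_sd)) tremor_noise_sd <- c(0, 3, 6)[i]
  stopifnot(velocity_scale >= 0, velocity_scale <= 1,
            rate_scale > 0, rate_scale <= 1, tremor_noise_sd >= 0)
  structure(list(mas_score = as.integer(mas_score),
                 velocity_scale = velocity_scale, rate_scale = rate_scale,
                 tremor_noise_sd = tremor_noise_sd),
            class = "spasticity_effect")
}

#' Sensor distortion and noise model
#'
#' Hard-iron distortion adds a constant field `mag_bias`; soft-iron
#' distortion scales each magnetometer axis by `mag_scale`. The gyro carries
#' an additive bias. `noise_sd` sets the white measurement noise per channel
#' type.
#'
#' @param mag_bias 3-vector, uT
#' @param mag_scale positive 3-vector, unitless
#' @param gyro_bias 3-vector, deg/s
#' @param noise_sd named list: `acc` (g), `gyro` (deg/s), `mag` (uT),
#'   `pressure` (Pa)
#' @return a `distortion_spec` object
#' @export
distortion_spec <- function(mag_bias = c(12, -8, 5),
                            mag_scale = c(1.10, 0.92, 1.05),
                            gyro_bias = c(0.8, -0.5, 0.3),
                            noise_sd = list(acc = 0.02, gyro = 0.5,
                                            mag = 0.3, pressure = 5)) {
  stopifnot(length(mag_bias) == 3, length(mag_scale) == 3,
            all(mag_scale > 0), length(gyro_bias) == 3)
  structure(list(mag_bias = mag_bias, mag_scale = mag_scale,
                 gyro_bias = gyro_bias, noise_sd = noise_sd),
            class = "distortion_spec")
}

#' @rdname distortion_spec
#' @export
distortion_none <- function() {
  distortion_spec(mag_bias = c(0, 0, 0), mag_scale = c(1, 1, 1),
                  gyro_bias = c(0, 0, 0),
                  noise_sd = list(acc = 0, gyro = 0, mag = 0, pressure = 0))
}

#: geomagnetic reference field in the world frame, uT (~48 uT with downward
#: dip); the world x axis points to magnetic north, so the field has no y
#: component — the same convention the attitude filter's heading feedback uses
MAG_REF <- c(22, 0, -42)

# rotate a fixed world vector into the sensor frame for every quaternion row
# of Q (n x 4): v_body = R(q)^T v
.rotate_inv_rows <- function(Q, v) {
  w <- Q[, 1]; x <- -Q[, 2]; y <- -Q[, 3]; z <- -Q[, 4]   # conjugate
  tx <- 2 * (y * v[3] - z * v[2])
  ty <- 2 * (z * v[1] - x * v[3])
  tz <- 2 * (x * v[2] - y * v[1])
  cbind(v[1] + w * tx + (y * tz - z * ty),
        v[2] + w * ty + (z * tx - x * tz),
        v[3] + w * tz + (x * ty - y * tx))
}

# minimal rotation taking unit vector a to unit vector b
.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  d <- sum(a * b)
  if (d < -1 + 1e-12) {
    ax <- .cross3(a, c(1, 0, 0))
    if (sum(ax^2) < 1e-12) ax <- .cross3(a, c(0, 1, 0))
    return(axis_angle_quat(ax, 180))
  }
  quat_normalize(c(1 + d, .cross3(a, b)))
}

# per-IMU constant mounting orientation (index 0-18), deterministic
.mount_quat <- function(imu) {
  euler_to_quat(roll = 8 * ((imu %% 3) - 1),
                pitch = -25 + 3 * imu,
                yaw = (23 * imu) %% 360 - 180)
}

# figure-8 warm-up sweep: Lissajous Euler trajectory covering all axes, with
# exact field-alignment poses inserted so every IMU's magnetometer attains
# +/-|B| on each axis (min/max calibration needs the extremes)
.warmup_quats <- function(n, fs, mounts) {
  tt <- (seq_len(n) - 1) / fs
  roll <- 80 * sin(2 * pi * 0.23 * tt)
  pitch <- 70 * sin(2 * pi * 0.17 * tt + 1)
  yaw <- 160 * sin(2 * pi * 0.07 * tt + 0.5)
  Q <- t(vapply(seq_len(n), function(i)
    euler_to_quat(roll[i], pitch[i], yaw[i]), numeric(4)))
  m_hat <- MAG_REF / sqrt(sum(MAG_REF^2))
  poses <- list()
  for (imu in seq_len(N_IMUS)) {
    for (j in 1:3) for (s in c(1, -1)) {
      e <- c(0, 0, 0); e[j] <- s
      q_i <- .rotation_between(e, m_hat)          # R(q_i) e_j = m_hat
      poses[[length(poses) + 1L]] <-
        quat_mul(q_i, quat_conj(mounts[[imu]]))
    }
  }
  k <- length(poses)
  if (n < 2 * k) stop("warm-up too short to cover calibration extremes (need >= ",
                      2 * k, " frames)")
  at <- round(seq(2, n - 1, length.out = k))
  for (i in seq_len(k)) Q[at[i], ] <- poses[[i]]
  Q
}

# body angular velocity (deg/s) of a quaternion track by finite differences
.track_gyro <- function(Q, fs) {
  n <- nrow(Q)
  out <- matrix(0, n, 3)
  for (i in 2:n) {
    rel <- quat_mul(quat_conj(Q[i - 1, ]), Q[i, ])
    vn <- sqrt(sum(rel[2:4]^2))
    if (vn > 0) {
      ang <- 2 * atan2(vn, rel[1])
      out[i, ] <- rel[2:4] / vn * ang * fs * 180 / pi
    }
  }
  out[1, ] <- out[2, ]
  out
}

#' Simulate one recording session
#'
#' Produces a complete session: a stationary desk segment, the figure-8
#' magnetometer warm-up, and the task segment of smooth periodic
#' flexion/extension cycles with per-cycle amplitude jitter. See the module
#' header for the signal model.
#'
#' @param template a [task_template()]
#' @param effect a [spasticity_effect()]
#' @param distortion a [distortion_spec()]
#' @param meta a [subject_meta()]; defaults to an anonymous subject whose MAS
#'   score matches `effect`
#' @param seed RNG seed; the same seed reproduces the session byte for byte
#' @param amp_factor,rate_factor subject-level multipliers on excursion and
#'   pace (cohort-level between-subject variability)
#' @param sample_rate_hz sampling rate, Hz
#' @param stationary_s length of the desk segment, seconds
#' @param warmup_frames length of the figure-8 sweep (>= 2 x 114 frames;
#'   2000 is the acquisition convention)
#' @param p_a ambient atmospheric pressure, Pa (ball-squeezing tasks)
#' @param cycle_jitter_sd sd of the per-cycle relative amplitude jitter
#' @param return_truth attach the generator's ground truth (task-segment
#'   flexion angles per IMU, degrees, and the per-IMU mounting quaternions)
#'   as attribute `"truth"` — used to validate the attitude filter
#' @return a `glove_session`; with `return_truth = TRUE` it carries attribute
#'   `truth`, a list with `theta_deg` (task-frames x 19 matrix) and `mounts`
#'   (list of 19 unit quaternions; the true task-segment attitude of IMU i is
#'   `mounts[[i+1]]` composed with a rotation of `theta_deg[, i+1]` about the
#'   body x axis)
#' @export
simulate_session <- function(template = task_template(),
                             effect = spasticity_effect(0),
                             distortion = distortion_spec(),
                             meta = NULL, seed = 1,
                             amp_factor = 1, rate_factor = 1,
                             sample_rate_hz = 50,
                             stationary_s = 2,
                             warmup_frames = 2000L,
                             p_a = 101325,
                             cycle_jitter_sd = 0.05,
                             return_truth = FALSE) {
  task <- template$task
  if (is.null(meta))
    meta <- subject_meta("anon",
                         group = if (effect$mas_score > 0) "stroke" else "healthy",
                         mas_score = effect$mas_score,
                         affected_side = if (effect$mas_score > 0) "right" else "none")
  set.seed(seed)
  fs <- sample_rate_hz
  dt <- 1 / fs
  ns <- as.integer(round(stationary_s * fs))
  nw <- as.integer(warmup_frames)
  f_eff <- template$cycle_rate_hz * effect$rate_scale * rate_factor
  nt <- as.integer(ceiling(template$n_cycles / f_eff * fs)) + 1L
  n <- ns + nw + nt
  mounts <- lapply(0:(N_IMUS - 1L), .mount_quat)

  # per-cycle amplitude jitter, shared across IMUs (whole-hand pacing)
  cyc_amp <- 1 + stats::rnorm(template$n_cycles, 0, cycle_jitter_sd)
  t_task <- (seq_len(nt) - 1) * dt
  phase <- f_eff * t_task
  cyc <- pmin(floor(phase), template$n_cycles - 1L)
  u <- phase - cyc
  done <- phase >= template$n_cycles
  shape <- ifelse(done, 0, 0.5 * (1 - cos(2 * pi * u)))      # 0..1..0
  dshape <- ifelse(done, 0, pi * f_eff * sin(2 * pi * u))    # d(shape)/dt
  d2shape <- ifelse(done, 0, 2 * pi^2 * f_eff^2 * cos(2 * pi * u))
  jit <- cyc_amp[cyc + 1L]

  Qw <- .warmup_quats(nw, fs, mounts)
  gyro_w_sweep <- .track_gyro(Qw, fs)

  nn <- distortion$noise_sd
  theta_all <- if (return_truth) matrix(0, nt, N_IMUS) else NULL
  cols <- vector("list", 1 + 9 * N_IMUS)
  cols[[1]] <- (seq_len(n) - 1) * dt
  vel <- effect$velocity_scale * amp_factor
  for (imu in 0:(N_IMUS - 1L)) {
    q0 <- mounts[[imu + 1L]]
    A <- template$amplitude_profile[imu + 1L] * vel
    theta <- A * jit * shape                       # degrees
    if (return_truth) theta_all[, imu + 1L] <- theta
    dtheta <- A * jit * dshape                     # deg/s
    d2theta <- A * jit * d2shape                   # deg/s^2
    # task-segment orientation: q0 composed with a rotation about body x
    half <- theta * pi / 360
    cth <- cos(half); sth <- sin(half)
    Qt <- cbind(q0[1] * cth - q0[2] * sth,
                q0[2] * cth + q0[1] * sth,
                q0[3] * cth + q0[4] * sth,
                q0[4] * cth - q0[3] * sth)
    Qs <- matrix(q0, ns, 4, byrow = TRUE)
    Qwi <- cbind(Qw[, 1] * q0[1] - Qw[, 2] * q0[2] - Qw[, 3] * q0[3] - Qw[, 4] * q0[4],
                 Qw[, 1] * q0[2] + Qw[, 2] * q0[1] + Qw[, 3] * q0[4] - Qw[, 4] * q0[3],
                 Qw[, 1] * q0[3] - Qw[, 2] * q0[4] + Qw[, 3] * q0[1] + Qw[, 4] * q0[2],
                 Qw[, 1] * q0[4] + Qw[, 2] * q0[3] - Qw[, 3] * q0[2] + Qw[, 4] * q0[1])
    Q <- rbind(Qs, Qwi, Qt)

    grav <- .rotate_inv_rows(Q, c(0, 0, 1))
    # small tangential motion term from the segment's angular acceleration
    lin <- cbind(0, c(rep(0, ns + nw), 0.02 * d2theta * pi / 180 / 9.81), 0)
    acc <- grav + lin +
      matrix(stats::rnorm(3 * n, 0, nn$acc), n, 3)

    # warm-up gyro: sweep angular velocity rotated into this IMU's frame
    gw <- t(apply(gyro_w_sweep, 1, function(v) quat_rotate_inv(q0, v)))
    gyro_true <- rbind(matrix(0, ns, 3), gw, cbind(dtheta, 0, 0))
    tremor <- effect$tremor_noise_sd
    gyro <- sweep(gyro_true, 2, distortion$gyro_bias, "+") +
      matrix(stats::rnorm(3 * n, 0, sqrt(nn$gyro^2 + tremor^2)), n, 3)

    mag_clean <- .rotate_inv_rows(Q, MAG_REF)
    mag <- sweep(sweep(mag_clean, 2, distortion$mag_scale, "*"),
                 2, distortion$mag_bias, "+") +
      matrix(stats::rnorm(3 * n, 0, nn$mag), n, 3)

    base <- 1 + 9 * imu
    cols[[base + 1]] <- acc[, 1]; cols[[base + 2]] <- acc[, 2]; cols[[base + 3]] <- acc[, 3]
    cols[[base + 4]] <- gyro[, 1]; cols[[base + 5]] <- gyro[, 2]; cols[[base + 6]] <- gyro[, 3]
    cols[[base + 7]] <- mag[, 1]; cols[[base + 8]] <- mag[, 2]; cols[[base + 9]] <- mag[, 3]
  }
  has_p <- task %in% BS_TASKS
  frames <- stats::setNames(as.data.frame(cols), channel_names(FALSE))
  if (has_p) {
    duty <- 0.5
    pulse <- ifelse(!done & u < duty, sin(pi * u / duty)^2, 0)
    height <- template$pressure_pulse_pa * vel * jit
    p_task <- p_a + height * pulse
    frames$pressure <- c(rep(p_a, ns + nw), p_task) +
      stats::rnorm(n, 0, nn$pressure)
  }
  out <- new_session(frames, task = task, meta = meta, sample_rate_hz = fs,
                     stationary_frames = ns, warmup_frames = nw)
  if (return_truth) attr(out, "truth") <- list(theta_deg = theta_all, mounts = mounts)
  out
}

#' Count squeeze pulses in a pressure-offset trace
#'
#' A pulse is an excursion of the offset trace above `min_height`; the count
#' is the number of upward crossings, robust to measurement noise around the
#' peaks.
#' @param p_prime offset pressure trace, Pa
#' @param min_height counting threshold, Pa
#' @return integer pulse count
#' @export
count_pressure_pulses <- function(p_prime, min_height) {
  above <- p_prime > min_height
  sum(diff(c(FALSE, above)) == 1)
}

#' Cohort specification
#'
#' The default mirrors the screening composition of the study cohort: nine
#' healthy-equivalent subjects (seven healthy plus two stroke subjects
#' without spasticity) and five spastic subjects (two at MAS 1, three at
#' MAS 2).
#'
#' @param n_healthy healthy-equivalent subject count
#' @param n_stroke_mas0 how many of those are stroke subjects with MAS 0
#'   (exercises the healthy-reassignment rule)
#' @param n_spastic_by_mas named counts for MAS levels `"1"` and `"2"`
#' @param tasks tasks every subject performs
#' @param seed master seed; per-session seeds are derived from it
#' @return a `cohort_spec` object
#' @export
cohort_spec <- function(n_healthy = 9L, n_stroke_mas0 = 2L,
                        n_spastic_by_mas = c("1" = 2L, "2" = 3L),
                        tasks = TASKS, seed = 1L) {
  stopifnot(n_healthy >= 0, n_stroke_mas0 >= 0, n_stroke_mas0 <= n_healthy,
            all(n_spastic_by_mas >= 0), all(tasks %in% TASKS))
  structure(list(n_healthy = as.integer(n_healthy),
                 n_stroke_mas0 = as.integer(n_stroke_mas0),
                 n_spastic_by_mas = n_spastic_by_mas,
                 tasks = tasks, seed = as.integer(seed)),
            class = "cohort_spec")
}

.derive_seed <- function(master, subj_idx, task_idx) {
  as.integer((as.numeric(master) * 7919 + subj_idx * 131 + task_idx * 17) %%
               2147483647)
}

#' Simulate a whole cohort
#'
#' One session per subject x task. Subject-level variability enters through
#' lognormal excursion and pace multipliers; the spasticity effect follows
#' each subject's MAS score.
#'
#' @param spec a [cohort_spec()]
#' @param distortion shared sensor [distortion_spec()]
#' @param subject_sd sd (log scale) of the between-subject excursion and
#'   pace multipliers
#' @param ... forwarded to [simulate_session()] (e.g. `warmup_frames`)
#' @return list with `sessions` (list of `glove_session`) and `manifest`
#'   (every parameter and derived seed, suitable for JSON serialisation)
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            distortion = distortion_spec(),
                            subject_sd = 0.08, ...) {
  subjects <- list()
  nh <- spec$n_healthy
  for (i in seq_len(nh)) {
    stroke0 <- i > (nh - spec$n_stroke_mas0)
    subjects[[length(subjects) + 1L]] <-
      subject_meta(sprintf("%s%02d", if (stroke0) "S0_" else "H", i),
                   group = if (stroke0) "stroke" else "healthy",
                   mas_score = 0L,
                   affected_side = if (stroke0) "right" else "none")
  }
  for (lev in names(spec$n_spastic_by_mas)) {
    for (i in seq_len(spec$n_spastic_by_mas[[lev]])) {
      subjects[[length(subjects) + 1L]] <-
        subject_meta(sprintf("S%s_%02d", lev, i), group = "stroke",
                     mas_score = as.integer(lev), affected_side = "right")
    }
  }
  sessions <- list()
  manifest_rows <- list()
  for (si in seq_along(subjects)) {
    meta <- subjects[[si]]
    sseed <- .derive_seed(spec$seed, si, 0L)
    set.seed(sseed)
    amp_f <- exp(stats::rnorm(1, 0, subject_sd))
    rate_f <- exp(stats::rnorm(1, 0, subject_sd))
    eff <- spasticity_effect(meta$mas_score)
    for (ti in seq_along(spec$tasks)) {
      task <- spec$tasks[ti]
      seed_st <- .derive_seed(spec$seed, si, ti)
      ses <- simulate_session(template = task_template(task), effect = eff,
                              distortion = distortion, meta = meta,
                              seed = seed_st, amp_factor = amp_f,
                              rate_factor = rate_f, ...)
      key <- paste(meta$subject_id, task, sep = ".")
      sessions[[key]] <- ses
      manifest_rows[[key]] <- list(subject_id = meta$subject_id, task = task,
                                   group = meta$group, mas_score = meta$mas_score,
                                   seed = seed_st, amp_factor = amp_f,
                                   rate_factor = rate_f)
    }
  }
  manifest <- list(spec = unclass(spec),
                   distortion = unclass(distortion),
                   subject_sd = subject_sd,
                   sessions = manifest_rows)
  list(sessions = sessions, manifest = manifest)
}
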