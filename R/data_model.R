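# Domain objects: sensor frames, sessions, subject metadata.
#
# A session holds the full multichannel recording of one subject performing
# one task: 19 nine-axis IMUs (18 glove units plus one upper-arm unit) sampled
# at a nominal 50 Hz, plus an air-pressure channel for the ball-squeezing
# tasks. Frames are stored wide (one row per tick, one column per channel),
# which keeps fixtures diffable and lets all signal operations vectorise.

#: number of IMUs: indices 0-17 are glove units, index 18 the upper-arm unit
N_IMUS <- 19L

#: recognised task codes: cone stacking, slow/fast flexion-extension,
#: slow/fast ball squeezing
TASKS <- c("CS", "S-FE", "F-FE", "S-BS", "F-BS")

#: tasks recorded with the pressure-ball module
BS_TASKS <- c("S-BS", "F-BS")

#' Channel column names for the wide frame table
#'
#' Column order is fixed: for each IMU index 0-18, the nine axis channels
#' `imuNN_acc_x, ..., imuNN_mag_z` (acceleration in g, angular velocity in
#' deg/s, magnetic field in uT). The time column `t` (seconds) precedes them
#' and, for ball-squeezing tasks, a final `pressure` column (Pa) follows.
#'
#' @param with_pressure include the trailing `pressure` column
#' @return character vector of column names, starting with `"t"`
#' @export
channel_names <- function(with_pressure = FALSE) {
  sensors <- c("acc", "gyro", "mag")
  cols <- as.vector(vapply(0:(N_IMUS - 1L), function(i) {
    as.vector(vapply(sensors, function(s) {
      paste0("imu", formatC(i, width = 2, flag = "0"), "_", s, "_", c("x", "y", "z"))
    }, character(3)))
  }, character(9)))
  c("t", cols, if (with_pressure) "pressure")
}

#' Names of the three axis columns of one IMU sensor triad
#' @param imu IMU index, 0-18
#' @param sensor one of `"acc"`, `"gyro"`, `"mag"`
#' @return character vector of length 3
#' @export
imu_cols <- function(imu, sensor) {
  stopifnot(imu %in% 0:(N_IMUS - 1L), sensor %in% c("acc", "gyro", "mag"))
  paste0("imu", formatC(imu, width = 2, flag = "0"), "_", sensor, "_", c("x", "y", "z"))
}

#' Subject metadata
#'
#' Stroke subjects scored MAS 0 at the finger MCP joints carry no spasticity
#' signal; for screening they are pooled with the healthy group (the
#' `group_for_screening()` accessor implements that reassignment).
#'
#' @param subject_id character label
#' @param group `"healthy"` or `"stroke"`
#' @param mas_score modified Ashworth scale score at the finger MCP joints,
#'   one of 0, 1, 2
#' @param affected_side `"left"`, `"right"` or `"none"`
#' @return a `subject_meta` object
#' @export
subject_meta <- function(subject_id, group = c("healthy", "stroke"),
                         mas_score = 0L,
                         affected_side = c("none", "left", "right")) {
  group <- match.arg(group)
  affected_side <- match.arg(affected_side)
  mas_score <- as.integer(mas_score)
  if (!mas_score %in% 0:2) stop("mas_score must be 0, 1 or 2")
  if (group == "healthy" && mas_score != 0L)
    stop("healthy subjects must have mas_score 0")
  structure(list(subject_id = as.character(subject_id), group = group,
                 mas_score = mas_score, affected_side = affected_side),
            class = "subject_meta")
}

#' Two-level screening label of a subject
#'
#' `"spastic"` iff MAS >= 1; stroke subjects without spasticity (MAS 0)
#' are healthy-equivalent.
#' @param meta a `subject_meta`
#' @return `"healthy"` or `"spastic"`
#' @export
group_for_screening <- function(meta) {
  if (meta$mas_score >= 1L) "spastic" else "healthy"
}

#' Construct a recording session
#'
#' @param frames data.frame with columns `t`, the 171 IMU channels of
#'   [channel_names()], and `pressure` for ball-squeezing tasks only
#' @param task task code, one of `r paste(TASKS, collapse = ", ")`
#' @param meta a [subject_meta()]
#' @param sample_rate_hz nominal sampling rate (default 50)
#' @param stationary_frames number of leading frames recorded with the glove
#'   at rest on the desk (accel/gyro bias window)
#' @param warmup_frames number of frames, after the stationary window, of the
#'   figure-8 rotation sweep used for magnetometer calibration
#' @param validate run [validate_session()] on the result
#' @return a `glove_session` object
#' @export
new_session <- function(frames, task, meta, sample_rate_hz = 50,
                        stationary_frames = 0L, warmup_frames = 0L,
                        validate = TRUE) {
  s <- structure(list(meta = meta, task = task,
                      frames = as.data.frame(frames),
                      sample_rate_hz = sample_rate_hz,
                      stationary_frames = as.integer(stationary_frames),
                      warmup_frames = as.integer(warmup_frames)),
                 class = "glove_session")
  if (validate) validate_session(s)
  s
}

#' Validate a session against its structural invariants
#'
#' Checks the channel set (19 IMUs x 9 axes), pressure presence exactly for
#' ball-squeezing tasks, finite values, and strictly increasing time at the
#' nominal step. Timing violations beyond `dt_tol` seconds are an error, not
#' silently accepted.
#'
#' @param session a `glove_session`
#' @param dt_tol tolerance on `|dt - 1/sample_rate_hz|`, seconds
#' @return the session, invisibly; the maximum timing deviation is attached
#'   as attribute `max_dt_dev` on the return value
#' @export
validate_session <- function(session, dt_tol = 1e-6) {
  if (!inherits(session, "glove_session")) stop("not a glove_session")
  if (!session$task %in% TASKS)
    stop("unknown task '", session$task, "'")
  has_p <- session$task %in% BS_TASKS
  want <- channel_names(with_pressure = has_p)
  got <- names(session$frames)
  if (!identical(sort(want), sort(got))) {
    miss <- setdiff(want, got); extra <- setdiff(got, want)
    stop("frame table columns do not match the ",
         if (has_p) "pressure" else "pressure-free", " layout for task ",
         session$task,
         if (length(miss)) paste0("; missing: ", paste(utils::head(miss, 5), collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(utils::head(extra, 5), collapse = ", ")))
  }
  max_dev <- 0
  if (nrow(session$frames) > 0) {
    bad <- !vapply(session$frames, function(col) all(is.finite(col)), logical(1))
    if (any(bad))
      stop("non-finite values in channel(s): ",
           paste(names(session$frames)[bad], collapse = ", "))
    tt <- session$frames$t
    if (tt[1] < 0) stop("t must be non-negative")
    if (length(tt) > 1) {
      dt <- diff(tt)
      if (any(dt <= 0)) stop("t must be strictly increasing")
      max_dev <- max(abs(dt - 1 / session$sample_rate_hz))
      if (max_dev > dt_tol)
        stop(sprintf("frame timing violates the nominal %.0f ms step: max |dt - nominal| = %.3g s",
                     1000 / session$sample_rate_hz, max_dev))
    }
  }
  invisible(structure(session, max_dt_dev = max_dev))
}

#' Task-segment frames of a session
#'
#' Drops the leading stationary and warm-up windows; features are computed on
#' this segment only.
#' @param session a `glove_session`
#' @return data.frame of frames
#' @export
task_frames <- function(session) {
  skip <- session$stationary_frames + session$warmup_frames
  if (skip >= nrow(session$frames)) return(session$frames[0, , drop = FALSE])
  session$frames[(skip + 1L):nrow(session$frames), , drop = FALSE]
}

#' @export
print.glove_session <- function(x, ...) {
  cat(sprintf("<glove_session> subject %s (%s, MAS %d), task %s: %d frames @ %g Hz",
              x$meta$subject_id, x$meta$group, x$meta$mas_score, x$task,
              nrow(x$frames), x$sample_rate_hz))
  if (x$stationary_frames + x$warmup_frames > 0)
    cat(sprintf(" (%d stationary + %d warm-up)", x$stationary_frames, x$warmup_frames))
  cat("\n")
  invisible(x)
}
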