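# Feature extraction.
#
# Hand movement is three-dimensional, so features are computed on the total
# magnitude (Euclidean norm) of each sensor triad rather than per axis. Each
# magnitude channel yields 20 statistics: 8 time-domain (mean, median, IQR,
# SD, CV, RMS, skewness, kurtosis) and 12 frequency-domain (the six main
# spectral frequencies and their amplitudes). With 19 IMUs x 3 sensors = 57
# channels this gives 1140 features per session; the ball-squeezing tasks add
# the pressure-offset channel for 1160.

TD_STATS <- c("Mean", "Median", "IQR", "SD", "CV", "RMS", "Skewness", "Kurtosis")
FD_STATS <- c(paste0("Mainfreq", 1:6), paste0("Amp", 1:6))
ALL_STATS <- c(TD_STATS, FD_STATS)
SENSOR_LABELS <- c(acc = "Acc", gyro = "Gyro", mag = "Mag")

#' Per-frame magnitude of a 3-axis signal
#' @param xyz n x 3 matrix or data.frame
#' @return numeric vector of Euclidean norms
#' @export
magnitude <- function(xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) >= 1)
  sqrt(rowSums(xyz^2))
}

#' Time-domain statistics of a magnitude series
#'
#' Conventions: quartiles by linear interpolation (type 7), SD with the n-1
#' denominator, CV = SD/mean, RMS = sqrt(mean of squares), skewness g1 =
#' m3/m2^(3/2) and excess kurtosis g2 = m4/m2^2 - 3 (moment estimators). A
#' zero-variance series has skewness and kurtosis 0 by convention; when the
#' mean is numerically zero relative to the signal scale the CV is
#' unidentified and reported as `NA`.
#'
#' @param x numeric vector, length >= 4
#' @return named vector of the 8 statistics
#' @export
time_domain_features <- function(x) {
  n <- length(x)
  if (n < 4) stop("need at least 4 samples for the shape statistics, got ", n)
  mu <- mean(x)
  sdv <- stats::sd(x)
  rms <- sqrt(mean(x^2))
  m2 <- mean((x - mu)^2)
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  } else skew <- kurt <- 0
  cv <- if (abs(mu) < 1e-9 * max(rms, .Machine$double.eps)) NA_real_ else sdv / mu
  c(Mean = mu, Median = stats::median(x),
    IQR = unname(stats::IQR(x, type = 7)), SD = sdv, CV = cv, RMS = rms,
    Skewness = skew, Kurtosis = kurt)
}

#' Single-sided amplitude spectrum
#'
#' Mean-removed, rectangular window: amplitude `2|X_k|/N` at frequency
#' `k fs / N` for `k = 1 .. floor(N/2)` (DC excluded).
#' @param x numeric vector
#' @param fs sampling rate, Hz
#' @return data.frame with columns `freq` and `amp`
#' @export
amplitude_spectrum <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  k <- seq_len(floor(n / 2))
  data.frame(freq = k * fs / n, amp = 2 * Mod(X[k + 1]) / n)
}

#' Frequency-domain statistics of a magnitude series
#'
#' The six main frequencies are the locations of the six largest-amplitude
#' local maxima of the single-sided spectrum (DC excluded), ordered by
#' descending amplitude; their amplitudes complete the 12 values. When the
#' spectrum has fewer than six peaks the remaining slots are 0.
#'
#' @param x numeric vector, length >= 16
#' @param fs sampling rate, Hz
#' @return named vector `Mainfreq1..6`, `Amp1..6`
#' @export
frequency_domain_features <- function(x, fs) {
  if (length(x) < 16) stop("need at least 16 samples for the spectrum, got ",
                           length(x))
  sp <- amplitude_spectrum(x, fs)
  a <- sp$amp
  m <- length(a)
  # local maxima; endpoints compared one-sided
  left <- c(Inf, a[-m]); right <- c(a[-1], -Inf)
  peaks <- which(a > left & a >= right)
  if (length(peaks) == 0 && m > 0 && any(a > 0)) peaks <- which.max(a)
  ord <- peaks[order(a[peaks], decreasing = TRUE)]
  top <- utils::head(ord, 6)
  mf <- amp <- rep(0, 6)
  if (length(top) > 0 && any(a[top] > 0)) {
    keep <- a[top] > 0
    top <- top[keep]
    mf[seq_along(top)] <- sp$freq[top]
    amp[seq_along(top)] <- a[top]
  }
  stats::setNames(c(mf, amp), FD_STATS)
}

.channel_feature_names <- function(with_pressure) {
  nm <- character(0)
  for (imu in 0:(N_IMUS - 1L))
    for (s in c("acc", "gyro", "mag"))
      nm <- c(nm, paste0(SENSOR_LABELS[[s]], "XYZ_", imu, "_", ALL_STATS))
  if (with_pressure) nm <- c(nm, paste0("Ball_Offset_", ALL_STATS))
  nm
}

#' Names of the full feature set
#'
#' Feature names follow `<Acc|Gyro|Mag>XYZ_<imu>_<Stat>` for the IMU
#' channels and `Ball_Offset_<Stat>` for the pressure channel, with Stat one
#' of the 20 statistics. 1140 names without the pressure channel, 1160 with.
#' @param with_pressure include the `Ball_Offset` block
#' @return character vector
#' @export
feature_names <- function(with_pressure = FALSE) {
  .channel_feature_names(with_pressure)
}

#' Parse a feature name
#' @param name a feature-name string
#' @return list with `sensor` (`"Acc"`, `"Gyro"`, `"Mag"` or
#'   `"Ball_Offset"`), `imu` (index or `NA`), `stat`
#' @export
parse_feature_name <- function(name) {
  if (grepl("^Ball_Offset_", name)) {
    stat <- sub("^Ball_Offset_", "", name)
    if (!stat %in% ALL_STATS) stop("unknown statistic in '", name, "'")
    return(list(sensor = "Ball_Offset", imu = NA_integer_, stat = stat))
  }
  m <- regmatches(name, regexec("^(Acc|Gyro|Mag)XYZ_([0-9]+)_(.+)$", name))[[1]]
  if (length(m) != 4 || !m[4] %in% ALL_STATS || !(as.integer(m[3]) %in% 0:(N_IMUS - 1L)))
    stop("unparseable feature name '", name, "'")
  list(sensor = m[2], imu = as.integer(m[3]), stat = m[4])
}

#' All 20 statistics of one series
#' @param x numeric vector
#' @param fs sampling rate, Hz
#' @return named vector of length 20
#' @export
channel_features <- function(x, fs) {
  c(time_domain_features(x), frequency_domain_features(x, fs))
}

#' Extract the full feature row of a session
#'
#' Computes, on the task segment only (stationary and warm-up windows
#' excluded), the 20 statistics of every signal-magnitude channel: 57 IMU
#' channels for every task, plus the pressure-offset channel for the
#' ball-squeezing tasks. The session should already be calibrated (see
#' [calibrate_session()]).
#'
#' @param session a `glove_session`
#' @param p_a ambient pressure used for the ball offset, Pa
#' @return named numeric vector of 1140 (1160 for ball-squeezing tasks)
#'   features, in the fixed [feature_names()] order
#' @export
extract_features <- function(session, p_a = 101325) {
  fr <- task_frames(session)
  has_p <- session$task %in% BS_TASKS
  if (has_p && is.null(fr$pressure))
    stop("ball-squeezing session is missing its pressure channel")
  fs <- session$sample_rate_hz
  out <- numeric(0)
  for (imu in 0:(N_IMUS - 1L)) {
    for (s in c("acc", "gyro", "mag")) {
      mg <- magnitude(fr[imu_cols(imu, s)])
      v <- channel_features(mg, fs)
      names(v) <- paste0(SENSOR_LABELS[[s]], "XYZ_", imu, "_", ALL_STATS)
      out <- c(out, v)
    }
  }
  if (has_p) {
    po <- pressure_offset(fr$pressure, pressure_calibration(p_a))
    v <- channel_features(po, fs)
    names(v) <- paste0("Ball_Offset_", ALL_STATS)
    out <- c(out, v)
  }
  stopifnot(identical(names(out), feature_names(has_p)))
  out
}

#' Feature table of a set of sessions
#'
#' @param sessions list of `glove_session`, all of the same task
#' @param p_a ambient pressure, Pa
#' @return data.frame: one row per session with `subject_id`, `group`,
#'   `mas_score`, `task`, then the feature columns
#' @export
feature_table <- function(sessions, p_a = 101325) {
  stopifnot(length(sessions) >= 1)
  tasks <- vapply(sessions, function(s) s$task, character(1))
  if (length(unique(tasks)) != 1)
    stop("sessions mix tasks: ", paste(unique(tasks), collapse = ", "))
  rows <- lapply(sessions, function(s) {
    cbind(data.frame(subject_id = s$meta$subject_id, group = s$meta$group,
                     mas_score = s$meta$mas_score, task = s$task,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(extract_features(s, p_a = p_a)),
                        check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
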