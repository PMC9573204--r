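test_that("pressure offset is the plain difference from ambient, and linear", {
  cal <- pressure_calibration(101325)
  expect_equal(pressure_offset(101325, cal), 0)
  expect_equal(pressure_offset(102000, cal), 675)
  p1 <- runif(1, 9e4, 1.1e5)
  expect_equal(pressure_offset(p1 + 37.5, cal) - pressure_offset(p1, cal), 37.5)
})

test_that("ball hardness classification uses the +/-0.5% band, boundary ok", {
  cal <- pressure_calibration(100000)
  expect_equal(classify_ball_hardness(0, cal), "ok")
  expect_equal(classify_ball_hardness(-600, cal), "too_soft")
  expect_equal(classify_ball_hardness(600, cal), "too_hard")
  expect_equal(classify_ball_hardness(c(-500, 500), cal), c("ok", "ok"))
})

test_that("min/max magnetometer fit matches hand-evaluated parameters", {
  buf <- rbind(c(-10, -20, -30), c(10, 20, 30), c(0, 0, 0))
  fit <- suppressWarnings(fit_mag_calibration(buf))
  expect_equal(fit$alpha, c(0, 0, 0))
  expect_equal(fit$sigma, c(10, 20, 30))
  expect_equal(fit$beta, c(2, 1, 2 / 3))
  # construction identity: mean(sigma * beta) = mean(sigma)
  expect_equal(mean(fit$sigma * fit$beta), mean(fit$sigma))

  sym <- rbind(c(-1, -1, -1), c(1, 1, 1))
  fs <- suppressWarnings(fit_mag_calibration(sym))
  expect_equal(fs$alpha, c(0, 0, 0))
  expect_equal(fs$beta, c(1, 1, 1))
})

test_that("applying the calibration maps bias to origin and rescales axes", {
  fit <- suppressWarnings(fit_mag_calibration(rbind(c(-10, -20, -30),
                                                    c(10, 20, 30))))
  expect_equal(apply_mag_calibration(fit$alpha, fit), c(0, 0, 0))
  fit0 <- fit; fit0$alpha <- c(0, 0, 0); fit0$beta <- c(2, 1, 2 / 3)
  expect_equal(apply_mag_calibration(c(1, 1, 3), fit0), c(2, 1, 2))
})

test_that("calibration recovers planted distortion from a coverage sweep and is idempotent", {
  bias <- c(12, -8, 5); scl <- c(1.10, 0.92, 1.05)
  d <- distortion_spec(mag_bias = bias, mag_scale = scl,
                       noise_sd = list(acc = 0, gyro = 0, mag = 0, pressure = 0))
  ses <- quick_session(seed = 3, n_cycles = 2, distortion = d)
  warm <- (ses$stationary_frames + 1):(ses$stationary_frames + ses$warmup_frames)
  B <- sqrt(sum(c(22, 0, -42)^2))
  for (imu in c(0L, 7L, 18L)) {
    buf <- ses$frames[warm, imu_cols(imu, "mag")]
    fit <- fit_mag_calibration(buf, expected_n = 300L)
    expect_equal(fit$alpha, bias, tolerance = 1e-12)    # extremes attained
    expect_equal(fit$sigma, scl * B, tolerance = 1e-12)
    expect_equal(fit$beta / fit$beta[1], (1 / scl) / (1 / scl[1]),
                 tolerance = 1e-12)                     # beta prop. 1/scale
    # idempotence: refit on calibrated data is the identity transform
    fit2 <- fit_mag_calibration(apply_mag_calibration(buf, fit),
                                expected_n = 300L)
    expect_equal(fit2$alpha, c(0, 0, 0), tolerance = 1e-9)
    expect_equal(fit2$beta, c(1, 1, 1), tolerance = 1e-9)
  }
})

test_that("degenerate magnetometer axes are refused by name", {
  buf <- cbind(x = c(1, 1, 1), y = c(-2, 0, 2), z = c(-1, 0, 1))
  expect_error(suppressWarnings(fit_mag_calibration(buf)), "axis x")
})

test_that("stationary fit recovers gyro bias and the gravity direction", {
  b <- c(0.8, -0.5, 0.3)
  gyro <- matrix(rep(b, each = 100), 100)
  acc <- matrix(rep(c(0, 0, 1), each = 100), 100)
  fit <- fit_imu_bias(acc, gyro)
  expect_equal(fit$gyro_bias, b)
  expect_equal(fit$accel_gravity_ref, c(0, 0, 1))

  # noisy window: error bounded by 3 standard errors per axis
  set.seed(21)
  gyro_n <- gyro[rep(1:100, 5), ] + matrix(rnorm(1500, 0, 0.1), 500)
  acc_n <- acc[rep(1:100, 5), ] + matrix(rnorm(1500, 0, 0.01), 500)
  fit_n <- fit_imu_bias(acc_n, gyro_n)
  expect_lt(max(abs(fit_n$gyro_bias - b)), 3 * 0.1 / sqrt(500))

  # tilted but stationary: unit-norm gravity along the tilt
  q <- euler_to_quat(25, -10, 0)
  g_tilt <- quat_rotate_inv(q, c(0, 0, 1))
  fit_t <- fit_imu_bias(matrix(rep(g_tilt, each = 60), 60), matrix(0, 60, 3))
  expect_equal(sqrt(sum(fit_t$accel_gravity_ref^2)), 1, tolerance = 1e-9)
  expect_equal(fit_t$accel_gravity_ref, g_tilt, tolerance = 1e-9)

  # a moving window is rejected
  expect_error(fit_imu_bias(acc * 3, gyro), "not stationary")
  expect_error(fit_imu_bias(acc[1:10, ], gyro[1:10, ]), "at least 1 s")
})

test_that("stationarity detection thresholds the gyro magnitude", {
  g <- rbind(c(0.1, 0.1, 0.1), c(30, 0, 0))
  expect_equal(is_stationary(g), c(TRUE, FALSE))
})
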