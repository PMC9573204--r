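test_that("euler conversions are mutually inverse away from gimbal lock", {
  expect_equal(unname(quat_to_euler(c(1, 0, 0, 0))), c(0, 0, 0))
  expect_equal(unname(quat_to_euler(axis_angle_quat(c(0, 0, 1), 90))),
               c(0, 0, 90))
  set.seed(31)
  for (i in 1:100) {
    q <- quat_normalize(rnorm(4))
    e <- quat_to_euler(q)
    if (abs(e[["pitch"]]) >= 80) next
    e2 <- quat_to_euler(euler_to_quat(e[["roll"]], e[["pitch"]], e[["yaw"]]))
    expect_lt(max(abs(e2 - e)), 1e-6)
  }
  near_lock <- quat_to_euler(euler_to_quat(10, 89.8, -30))
  expect_true(isTRUE(attr(near_lock, "gimbal_lock")))
})

test_that("gyro-only integration reproduces a 90 degree rotation", {
  q <- c(1, 0, 0, 0)
  for (i in 1:50)
    q <- update_attitude(q, c(0, 0, 0), c(90, 0, 0), c(0, 0, 0), dt = 0.02,
                         k_acc = 0, k_mag = 0)
  expect_equal(quat_to_euler(q)[["roll"]], 90, tolerance = 0.5)
})

test_that("a level stationary reading is a fixed point of the filter", {
  q <- c(1, 0, 0, 0)
  for (i in 1:20)
    q <- update_attitude(q, c(0, 0, 1), c(0, 0, 0), c(22, 0, -42), 0.02)
  expect_equal(q, c(1, 0, 0, 0), tolerance = 1e-9)
})

test_that("static readings pull an arbitrary initial attitude to the tilt", {
  q_true <- euler_to_quat(20, -15, 40)
  acc <- quat_rotate_inv(q_true, c(0, 0, 1))
  mag <- quat_rotate_inv(q_true, c(22, 0, -42))
  q <- euler_to_quat(100, 10, -120)
  for (i in 1:3000)
    q <- update_attitude(q, acc, c(0, 0, 0), mag, 0.02, k_acc = 2, k_mag = 1)
  resid <- sqrt(sum((quat_rotate_inv(q, c(0, 0, 1)) - acc)^2))
  expect_lt(resid, 0.01)
  expect_lt(joint_angle(q, q_true), 2)
})

test_that("zero-norm accel or mag readings fall back to gyro-only, flagged", {
  q <- update_attitude(c(1, 0, 0, 0), c(0, 0, 0), c(10, 0, 0), c(0, 0, 0), 0.02)
  expect_true(isTRUE(attr(q, "gyro_only")))
  expect_equal(sqrt(sum(q^2)), 1, tolerance = 1e-12)
})

test_that("unit norm is preserved over long random update sequences", {
  set.seed(7)
  q <- quat_normalize(rnorm(4))
  for (i in 1:500)
    q <- update_attitude(q, rnorm(3), rnorm(3, 0, 100), rnorm(3, 0, 40), 0.02)
  expect_equal(sqrt(sum(q^2)), 1, tolerance = 1e-6)
})

test_that("attitude returns after a closed rotation loop", {
  q <- c(1, 0, 0, 0)
  steps <- list(c(90, 0, 0), c(0, 90, 0), c(-90, 0, 0), c(0, -90, 0))
  # the loop of four 90-degree rotations about alternating axes is not the
  # identity in general, but forward-then-exact-reverse is
  seqs <- c(steps, rev(lapply(steps, function(s) -s)))
  for (s in seqs) for (i in 1:50)
    q <- update_attitude(q, c(0, 0, 0), s, c(0, 0, 0), 0.02, 0, 0)
  expect_lt(2 * acos(min(1, abs(q[1]))) * 180 / pi, 1)
})

test_that("joint angle has the closed-form values and invariances", {
  q <- euler_to_quat(12, -40, 77)
  expect_equal(joint_angle(q, q), 0)
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1))) {
    qb <- quat_mul(q, axis_angle_quat(ax, 90))
    expect_equal(joint_angle(q, qb), 90, tolerance = 1e-9)
    expect_equal(joint_angle(qb, q), 90, tolerance = 1e-9)   # symmetry
    pre <- euler_to_quat(-30, 10, 150)                       # common pre-rotation
    expect_equal(joint_angle(quat_mul(pre, q), quat_mul(pre, qb)), 90,
                 tolerance = 1e-9)
  }
})

test_that("fused joint angles track the generator's programmed excursion", {
  ses <- simulate_session(task_template("S-FE", n_cycles = 4),
                          spasticity_effect(0), distortion_none(), seed = 1,
                          warmup_frames = 300L, cycle_jitter_sd = 0,
                          return_truth = TRUE)
  tr <- attr(ses, "truth")
  fr <- task_frames(ses)
  task_ses <- new_session(fr, ses$task, ses$meta, validate = FALSE)
  pairs <- list(c(0L, 4L), c(4L, 5L))
  att <- list()
  for (imu in unique(unlist(pairs)))
    att[[as.character(imu)]] <- estimate_attitude(task_ses, imu,
                                                  q0 = tr$mounts[[imu + 1L]],
                                                  k_acc = 0.5, k_mag = 0.3)
  for (p in pairs) {
    est <- vapply(seq_len(nrow(fr)), function(i)
      joint_angle(att[[as.character(p[1])]][i, ],
                  att[[as.character(p[2])]][i, ]), numeric(1))
    tru <- vapply(seq_len(nrow(fr)), function(i) {
      qa <- quat_mul(tr$mounts[[p[1] + 1L]],
                     axis_angle_quat(c(1, 0, 0), tr$theta_deg[i, p[1] + 1L]))
      qb <- quat_mul(tr$mounts[[p[2] + 1L]],
                     axis_angle_quat(c(1, 0, 0), tr$theta_deg[i, p[2] + 1L]))
      joint_angle(qa, qb)
    }, numeric(1))
    expect_lt(max(abs(est - tru)), 2)
    expect_true(all(est >= 0 & est <= 180))
  }
})

test_that("the joint map covers the hand and the elbow", {
  jt <- joint_table()
  expect_equal(nrow(jt), 18L)
  expect_true(all(jt$imu_a %in% 0:18) && all(jt$imu_b %in% 0:18))
  expect_equal(jt[jt$joint == "elbow", c("imu_a", "imu_b")],
               data.frame(imu_a = 0L, imu_b = 18L, row.names = 18L))
})
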