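test_that("magnitude is the per-frame Euclidean norm", {
  expect_equal(magnitude(matrix(c(3, 4, 0), 1)), 5)
  expect_equal(magnitude(matrix(0, 1, 3)), 0)
  set.seed(12)
  m <- matrix(rnorm(300), 100)
  expect_equal(magnitude(m), sqrt(m[, 1]^2 + m[, 2]^2 + m[, 3]^2))
})

test_that("time-domain statistics match hand-computed values", {
  x <- c(1, 2, 3, 4, 5)
  td <- time_domain_features(x)
  expect_equal(td[["Mean"]], 3)
  expect_equal(td[["Median"]], 3)
  expect_equal(td[["IQR"]], 2)
  expect_equal(td[["SD"]], sqrt(2.5))
  expect_equal(td[["RMS"]], sqrt(11))
  expect_equal(td[["CV"]], sqrt(2.5) / 3)

  cst <- time_domain_features(rep(4, 10))
  expect_equal(unname(cst), c(4, 4, 0, 0, 0, 4, 0, 0))

  zm <- time_domain_features(c(-1, 1, -1, 1, -1, 1))
  expect_true(is.na(zm[["CV"]]))
  expect_error(time_domain_features(1:3), "at least 4")
})

test_that("time-domain statistics agree with a naive oracle on random series", {
  set.seed(99)
  for (i in 1:100) {
    x <- rnorm(sample(20:200, 1), mean = runif(1, -2, 5), sd = runif(1, 0.1, 3))
    got <- time_domain_features(x)
    want <- naive_td(x)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("spectral peaks recover pure-tone frequency and amplitude", {
  fs <- 50; n <- 500
  t <- (0:(n - 1)) / fs
  A <- 3.2
  fd <- frequency_domain_features(5 + A * sin(2 * pi * 2 * t), fs)
  expect_lt(abs(fd[["Mainfreq1"]] - 2), fs / n + 1e-12)    # within one bin
  expect_lt(abs(fd[["Amp1"]] - A) / A, 0.02)

  two <- 2 * sin(2 * pi * 3 * t) + 1 * sin(2 * pi * 7 * t)
  fd2 <- frequency_domain_features(two, fs)
  expect_lt(abs(fd2[["Mainfreq1"]] - 3), fs / n + 1e-12)
  expect_lt(abs(fd2[["Mainfreq2"]] - 7), fs / n + 1e-12)
  expect_equal(fd2[["Amp1"]] / fd2[["Amp2"]], 2, tolerance = 0.05)

  expect_equal(unname(frequency_domain_features(rep(1, 64), fs)), rep(0, 12))
  expect_error(frequency_domain_features(rnorm(10), fs), "at least 16")
})

test_that("feature vectors have the documented size and naming", {
  cs <- quick_session("CS", n_cycles = 2, seed = 14)
  f_cs <- extract_features(cs)
  expect_length(f_cs, 1140L)
  bs <- quick_session("S-BS", n_cycles = 2, seed = 14)
  f_bs <- extract_features(bs)
  expect_length(f_bs, 1160L)
  expect_equal(sum(startsWith(names(f_bs), "Ball_Offset_")), 20L)
  expect_equal(sum(grepl("_(Mainfreq|Amp)[1-6]$", names(f_cs))), 57L * 12L)
  expect_identical(names(f_cs), feature_names(FALSE))

  p <- parse_feature_name("GyroXYZ_9_SD")
  expect_equal(p, list(sensor = "Gyro", imu = 9L, stat = "SD"))
  expect_equal(parse_feature_name("Ball_Offset_CV")$stat, "CV")
  expect_error(parse_feature_name("GyroXYZ_19_SD"), "unparseable")
  # the name set parses back bijectively
  back <- vapply(feature_names(TRUE), function(nm) {
    q <- parse_feature_name(nm)
    if (q$sensor == "Ball_Offset") paste0("Ball_Offset_", q$stat)
    else paste0(q$sensor, "XYZ_", q$imu, "_", q$stat)
  }, character(1))
  expect_identical(unname(back), feature_names(TRUE))
})

test_that("a ball-squeeze session without pressure is refused", {
  bs <- quick_session("S-BS", n_cycles = 2)
  bs$frames$pressure <- NULL
  expect_error(extract_features(bs), "pressure")
})

test_that("features scale and reverse the way each statistic must", {
  set.seed(55)
  x <- abs(rnorm(256, 5)) + sin(2 * pi * 3 * (0:255) / 50)
  fs <- 50; k <- 3.7
  f1 <- channel_features(x, fs)
  fk <- channel_features(k * x, fs)
  scale_with_k <- c("Mean", "Median", "IQR", "SD", "RMS", paste0("Amp", 1:6))
  invariant <- c("CV", "Skewness", "Kurtosis", paste0("Mainfreq", 1:6))
  expect_equal(fk[scale_with_k], k * f1[scale_with_k], tolerance = 1e-10)
  expect_equal(fk[invariant], f1[invariant], tolerance = 1e-10)
  # time reversal changes no feature (rank-based, moment-based, or spectral)
  fr <- channel_features(rev(x), fs)
  expect_equal(fr, f1, tolerance = 1e-8)
})

test_that("feature tables stack sessions of one task only", {
  s1 <- quick_session("CS", n_cycles = 2, seed = 1)
  s2 <- quick_session("CS", n_cycles = 2, seed = 2, mas = 1)
  ft <- feature_table(list(s1, s2))
  expect_equal(dim(ft), c(2L, 4L + 1140L))
  expect_equal(ft$mas_score, c(0L, 1L))
  s3 <- quick_session("S-BS", n_cycles = 2, seed = 3)
  expect_error(feature_table(list(s1, s3)), "mix tasks")
})
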