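# Shared fixtures and independent oracles, built in code at test time.

# small, fast session: short warm-up, few cycles
quick_session <- function(task = "S-FE", mas = 0L, seed = 1, n_cycles = 5,
                          distortion = distortion_spec(), ...) {
  simulate_session(template = task_template(task, n_cycles = n_cycles),
                   effect = spasticity_effect(mas),
                   distortion = distortion, seed = seed,
                   warmup_frames = 300L, ...)
}

# a random frame row on the packet quantisation grid
grid_frame <- function(with_pressure = FALSE) {
  q <- packet_quantization()
  lsb <- rep(rep(c(q$acc, q$gyro, q$mag), each = 3), 19)
  vals <- sample(-32767:32767, length(lsb), replace = TRUE) * lsb
  fr <- as.data.frame(as.list(stats::setNames(vals, channel_names(FALSE)[-1])))
  fr <- cbind(t = sample(0:10^6, 1) * q$t, fr)
  if (with_pressure) fr$pressure <- sample(0:2^24, 1) * q$pressure
  fr
}

# independent naive recomputation of the 8 time-domain statistics
naive_td <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  med <- stats::median(x)
  qs <- stats::quantile(x, c(0.25, 0.75), type = 7)
  sdv <- sqrt(sum((x - mu)^2) / (n - 1))
  rms <- sqrt(sum(x^2) / n)
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(Mean = mu, Median = med, IQR = unname(qs[2] - qs[1]), SD = sdv,
    CV = sdv / mu, RMS = rms,
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

# brute-force two-sided permutation p-value for the rank-sum statistic
perm_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); n1 <- length(a)
  r <- rank(pooled)
  splits <- utils::combn(n, n1)
  W <- apply(splits, 2, function(idx) sum(r[idx]))
  E <- n1 * mean(r)
  w_obs <- sum(r[seq_len(n1)])
  mean(abs(W - E) >= abs(w_obs - E) - 1e-9)
}

# feature table of a simulated cohort for one task, after calibration
cohort_features <- function(spec, task = "S-FE", warmup = 400L, ...) {
  spec$tasks <- task
  sim <- simulate_cohort(spec, warmup_frames = warmup, ...)
  cal <- lapply(sim$sessions, function(s) calibrate_session(s)$session)
  feature_table(cal)
}
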