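test_that("rank-sum test has the enumerated small-sample values", {
  x <- rnorm(5)
  expect_equal(rank_test_two_groups(x, x), 1)
  expect_equal(rank_test_two_groups(c(1, 2, 3), c(10, 11, 12)), 0.1)
})

test_that("exact rank-sum p equals brute-force enumeration on all small splits", {
  set.seed(17)
  for (n in 4:10) {
    for (n1 in 2:(n - 2)) {
      a <- rnorm(n1); b <- rnorm(n - n1, mean = runif(1, -1, 1))
      expect_equal(rank_test_two_groups(a, b), perm_ranksum_p(a, b),
                   tolerance = 1e-12)
      # ties via rounding exercise the mid-rank path
      a2 <- round(a); b2 <- round(b)
      if (length(unique(c(a2, b2))) > 1)
        expect_equal(rank_test_two_groups(a2, b2), perm_ranksum_p(a2, b2),
                     tolerance = 1e-12)
    }
  }
})

test_that("rank-sum p is symmetric, in (0,1], and monotone-invariant", {
  set.seed(23)
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1))
    p <- rank_test_two_groups(a, b)
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(rank_test_two_groups(b, a), p, tolerance = 1e-12)
    expect_equal(rank_test_two_groups(exp(a), exp(b)), p, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis matches hand-computed H and its exact enumeration", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  p <- kruskal_wallis(g, exact = TRUE)
  # ranks 1..6, rank sums 3, 7, 11 -> H = 12/(6*7)*(9/2+49/2+121/2) - 21
  h_hand <- 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21
  expect_equal(attr(p, "H"), h_hand, tolerance = 1e-12)
  # enumeration over 6!/(2!2!2!) = 90 assignments; the observed split is
  # maximally separated and 3! orderings of the groups tie with it
  expect_equal(as.numeric(p), 6 / 90, tolerance = 1e-12)
  expect_equal(as.numeric(kruskal_wallis(list(c(1, 2), c(1, 2), c(1, 2)))), 1)
  expect_error(kruskal_wallis(list(1:2, numeric(0), 1:2)), "empty")
})

test_that("Kruskal-Wallis chi-square route agrees with the two-group rank test direction", {
  set.seed(41)
  g <- list(rnorm(9), rnorm(2, 3), rnorm(3, 6))
  p_chi <- kruskal_wallis(g)
  expect_lt(as.numeric(p_chi), 0.05)
  p_ex <- kruskal_wallis(g, exact = TRUE)
  expect_lt(as.numeric(p_ex), 0.05)
})

test_that("screening a null table keeps the advertised type-I behaviour", {
  # feature table with pure-noise features and the cohort's 9 vs 5 labels
  set.seed(61)
  n_feat <- 400
  tab <- as.data.frame(matrix(rnorm(14 * n_feat), 14))
  names(tab) <- paste0("GyroXYZ_", rep(0:18, length.out = n_feat), "_",
                       rep(c("Mean", "SD"), each = 200))[1:n_feat]
  # names must be unique and parseable; build from the real name set instead
  names(tab) <- feature_names(FALSE)[seq_len(n_feat)]
  tab <- cbind(data.frame(subject_id = sprintf("p%02d", 1:14),
                          group = "healthy",
                          mas_score = rep(c(0L, 1L), c(9, 5)),
                          task = "CS", stringsAsFactors = FALSE), tab)
  rep <- screen_task(tab)
  rate <- mean(rep$p_values$significant)
  # attainable level of the exact (9,5) two-sided test at 0.05 is ~0.042
  expect_lt(rate, 0.09)
  expect_gt(rate, 0.005)
  expect_true(all(rep$p_values$p_two_group > 0 & rep$p_values$p_two_group <= 1))
})

test_that("two identical groups yield zero significant features", {
  base <- as.data.frame(matrix(rnorm(7 * 40), 14, 40)[rep(1:7, 2), ])
  names(base) <- feature_names(FALSE)[1:40]
  tab <- cbind(data.frame(subject_id = sprintf("q%02d", 1:14), group = "healthy",
                          mas_score = rep(c(0L, 1L), 7), task = "CS",
                          stringsAsFactors = FALSE), base)
  rep <- screen_task(tab)
  expect_equal(sum(rep$p_values$significant), 0L)
})

test_that("selection takes the smallest p with lexicographic tie-break", {
  set.seed(71)
  tab <- data.frame(subject_id = sprintf("r%02d", 1:14), group = "healthy",
                    mas_score = rep(c(0L, 1L, 2L), c(9, 2, 3)), task = "S-BS",
                    stringsAsFactors = FALSE)
  sep <- c(rnorm(9), rnorm(5, 12))          # maximally separated, p ties
  tab$GyroXYZ_9_SD <- sep
  tab$AccXYZ_3_Mean <- sep + rnorm(14, 0, 1e-6)
  tab$MagXYZ_2_RMS <- rnorm(14)
  tab$Ball_Offset_CV <- sep
  rep <- screen_task(tab)
  sel <- rep$selected
  expect_equal(sel$feature[sel$kind == "kinematic"], "AccXYZ_3_Mean")
  expect_equal(sel$feature[sel$kind == "force"], "Ball_Offset_CV")
  expect_true(all(is.finite(sel$p_three_level)))
  expect_lt(sel$p_three_level[1], 0.05)
})

test_that("reports render to disk and round-trip through the reader", {
  s1 <- lapply(1:6, function(i) quick_session("CS", n_cycles = 2, seed = i,
                                              mas = c(0, 0, 0, 1, 2, 2)[i]))
  ft <- feature_table(lapply(s1, function(s) calibrate_session(s)$session))
  rep <- screen_task(ft)
  path <- file.path(withr::local_tempdir(), "rep")
  render_report(rep, path)
  expect_true(all(file.exists(paste0(path, c("_pvalues.csv", "_all_imus.csv",
                                             "_selected.csv", ".json")))))
  back <- read_screening_report(path)
  expect_equal(back$p_values$p_two_group, rep$p_values$p_two_group)
  expect_equal(back$selected$feature, rep$selected$feature)
  expect_equal(back$task, rep$task)
})

test_that("screening refuses degenerate labelings", {
  tab <- data.frame(subject_id = c("a", "b", "c"), group = "healthy",
                    mas_score = c(0L, 0L, 1L), task = "CS",
                    GyroXYZ_0_Mean = rnorm(3), stringsAsFactors = FALSE)
  expect_error(screen_task(tab), "at least 2 subjects")
})
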