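# Nonparametric screening.
#
# With a cohort of this size (nine healthy-equivalent vs five spastic
# subjects) parametric tests are not defensible; features are screened with
# the unpaired two-sample Wilcoxon rank-sum (Mann-Whitney) test, exact by
# full enumeration of group assignments up to combined n = 20 (mid-ranks for
# ties), and the selected features are graded across the three MAS levels
# with the Kruskal-Wallis test. A feature counts as significant at p < 0.05
# with no multiple-testing correction; an optional Benjamini-Hochberg
# adjustment is available but off by default.

# cache of enumerated rank-sum null distributions, keyed by the rank multiset
.rank_null_cache <- new.env(parent = emptyenv())

.ranksum_null <- function(ranks, n1) {
  key <- paste(n1, paste(signif(sort(ranks), 12), collapse = ","), sep = "|")
  hit <- .rank_null_cache[[key]]
  if (!is.null(hit)) return(hit)
  cmb <- utils::combn(length(ranks), n1)
  W <- colSums(matrix(ranks[cmb], nrow = n1))
  assign(key, W, envir = .rank_null_cache)
  W
}

#' Exact two-sample rank-sum test
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum p-value. For combined
#' `n <= exact_max` the null distribution of the rank sum is enumerated over
#' all group assignments (mid-ranks for ties) and the p-value is the null
#' probability of a rank sum at least as far from its expectation as the one
#' observed. Above that, the normal approximation with tie correction
#' (`stats::wilcox.test`) is used.
#'
#' @param a,b numeric samples, each of size >= 2 after dropping missing
#'   values
#' @param exact_max largest combined sample size for the exact enumeration
#' @return two-sided p-value in (0, 1]
#' @export
rank_test_two_groups <- function(a, b, exact_max = 20L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per group")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  n1 <- length(a); n <- length(pooled)
  r <- rank(pooled)
  if (n <= exact_max) {
    W <- .ranksum_null(r, n1)
    E <- n1 * mean(r)
    w_obs <- sum(r[seq_len(n1)])
    mean(abs(W - E) >= abs(w_obs - E) - 1e-9)
  } else {
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  }
}

#' Kruskal-Wallis test across spasticity levels
#'
#' Tie-corrected H statistic with the chi-square reference distribution
#' (`stats::kruskal.test`); optionally, for total n up to `exact_max`, an
#' exact p-value by full enumeration of the multinomial group assignments.
#'
#' @param groups list of >= 3 non-empty numeric vectors
#' @param exact enumerate the permutation null instead of the chi-square
#'   approximation
#' @param exact_max largest total n for which `exact = TRUE` is allowed
#' @return p-value; the H statistic is attached as attribute `"H"`
#' @export
kruskal_wallis <- function(groups, exact = FALSE, exact_max = 14L) {
  stopifnot(length(groups) >= 3)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("empty group in Kruskal-Wallis input")
  x <- unlist(groups, use.names = FALSE)
  if (sum(sizes) < 5) stop("need total n >= 5")
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  if (!exact) {
    p <- kt$p.value
    if (is.nan(p)) p <- 1          # all values identical: H = 0/0 -> no evidence
    return(structure(p, H = if (is.nan(H)) 0 else H))
  }
  n <- sum(sizes)
  if (n > exact_max)
    stop("exact enumeration limited to total n <= ", exact_max)
  r <- rank(x)
  tie_corr <- 1 - sum(table(x)^3 - table(x)) / (n^3 - n)
  if (tie_corr == 0) return(structure(1, H = 0))
  h_of <- function(assign_idx) {
    rs <- vapply(split(r[assign_idx], rep(seq_along(sizes), sizes)),
                 sum, numeric(1))
    (12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)) / tie_corr
  }
  h_obs <- h_of(seq_len(n))
  perms <- .multiset_assignments(n, sizes)
  h_all <- vapply(perms, h_of, numeric(1))
  structure(mean(h_all >= h_obs - 1e-9), H = h_obs)
}

# all ordered partitions of 1..n into groups of the given sizes
.multiset_assignments <- function(n, sizes) {
  rec <- function(remaining, sizes) {
    if (length(sizes) == 1L) return(list(remaining))
    first <- utils::combn(length(remaining), sizes[1], simplify = FALSE)
    out <- list()
    for (idx in first) {
      rest <- rec(remaining[-idx], sizes[-1])
      for (tail in rest)
        out[[length(out) + 1L]] <- c(remaining[idx], tail)
    }
    out
  }
  rec(seq_len(n), sizes)
}

#' Screen one task's feature table
#'
#' For every feature, the two-group rank-sum p-value (healthy-equivalent vs
#' spastic; MAS-0 stroke subjects count as healthy). A feature is significant
#' at `alpha` with no multiple-testing correction unless `adjust = "BH"`. A
#' (sensor, statistic) pair is flagged `all_imus_significant` when the
#' feature is significant for every one of the 19 IMUs. The most significant
#' kinematic (IMU) feature — smallest p, ties broken by lexicographic feature
#' name — is selected per task, plus the most significant pressure-ball
#' feature for ball-squeezing tasks; for the selected features the
#' Kruskal-Wallis p across the three MAS levels is added.
#'
#' @param features a [feature_table()] for one task
#' @param alpha significance level (default 0.05)
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#' @param restrict_to_all_imus restrict selection candidates to features
#'   whose (sensor, statistic) pair is significant for all IMUs
#' @param kw_exact use the exact Kruskal-Wallis enumeration for the selected
#'   features (total n permitting)
#' @return a `screening_report`: list with `task`, `p_values` (data.frame
#'   per feature), `all_imus` (data.frame per sensor x statistic),
#'   `selected` (data.frame), `n_healthy`, `n_spastic`, `alpha`
#' @export
screen_task <- function(features, alpha = 0.05, adjust = c("none", "BH"),
                        restrict_to_all_imus = FALSE, kw_exact = FALSE) {
  adjust <- match.arg(adjust)
  task <- unique(features$task)
  stopifnot(length(task) == 1)
  two_level <- ifelse(features$mas_score >= 1, "spastic", "healthy")
  if (min(table(factor(two_level, c("healthy", "spastic")))) < 2)
    stop("need at least 2 subjects in each two-level group")
  meta_cols <- c("subject_id", "group", "mas_score", "task")
  fnames <- setdiff(names(features), meta_cols)
  p <- vapply(fnames, function(f) {
    a <- features[[f]][two_level == "healthy"]
    b <- features[[f]][two_level == "spastic"]
    if (sum(is.finite(a)) < 2 || sum(is.finite(b)) < 2) return(NA_real_)
    rank_test_two_groups(a, b)
  }, numeric(1))
  p_use <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  sig <- !is.na(p_use) & p_use < alpha
  parsed <- lapply(fnames, parse_feature_name)
  pv <- data.frame(feature = fnames,
                   sensor = vapply(parsed, `[[`, character(1), "sensor"),
                   imu = vapply(parsed, `[[`, integer(1), "imu"),
                   stat = vapply(parsed, `[[`, character(1), "stat"),
                   p_two_group = unname(p), significant = unname(sig),
                   stringsAsFactors = FALSE)
  imu_pv <- pv[pv$sensor != "Ball_Offset", ]
  all_imus <- do.call(rbind, lapply(split(imu_pv, list(imu_pv$sensor, imu_pv$stat)),
                                    function(d) data.frame(
    sensor = d$sensor[1], stat = d$stat[1],
    n_significant = sum(d$significant),
    all_imus_significant = sum(d$significant) == N_IMUS,
    stringsAsFactors = FALSE)))
  rownames(all_imus) <- NULL
  all_imus <- all_imus[order(all_imus$sensor, match(all_imus$stat, ALL_STATS)), ]

  mas_groups <- function(f) {
    split(features[[f]], factor(features$mas_score, 0:2))
  }
  select_from <- function(d) {
    d <- d[!is.na(d$p_two_group), ]
    if (restrict_to_all_imus && any(all_imus$all_imus_significant)) {
      ok <- all_imus[all_imus$all_imus_significant, ]
      d <- d[paste(d$sensor, d$stat) %in% paste(ok$sensor, ok$stat), ]
    }
    if (nrow(d) == 0) return(NULL)
    d <- d[order(d$p_two_group, d$feature), ]
    d[1, ]
  }
  kw_p <- function(f) {
    g <- mas_groups(f)
    if (any(lengths(lapply(g, function(v) v[is.finite(v)])) == 0)) return(NA_real_)
    as.numeric(kruskal_wallis(g, exact = kw_exact))
  }
  sel_rows <- list()
  kin <- select_from(pv[pv$sensor != "Ball_Offset", ])
  if (!is.null(kin))
    sel_rows$kinematic <- data.frame(kind = "kinematic", feature = kin$feature,
                                     p_two_group = kin$p_two_group,
                                     p_three_level = kw_p(kin$feature),
                                     stringsAsFactors = FALSE)
  if (any(pv$sensor == "Ball_Offset")) {
    frc <- select_from(pv[pv$sensor == "Ball_Offset", ])
    if (!is.null(frc))
      sel_rows$force <- data.frame(kind = "force", feature = frc$feature,
                                   p_two_group = frc$p_two_group,
                                   p_three_level = kw_p(frc$feature),
                                   stringsAsFactors = FALSE)
  }
  selected <- if (length(sel_rows)) do.call(rbind, sel_rows) else
    data.frame(kind = character(0), feature = character(0),
               p_two_group = numeric(0), p_three_level = numeric(0))
  rownames(selected) <- NULL
  structure(list(task = task, p_values = pv, all_imus = all_imus,
                 selected = selected,
                 n_healthy = sum(two_level == "healthy"),
                 n_spastic = sum(two_level == "spastic"),
                 alpha = alpha, adjust = adjust),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> task %s: %d features, %d significant at p < %g (%d healthy vs %d spastic)\n",
              x$task, nrow(x$p_values), sum(x$p_values$significant, na.rm = TRUE),
              x$alpha, x$n_healthy, x$n_spastic))
  ai <- x$all_imus[x$all_imus$all_imus_significant, ]
  if (nrow(ai))
    cat("  significant for all IMUs:",
        paste(paste0(ai$sensor, " ", ai$stat), collapse = ", "), "\n")
  if (nrow(x$selected))
    for (i in seq_len(nrow(x$selected)))
      cat(sprintf("  selected %s feature: %s (two-level p = %.4g, three-level p = %.4g)\n",
                  x$selected$kind[i], x$selected$feature[i],
                  x$selected$p_two_group[i], x$selected$p_three_level[i]))
  invisible(x)
}

#' Write a screening report to disk
#'
#' Writes `<path>_pvalues.csv`, `<path>_all_imus.csv`, `<path>_selected.csv`
#' and a JSON bundle `<path>.json` that [read_screening_report()] restores.
#' @param report a `screening_report`
#' @param path file path prefix
#' @return `path`, invisibly
#' @export
render_report <- function(report, path) {
  stopifnot(inherits(report, "screening_report"))
  utils::write.csv(report$p_values, paste0(path, "_pvalues.csv"), row.names = FALSE)
  utils::write.csv(report$all_imus, paste0(path, "_all_imus.csv"), row.names = FALSE)
  utils::write.csv(report$selected, paste0(path, "_selected.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(report), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       na = "null")
  invisible(path)
}

#' Read back a screening report written by [render_report()]
#' @param path file path prefix
#' @return a `screening_report`
#' @export
read_screening_report <- function(path) {
  x <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  for (f in c("p_values", "all_imus", "selected")) x[[f]] <- as.data.frame(x[[f]])
  if (nrow(x$p_values)) x$p_values$imu <- as.integer(x$p_values$imu)
  structure(x, class = "screening_report")
}
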