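test_that("median centering: arithmetic, defining property, scale invariance", {
  expect_equal(as.numeric(median_center(c(2, 4, 8))), c(0.5, 1, 2))
  set.seed(1)
  v <- rlnorm(25)
  expect_equal(median(median_center(v)), 1)
  expect_equal(as.numeric(median_center(v * 17)), as.numeric(median_center(v)))
  expect_error(median_center(c(-1, 0, 1)), "median")
  # subtraction variant and invertibility
  sub <- median_center(v, method = "subtract")
  expect_equal(median(sub), 0)
  expect_equal(as.numeric(sub) + attr(sub, "center"), v)
})

test_that("control normalization and z-scores", {
  set.seed(2)
  v <- rnorm(40, 10, 2)
  z <- zscore(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(zscore(v, ref_sd = 0), "ref_sd")

  ctrl <- rlnorm(30)
  nn <- normalize_to_control(ctrl, mean(ctrl))
  expect_equal(mean(nn), 1, tolerance = 1e-12)
  expect_error(normalize_to_control(ctrl, 0), "control_mean")
  # invertible given stored parameters
  expect_equal(as.numeric(nn) * attr(nn, "control_mean"), ctrl)
})

test_that("z-scored chronic murine profile sits closer to the human-like
           fibrotic profile than the transition stage does", {
  ks_dist <- function(a, b) {
    u <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(u) - ecdf(b)(u)))
  }
  d21 <- iid_mixture(2000, 2, 0.25, 35, 0.3, 0.40, seed = 51)
  d14 <- iid_mixture(2000, 2, 0.25, 28, 0.3, 0.25, seed = 52)
  human <- iid_mixture(2000, 3, 0.25, 40, 0.3, 0.42, seed = 53)
  z <- function(v) as.numeric(zscore(v))
  expect_lt(ks_dist(z(d21), z(human)), ks_dist(z(d14), z(human)))
})

test_that("ROUT flags the gross outlier and respects the null", {
  v <- c(rep(0, 19), 100)
  r <- rout_outliers(v)
  expect_equal(r$outlier_idx, 20L)

  # clean null, scaled to 25 seeds (acceptance runs 100)
  rates <- vapply(1:25, function(s) {
    set.seed(s)
    length(rout_outliers(rnorm(1000))$outlier_idx) / 1000
  }, numeric(1))
  expect_lte(mean(rates), 0.02)

  small <- rout_outliers(rnorm(5))
  expect_length(small$outlier_idx, 0)
  expect_match(small$warning, "n < 10")
})

test_that("ROUT flag set is invariant under affine transforms", {
  set.seed(9)
  v <- c(rnorm(40), 8, -7)
  base <- rout_outliers(v)$outlier_idx
  expect_identical(rout_outliers(3.7 * v - 11)$outlier_idx, base)
  expect_identical(rout_outliers(-0.2 * v + 5)$outlier_idx, base)
})

test_that("group tests choose methods, map stars, and handle degenerate input", {
  expect_equal(significance_stars(c(0.004, 0.03, 2e-4, 5e-5, 0.2)),
               c("**", "*", "***", "****", "ns"))

  set.seed(4)
  a <- rnorm(30); b <- a   # identical groups
  rep_same <- group_tests(c(a, b), rep(c("g1", "g2"), each = 30))
  expect_gt(rep_same$p[1], 0.9)
  expect_equal(rep_same$stars[1], "ns")

  # two normals 3 sd apart: **** tier expected almost always (10 seeds here)
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    x <- rnorm(30); y <- rnorm(30, 3)
    group_tests(c(x, y), rep(c("a", "b"), each = 30))$p[1] < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  tiny <- group_tests(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_match(tiny$method[1], "skipped")

  # multi-group non-parametric path emits Kruskal-Wallis + Dunn rows
  set.seed(5)
  v <- c(rlnorm(20), rlnorm(20, 1), rlnorm(20, 2))
  g <- rep(c("a", "b", "c"), each = 20)
  rep3 <- group_tests(v, g)
  expect_true("Kruskal-Wallis" %in% rep3$method)
  expect_equal(sum(rep3$method == "Dunn post hoc"), 3)
})

test_that("exact Spearman reproduces the printed six-pair example", {
  r <- spearman_exact(1:6, c(2, 1, 3, 4, 6, 5))
  expect_equal(round(r$rho, 3), 0.886)
  expect_equal(round(r$p_two_sided, 4), 0.0333)
  expect_equal(r$method, "exact-permutation")
})

test_that("exact Spearman p equals independent DFS enumeration for n <= 7", {
  cases <- list(
    list(x = 1:4, y = c(2, 1, 4, 3)),
    list(x = 1:5, y = c(1, 3, 2, 5, 4)),
    list(x = 1:6, y = 6:1),
    list(x = 1:7, y = c(3, 1, 2, 7, 4, 6, 5))
  )
  for (cs in cases) {
    r <- spearman_exact(cs$x, cs$y)
    rx <- rank(cs$x); ry <- rank(cs$y)
    s_obs <- sum((rx - ry)^2)
    tail <- dfs_spearman_tail(length(cs$x), s_obs, lower = r$rho >= 0)
    expect_equal(r$p_two_sided,
                 min(1, 2 * tail / factorial(length(cs$x))))
  }
})

test_that("Spearman symmetries, concordance tail, and tie handling", {
  x <- c(3, 9, 1, 7, 5, 11)
  y <- c(4, 10, 2, 9, 6, 12)
  expect_equal(spearman_exact(x, y)$rho, spearman_exact(y, x)$rho)
  expect_equal(spearman_exact(x, -y)$rho, -spearman_exact(x, y)$rho)

  conc <- spearman_exact(1:6, 2 * (1:6))
  expect_equal(conc$rho, 1)
  expect_equal(conc$p_two_sided, 2 / factorial(6))

  tied <- spearman_exact(c(1, 1, 2, 3, 4), c(2, 3, 3, 5, 7))
  expect_equal(tied$method, "asymptotic")
  expect_match(tied$note, "ties")

  const <- spearman_exact(rep(1, 5), 1:5)
  expect_true(is.na(const$rho))
  expect_equal(const$method, "undefined")
})

test_that("delta-delta-Ct arithmetic", {
  expect_equal(ddct_fold_change(20, 18, 22, 20)$fold_change, 1)
  expect_equal(ddct_fold_change(20, 21, 22, 22)$fold_change, 2)
  r <- ddct_fold_change(25, 20, 28, 20)
  expect_equal(r$ddct, -3)
  expect_equal(r$fold_change, 8)
  expect_error(ddct_fold_change(-1, 20, 28, 20), "positive")
})

test_that("stage correlation: coupled, decoupled, and degenerate cohorts", {
  # coupled day-21-like cohort at n = 6: rho >= 0.8 in >= 90% of seeds
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    sev <- rnorm(6, 0, 1)
    df <- data.frame(specimen_id = paste0("s", 1:6),
                     collagen_fraction = 0.1 + 0.05 * sev + rnorm(6, 0, 0.004),
                     mean_E_kpa = 5 + 3 * sev + rnorm(6, 0, 0.25),
                     timepoint_days = 21)
    stage_correlation(df)$rho >= 0.8
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # decoupled day-3-like cohort: |rho| median < 0.5
  rhos <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    df <- data.frame(specimen_id = paste0("s", 1:6),
                     collagen_fraction = runif(6, 0.01, 0.05),
                     mean_E_kpa = rlnorm(6, log(3), 0.3),
                     timepoint_days = 3)
    abs(stage_correlation(df)$rho)
  }, numeric(1))
  expect_lt(median(rhos), 0.5)

  skip_row <- stage_correlation(data.frame(
    specimen_id = c("a", "b", "c"), collagen_fraction = c(0.1, 0.2, 0.3),
    mean_E_kpa = c(1, 2, 3), timepoint_days = 14))
  expect_match(skip_row$note, "n < 4")

  const_row <- stage_correlation(data.frame(
    specimen_id = letters[1:5], collagen_fraction = rep(0.2, 5),
    mean_E_kpa = 1:5, timepoint_days = 21))
  expect_true(is.na(const_row$rho))
  expect_match(const_row$note, "constant")
})
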