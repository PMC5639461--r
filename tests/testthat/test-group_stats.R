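random_rm_table <- function(n_per = 3, n_levels = 4, effect = 0) {
  tab <- expand.grid(subject = paste0("s", seq_len(2 * n_per)),
                     level = paste0("L", seq_len(n_levels)),
                     stringsAsFactors = FALSE)
  tab$genotype <- ifelse(tab$subject %in% paste0("s", seq_len(n_per)),
                         "WT", "MUT")
  tab$value <- rnorm(nrow(tab)) +
    effect * (tab$genotype == "MUT") * (tab$level == "L1")
  tab
}

test_that("ANOVA sums of squares match the mean-decomposition oracle", {
  set.seed(61)
  for (i in 1:10) {
    tab <- random_rm_table(n_per = sample(2:4, 1),
                           n_levels = sample(2:4, 1))
    res <- two_way_rm_anova(tab)
    ss <- setNames(res$effects$SS, res$effects$effect)
    expect_equal(ss, oracle_rm_anova_ss(tab)[names(ss)],
                 tolerance = 1e-10)
    expect_equal(sum(res$effects$pct_variation), 100, tolerance = 1e-10)
  }
})

test_that("ANOVA degrees of freedom follow the mixed design", {
  set.seed(62)
  tab <- random_rm_table(n_per = 6, n_levels = 4)
  res <- two_way_rm_anova(tab)
  df <- setNames(res$effects$df, res$effects$effect)
  expect_equal(unname(df["genotype"]), 1)
  expect_equal(unname(df["subject"]), 10)
  expect_equal(unname(df["level"]), 3)
  expect_equal(unname(df["genotype:level"]), 3)
  expect_equal(unname(df["residual"]), 30)
})

test_that("Bonferroni adjustment is min(1, k * raw) and never below raw", {
  set.seed(63)
  tab <- random_rm_table(n_levels = 4)
  res <- two_way_rm_anova(tab)
  expect_equal(res$posthoc$P_bonferroni,
               pmin(1, 4 * res$posthoc$P_raw))
  expect_true(all(res$posthoc$P_bonferroni >= res$posthoc$P_raw))
})

test_that("missing cells are an error, not imputed", {
  set.seed(64)
  tab <- random_rm_table()
  expect_error(two_way_rm_anova(tab[-1, ]), "unbalanced")
})

test_that("Welch test matches the closed-form computation", {
  set.seed(65)
  a <- rnorm(8, 10, 2); b <- rnorm(12, 12, 4)
  res <- welch_t_test(a, b)
  se2a <- var(a) / length(a); se2b <- var(b) / length(b)
  t_manual <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df_manual <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$df, df_manual, tolerance = 1e-12)
  expect_equal(res$P, 2 * pt(-abs(t_manual), df_manual),
               tolerance = 1e-12)
})

test_that("Welch degenerate conventions", {
  expect_equal(welch_t_test(c(5, 5, 5), c(5, 5, 5))$P, 1)
  strong <- welch_t_test(c(100.0, 100.1, 99.9), c(1.0, 1.1, 0.9))
  expect_lt(strong$P, 1e-6)
})

test_that("log-scale t test reports geometric means and is scale invariant", {
  expect_equal(log_geomean_t_test(c(1, 100), c(1, 100))$P, 1)
  expect_equal(log_geomean_t_test(c(1, 100), c(2, 50))$geomean_a, 10)
  set.seed(66)
  a <- rlnorm(10, 1, 0.5); b <- rlnorm(10, 1.5, 0.5)
  r1 <- log_geomean_t_test(a, b)
  r2 <- log_geomean_t_test(37 * a, 37 * b)
  expect_equal(r1$t, r2$t, tolerance = 1e-12)
  expect_equal(r1$P, r2$P, tolerance = 1e-12)
  expect_error(log_geomean_t_test(c(1, -1), c(1, 2)), "positive")
})

test_that("skew-normal comparison has the documented df and nesting", {
  set.seed(67)
  a <- rskewnorm(400, 10, 3, 4)
  b <- rskewnorm(400, 12, 3, 4)
  cmp <- compare_distributions_skewnormal(a, b, n_bins = 21)
  expect_equal(cmp$df1, 3L)
  expect_equal(cmp$df2, 36L)  # 2*21 bins - 6 fitted parameters
  expect_true(cmp$converged)
  expect_gte(cmp$ss_pooled, cmp$ss_separate)
  # relabeling groups leaves F unchanged
  cmp2 <- compare_distributions_skewnormal(b, a, n_bins = 21)
  expect_equal(cmp$F, cmp2$F, tolerance = 1e-6)
})

test_that("skew-normal comparison separates shifted populations", {
  set.seed(68)
  null_ok <- 0; shift_hit <- 0; n_rep <- 40
  for (r in seq_len(n_rep)) {
    a <- rskewnorm(500, 10, 3, 4)
    b <- rskewnorm(500, 10, 3, 4)
    cmp <- compare_distributions_skewnormal(a, b)
    if (cmp$converged && cmp$P > 0.05) null_ok <- null_ok + 1
    a2 <- rskewnorm(500, 10, 3, 4)
    b2 <- rskewnorm(500, 11.5, 3, 4)
    cmp2 <- compare_distributions_skewnormal(a2, b2)
    if (cmp2$converged && cmp2$P < 0.01) shift_hit <- shift_hit + 1
  }
  # the histogram least-squares F test runs mildly anti-conservative
  # (correlated multinomial bin errors), so the null band is wide
  expect_gte(null_ok, 0.7 * n_rep)
  expect_gte(shift_hit, 0.9 * n_rep)
})

test_that("rise-time exclusion keeps exactly the fast events", {
  ev <- data.frame(amplitude = 1:6,
                   rise_time_ms = c(1, 2, 2.01, 3, 0.5, 1.99))
  kept <- filter_events_by_rise_time(ev)
  expect_equal(kept$amplitude, c(1, 2, 5, 6))
  expect_equal(nrow(filter_events_by_rise_time(
    data.frame(rise_time_ms = rep(3, 5)))), 0L)
  all_fast <- data.frame(rise_time_ms = rep(1, 5))
  expect_equal(nrow(filter_events_by_rise_time(all_fast)), 5L)
  # oracle count on a mixed set
  set.seed(69)
  mixed <- data.frame(rise_time_ms = runif(500, 0, 4))
  expect_equal(nrow(filter_events_by_rise_time(mixed)),
               sum(mixed$rise_time_ms <= 2))
})
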