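test_that("a pure 24-h square wave peaks at 24 h", {
  x <- rep(rep(c(0, 1), each = 12), 28)  # 28 days hourly
  pg <- chi_square_periodogram(x, c(16, 120), analysis_bin_s = 3600)
  expect_equal(pg$period_h[which.max(pg$Qp)], 24)
  est <- estimate_tau(pg, c(16, 120))
  expect_equal(est$tau_h, 24)
  expect_true(est$significant)
})

test_that("a constant series has Qp = 0 everywhere", {
  pg <- chi_square_periodogram(rep(5, 800), c(16, 60),
                               analysis_bin_s = 3600)
  expect_true(all(pg$Qp == 0))
})

test_that("the significance line increases with degrees of freedom", {
  pg <- chi_square_periodogram(rnorm(800), c(10, 60),
                               analysis_bin_s = 3600)
  expect_true(all(diff(pg$threshold) > 0))
  expect_equal(pg$df, pg$period_bins - 1L)
})

test_that("Qp is invariant under affine rescaling of the series", {
  set.seed(41)
  x <- rep(rep(c(0, 1), each = 12), 20) + rnorm(480, 0, 0.3)
  pg1 <- chi_square_periodogram(x, c(16, 48), analysis_bin_s = 3600)
  pg2 <- chi_square_periodogram(7 * x - 3, c(16, 48),
                                analysis_bin_s = 3600)
  expect_equal(pg1$Qp, pg2$Qp, tolerance = 1e-12)
})

test_that("concatenated repetitions of a periodic signal keep the argmax", {
  set.seed(42)
  base <- rep(rep(c(0, 1), each = 12), 10) + rnorm(240, 0, 0.2)
  # search below the first period multiple: folding at 2x the true
  # period also separates phases perfectly, as for any chi-square
  # periodogram, so multiples are excluded from the range
  for (k in 2:3) {
    pg <- chi_square_periodogram(rep(base, k), c(16, 36),
                                 analysis_bin_s = 3600)
    expect_equal(pg$period_h[which.max(pg$Qp)], 24)
  }
})

test_that("a 12-h harmonic outside the search range is not returned", {
  x <- rep(sin(2 * pi * (0:23) / 24) + 0.5 * sin(2 * pi * (0:23) / 12), 28)
  pg <- chi_square_periodogram(x, c(8, 48), analysis_bin_s = 3600)
  est <- estimate_tau(pg, c(20, 28))
  expect_equal(est$tau_h, 24)
})

test_that("white noise is called arrhythmic", {
  set.seed(43)
  # majority of pure-noise series yield no significant tau
  res <- vapply(1:20, function(i) {
    pg <- chi_square_periodogram(rnorm(960), c(20, 28),
                                 analysis_bin_s = 3600)
    is.na(estimate_tau(pg)$tau_h)
  }, logical(1))
  expect_gte(sum(res), 15)
})

test_that("tau ties break toward the shorter period", {
  pg <- chi_square_periodogram(rep(rep(c(0, 1), each = 12), 28),
                               c(16, 48), analysis_bin_s = 3600)
  # duplicate the maximum at a longer period by hand
  i <- which.max(pg$Qp)
  pg$Qp[i + 5] <- pg$Qp[i]
  pg$threshold[i + 5] <- 0
  expect_equal(estimate_tau(pg, c(16, 48))$tau_h, pg$period_h[i])
})

test_that("series too short for the period range are rejected", {
  expect_error(chi_square_periodogram(rnorm(100), c(20, 60),
                                      analysis_bin_s = 3600),
               "too short")
})

test_that("double-plot layout pairs consecutive days and pads the end", {
  x <- seq_len(3 * 240)  # 3 days at 6-min bins
  m <- double_plot_actogram(x, modulo_h = 24, analysis_bin_s = 360)
  expect_equal(dim(m), c(3, 480))
  # row 1 right half equals row 2 left half (day 2 plotted twice)
  expect_equal(m[1, 241:480], m[2, 1:240])
  # last row right half is padding
  expect_true(all(is.na(m[3, 241:480])))
  expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1))
  expect_error(double_plot_actogram(numeric(0)), "empty")
  expect_error(double_plot_actogram(seq_len(100), modulo_h = 24,
                                    analysis_bin_s = 360), "two days")
})

test_that("folding at the true tau minimises column variance of the actogram", {
  sched <- lighting_schedule("DD", lux = 0.5, days = 10)
  spec <- mouse_cohort_spec(n_per_genotype = 1, genotypes = "WT",
                            intrinsic_tau_h = 25, aschoff_slope = 0,
                            seed = 44)
  tr <- simulate_mouse_activity(spec, sched)[[1]]
  col_var <- function(modulo) {
    m <- double_plot_actogram(tr, modulo_h = modulo)
    mean(apply(m[, seq_len(ncol(m) / 2)], 2, stats::var, na.rm = TRUE))
  }
  # the free-running trace lines up vertically at its own tau
  expect_lt(col_var(25), col_var(24))
  expect_lt(col_var(25), col_var(26))
})

test_that("tau-adjusted activity follows the 24/tau rescaling", {
  tr <- activity_trace(rep(10, 8640))
  expect_equal(tau_adjusted_daily_activity(tr, 24)$value, 10)
  expect_equal(tau_adjusted_daily_activity(tr, 25)$value, 9.6)
  expect_equal(tau_adjusted_daily_activity(tr, 12)$value, 20)
  unadj <- tau_adjusted_daily_activity(tr, NA)
  expect_false(unadj$adjusted)
  expect_equal(unadj$value, 10)
})

test_that("light_response_table excludes short blocks and absent coverage", {
  sched <- lighting_schedule(c("DD", "LL"), lux = c(0.5, 100),
                             days = c(10, 5))
  spec <- mouse_cohort_spec(n_per_genotype = 2, genotypes = "WT",
                            seed = 45)
  traces <- simulate_mouse_activity(spec, sched)
  expect_warning(lrt <- light_response_table(traces, sched),
                 "shorter than 9 days")
  expect_true(all(lrt$block == 1))
  expect_equal(nrow(lrt), 2)
})
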