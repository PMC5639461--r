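test_that("equal specs and seeds give bit-identical cohorts", {
  sched <- lighting_schedule("LD", lux = 150, days = 2)
  spec <- mouse_cohort_spec(n_per_genotype = 2, seed = 51)
  a <- simulate_mouse_activity(spec, sched)
  b <- simulate_mouse_activity(spec, sched)
  for (i in seq_along(a)) expect_identical(a[[i]]$values, b[[i]]$values)
  d1 <- simulate_sleep_diary(diary_spec(seed = 51))
  d2 <- simulate_sleep_diary(diary_spec(seed = 51))
  expect_identical(d1$asleep, d2$asleep)
})

test_that("traces have the exact bin count and every bin is one state", {
  sched <- lighting_schedule(c("LD", "DD"), lux = c(150, 0.5),
                             days = c(2, 3))
  spec <- mouse_cohort_spec(n_per_genotype = 1, seed = 52)
  for (tr in simulate_mouse_activity(spec, sched)) {
    expect_equal(length(tr$values), 5 * 8640)
    expect_true(all(tr$values >= 0 & tr$values <= 100))
    active_bins <- sum(tr$values > 0)
    immobile_bins <- sum(tr$values == 0)
    expect_identical(active_bins + immobile_bins, length(tr$values))
  }
})

test_that("degenerate cohort specs are rejected", {
  expect_error(mouse_cohort_spec(n_per_genotype = 0), "n_per_genotype")
  expect_error(mouse_cohort_spec(brief_bout_deficit = 0), "deficit")
  expect_error(mouse_cohort_spec(brief_bout_deficit = 1.2), "deficit")
  expect_error(mouse_cohort_spec(activity_mix = c(-1, 1, 1, 1)),
               "weights")
  expect_error(mouse_cohort_spec(bin_seconds = 7), "divide 60")
})

test_that("nocturnal generator puts most activity in the dark", {
  sched <- lighting_schedule("LD", lux = 150, days = 7)
  spec <- mouse_cohort_spec(n_per_genotype = 6, genotypes = "WT",
                            nocturnality = 2, seed = 53)
  traces <- simulate_mouse_activity(spec, sched)
  dark_dominant <- vapply(traces, function(tr) {
    dk <- is_dark_at(sched, trace_times(tr))
    mean(tr$values[dk]) > mean(tr$values[!dk])
  }, logical(1))
  expect_gte(sum(dark_dominant), 5)
})

test_that("lower brief_bout_deficit strictly lowers sub-minute bout counts", {
  sched <- lighting_schedule("LD", lux = 150, days = 2)
  count_brief <- function(deficit, seed) {
    spec <- mouse_cohort_spec(n_per_genotype = 1, genotypes = "M",
                              brief_bout_deficit = deficit, seed = seed)
    tr <- simulate_mouse_activity(spec, sched)[[1]]
    ct <- categorize_bouts(segment_activity_bouts(tr))$length_counts
    ct$count[1]
  }
  seeds <- 1:50
  full <- vapply(seeds, function(s) count_brief(1, s), numeric(1))
  reduced <- vapply(seeds, function(s) count_brief(0.5, s), numeric(1))
  expect_lt(mean(reduced), mean(full))
  # the planted effect should be near the nominal 50% on average
  expect_lt(mean(reduced) / mean(full), 0.8)
})

test_that("tau estimates are non-decreasing in lux when slope is positive", {
  sched <- lighting_schedule(c("DD", "LL", "LL", "LL"),
                             lux = c(0.5, 10, 100, 500), days = 9)
  spec <- mouse_cohort_spec(n_per_genotype = 2, genotypes = "WT",
                            intrinsic_tau_h = 23.6, aschoff_slope = 0.5,
                            seed = 54)
  traces <- simulate_mouse_activity(spec, sched)
  lrt <- light_response_table(traces, sched)
  for (d in split(lrt, lrt$subject)) {
    expect_false(is.unsorted(d$tau_h[order(d$lux)]))
  }
})

test_that("diaries hit the requested duty cycle and length", {
  d <- simulate_sleep_diary(diary_spec(cycle_length_h = 72,
                                       sleep_fraction = 0.35, days = 28,
                                       seed = 55))
  expect_equal(length(d$asleep), 28 * 24)
  expect_lt(abs(mean(d$asleep) - 0.35), 0.035)
})

test_that("degenerate diary specs are rejected", {
  expect_error(diary_spec(sleep_fraction = 0), "sleep_fraction")
  expect_error(diary_spec(cycle_length_h = 20), "cycle_length_h")
  expect_error(diary_spec(days = 14), "27 or 28")
  expect_error(diary_spec(resolution_h = 0.5), "hourly")
})

test_that("a 24-h diary cycle folds back to a 24-h peak", {
  d <- simulate_sleep_diary(diary_spec(cycle_length_h = 24,
                                       sleep_fraction = 0.4, days = 28,
                                       jitter_sdlog = 0.01, seed = 56))
  # search below the 48-h multiple (periodogram scores all multiples of
  # a true period)
  pg <- chi_square_periodogram(d$asleep, c(16, 40), analysis_bin_s = 3600)
  expect_equal(estimate_tau(pg, c(16, 40))$tau_h, 24, tolerance = 0.05)
})

test_that("planted pedigree variants round-trip their inheritance model", {
  # one planted X-linked candidate among background
  toy <- make_toy_pedigree_vcf(pedigree_vcf_spec(
    100, planted = data.frame(model = "x_linked"), seed = 57))
  cands <- run_full_filter(toy$records, toy$pedigree)$candidates
  expect_equal(unname(candidate_counts(cands)), c(0L, 0L, 1L, 0L))
  expect_equal(paste0(cands$x_linked$chrom, ":", cands$x_linked$pos),
               toy$planted_keys)
  # nothing planted -> empty candidate lists
  toy0 <- make_toy_pedigree_vcf(pedigree_vcf_spec(100, seed = 58))
  expect_equal(sum(candidate_counts(
    run_full_filter(toy0$records, toy0$pedigree)$candidates)), 0L)
  # compound-het pair: one allele per parent, one gene-level candidate
  toy2 <- make_toy_pedigree_vcf(pedigree_vcf_spec(
    100, planted = data.frame(model = c("compound_het", "compound_het"),
                              gene = c("CHGENE", "CHGENE")), seed = 59))
  cands2 <- run_full_filter(toy2$records, toy2$pedigree)$candidates
  expect_equal(length(cands2$compound_het), 1L)
  expect_equal(nrow(cands2$compound_het$CHGENE), 2L)
  expect_equal(sum(cands2$compound_het$CHGENE$gt_father == "0/1"), 1L)
  expect_equal(sum(cands2$compound_het$CHGENE$gt_mother == "0/1"), 1L)
})

test_that("recessive and X-linked plants stay in their own models", {
  toy <- make_toy_pedigree_vcf(pedigree_vcf_spec(
    50, planted = data.frame(model = c("recessive", "x_linked")),
    seed = 60))
  cands <- run_full_filter(toy$records, toy$pedigree)$candidates
  expect_equal(nrow(cands$recessive), 1L)
  expect_equal(nrow(cands$x_linked), 1L)
  expect_equal(nrow(cands$shared_denovo), 0L)
  expect_false(cands$recessive$chrom %in% c("X"))
  expect_equal(cands$x_linked$chrom, "X")
})

test_that("dose-response tables obey the model and are reproducible", {
  d <- simulate_dose_response(ec50_mM = 0.53, noise_sd = 0,
                              concentrations_mM = c(0.01, 0.1, 0.53, 5, 10))
  # response at the EC50 is (top + bottom) / 2
  expect_equal(d$response[d$concentration_mM == 0.53], 0.5)
  # matches the independent closed form everywhere
  expect_equal(d$response,
               oracle_dose_response(d$concentration_mM, 0, 1, 0.53),
               tolerance = 1e-12)
  n1 <- simulate_dose_response(noise_sd = 0.05, seed = 8)
  n2 <- simulate_dose_response(noise_sd = 0.05, seed = 8)
  expect_identical(n1$response, n2$response)
  expect_error(simulate_dose_response(concentrations_mM = c(1, 2, 5, 10)),
               "span")
})
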