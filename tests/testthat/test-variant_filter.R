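base_record <- function(...) {
  args <- list(...)
  rec <- data.frame(
    chrom = "7", pos = 1000L, ref = "G", alt = "A", gene = "GENE1",
    consequence = "nonsynonymous SNV",
    af_1000g = 0, af_esp = 0, af_gnomad = 0,
    gnomad_hom_hemi = FALSE, cohort_hets = 0L, cohort_hom_hemi = 0L,
    gt_father = "0/0", gt_mother = "0/0", gt_son1 = "0/1",
    gt_son2 = "0/1",
    gll_father = -9.9, gll_mother = -9.9, gll_son1 = -9.9,
    gll_son2 = -9.9,
    planted_model = NA_character_, stringsAsFactors = FALSE)
  for (nm in names(args)) rec[[nm]] <- args[[nm]]
  rec
}

test_that("consequence whitelist keeps protein-altering classes only", {
  recs <- rbind(base_record(consequence = "synonymous SNV"),
                base_record(consequence = "stopgain", pos = 2000L),
                base_record(consequence = "intronic", pos = 3000L),
                base_record(consequence = "splice site", pos = 4000L))
  out <- filter_consequence(recs)
  expect_equal(out$pos, c(2000L, 4000L))
  expect_equal(nrow(filter_consequence(recs[0, ])), 0L)
  expect_warning(filter_consequence(base_record(consequence = NA)),
                 "without consequence")
})

test_that("frequency filter applies the strict > 0.005 rule", {
  recs <- rbind(base_record(af_1000g = 0.006),
                base_record(af_1000g = 0.005, pos = 2000L),
                base_record(af_esp = 0.02, pos = 3000L),
                base_record(pos = 4000L))
  out <- filter_frequency(recs)
  expect_equal(out$pos, c(2000L, 4000L))  # 0.005 exactly is retained
})

test_that("cohort and gnomAD carrier rules", {
  recs <- rbind(base_record(cohort_hets = 6L),
                base_record(cohort_hets = 5L, pos = 2000L),
                base_record(cohort_hom_hemi = 1L, pos = 3000L),
                base_record(gnomad_hom_hemi = TRUE, pos = 4000L))
  out <- filter_frequency(recs)
  expect_equal(out$pos, 2000L)  # five heterozygotes are allowed, six are not
})

test_that("inheritance models require their exact genotype patterns", {
  ped <- quartet_pedigree()
  x_ok <- base_record(chrom = "X", gt_father = "0", gt_mother = "0/1",
                      gt_son1 = "1", gt_son2 = "1")
  rec_ok <- base_record(gt_father = "0/1", gt_mother = "0/1",
                        gt_son1 = "1/1", gt_son2 = "1/1", pos = 2000L)
  dn_ok <- base_record(pos = 3000L)  # default pattern is shared de novo
  cands <- apply_inheritance_models(rbind(x_ok, rec_ok, dn_ok), ped)
  expect_equal(nrow(cands$x_linked), 1L)
  expect_equal(cands$x_linked$chrom, "X")
  expect_equal(nrow(cands$recessive), 1L)
  expect_equal(cands$recessive$pos, 2000L)
  expect_equal(nrow(cands$shared_denovo), 1L)
  expect_equal(cands$shared_denovo$pos, 3000L)
})

test_that("de novo candidates need confident calls in all four members", {
  ped <- quartet_pedigree()
  # GLL ratio -4 in one member (threshold is < -5) -> excluded
  weak <- base_record(gll_mother = -4)
  expect_equal(nrow(apply_inheritance_models(weak, ped)$shared_denovo), 0L)
  borderline <- base_record(gll_father = -5)
  expect_equal(nrow(apply_inheritance_models(borderline, ped)$shared_denovo),
               0L)
  confident <- base_record(gll_father = -5.1)
  expect_equal(nrow(apply_inheritance_models(confident, ped)$shared_denovo),
               1L)
  # absent likelihoods make the record ineligible, not an error
  no_pl <- base_record(gll_son1 = NA)
  expect_equal(nrow(apply_inheritance_models(no_pl, ped)$shared_denovo), 0L)
})

test_that("compound het needs one allele from each parent in one gene", {
  ped <- quartet_pedigree()
  from_f <- base_record(gt_father = "0/1", gt_mother = "0/0")
  from_m <- base_record(gt_father = "0/0", gt_mother = "0/1", pos = 2000L)
  both_m <- base_record(gt_father = "0/0", gt_mother = "0/1", pos = 3000L)
  # trans pair -> candidate
  cands <- apply_inheritance_models(rbind(from_f, from_m), ped)
  expect_equal(length(cands$compound_het), 1L)
  # two variants both inherited from the mother -> no candidate
  cands2 <- apply_inheritance_models(rbind(from_m, both_m), ped)
  expect_equal(length(cands2$compound_het), 0L)
  # trans pair split across two genes -> no candidate
  from_m_g2 <- base_record(gt_father = "0/0", gt_mother = "0/1",
                           pos = 4000L, gene = "GENE2")
  cands3 <- apply_inheritance_models(rbind(from_f, from_m_g2), ped)
  expect_equal(length(cands3$compound_het), 0L)
})

test_that("missing genotypes make a record ineligible without error", {
  ped <- quartet_pedigree()
  rec <- base_record(gt_father = "./.")
  cands <- apply_inheritance_models(rec, ped)
  expect_equal(sum(candidate_counts(cands)), 0L)
})

test_that("filter stages are monotone subsets and order-independent", {
  set.seed(71)
  toy <- make_toy_pedigree_vcf(pedigree_vcf_spec(
    200, planted = data.frame(model = c("x_linked", "recessive")),
    seed = 71))
  recs <- toy$records
  cfg <- filter_config()
  a <- filter_frequency(filter_consequence(recs, cfg), cfg)
  b <- filter_consequence(filter_frequency(recs, cfg), cfg)
  key <- function(d) sort(paste(d$chrom, d$pos))
  expect_equal(key(a), key(b))
  expect_lte(nrow(a), nrow(recs))
})

test_that("the funnel is additive and ends at the planted candidates", {
  toy <- make_toy_pedigree_vcf(pedigree_vcf_spec(
    300, planted = data.frame(model = "x_linked"), seed = 72))
  res <- run_full_filter(toy$records, toy$pedigree)
  f <- res$funnel
  expect_equal(f$records_in - f$removed, f$records_out)
  expect_equal(f$records_out[f$stage == "inheritance"], 1)
  expect_equal(sum(candidate_counts(res$candidates)), 1L)
})
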