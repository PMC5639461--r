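#' Variant filter configuration
#'
#' The candidate-variant prioritisation rules for a family quartet:
#' protein-altering consequence classes only; population allele frequency
#' at most 0.005 in each reference panel (strictly greater is excluded, so
#' a frequency of exactly 0.005 is retained; an absent annotation counts
#' as novel, i.e. 0); no homozygote/hemizygote carriers and at most five
#' heterozygotes in the internal sequencing cohort; no homozygotes or
#' hemizygotes in gnomAD; and, for shared-de-novo candidates, a genotype
#' log-likelihood ratio below -5 (log10 units; see [read_vcf()] for the
#' ratio's orientation) in all four family members.
#'
#' @param max_af maximum population allele frequency (default 0.005).
#' @param max_cohort_hets maximum internal-cohort heterozygote count
#'   (default 5).
#' @param disallow_cohort_hom_hemi exclude variants with any internal
#'   hom/hemi carrier (default `TRUE`).
#' @param disallow_gnomad_hom_hemi exclude variants seen hom/hemi in
#'   gnomAD (default `TRUE`).
#' @param consequence_whitelist protein-altering consequence classes.
#' @param denovo_gll_threshold GLL-ratio cutoff for de novo candidates
#'   (default -5; must be negative).
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_af = 0.005,
                          max_cohort_hets = 5,
                          disallow_cohort_hom_hemi = TRUE,
                          disallow_gnomad_hom_hemi = TRUE,
                          consequence_whitelist = .consequence_whitelist,
                          denovo_gll_threshold = -5) {
  if (max_af < 0 || max_af > 1) stop("max_af must be in [0, 1]")
  if (denovo_gll_threshold >= 0)
    stop("denovo_gll_threshold must be negative")
  structure(list(max_af = max_af,
                 max_cohort_hets = max_cohort_hets,
                 disallow_cohort_hom_hemi = disallow_cohort_hom_hemi,
                 disallow_gnomad_hom_hemi = disallow_gnomad_hom_hemi,
                 consequence_whitelist = consequence_whitelist,
                 denovo_gll_threshold = denovo_gll_threshold),
            class = "filter_config")
}

#' Keep protein-altering variants
#'
#' Retains records whose consequence class is on the whitelist
#' (nonsynonymous SNV, stop gain/loss, frameshift or inframe indel,
#' splice site).  Records with a missing consequence annotation are
#' dropped with a warning (and counted in the funnel).
#'
#' @param records variant-record data frame.
#' @param cfg a [filter_config()].
#' @return the passing subset.
#' @export
filter_consequence <- function(records, cfg = filter_config()) {
  miss <- is.na(records$consequence) | records$consequence == ""
  if (any(miss))
    warning(sprintf("%d record(s) without consequence annotation dropped",
                    sum(miss)))
  records[!miss & records$consequence %in% cfg$consequence_whitelist, ,
          drop = FALSE]
}

#' Keep sufficiently rare variants
#'
#' Excludes records with any population allele frequency strictly greater
#' than `max_af`, any internal-cohort homozygote/hemizygote, more than
#' `max_cohort_hets` internal-cohort heterozygotes, or a gnomAD hom/hemi
#' observation.  Missing frequency annotations are treated as 0 (novel).
#'
#' @inheritParams filter_consequence
#' @return the passing subset.
#' @export
filter_frequency <- function(records, cfg = filter_config()) {
  z <- function(x) ifelse(is.na(x), 0, x)
  keep <- z(records$af_1000g) <= cfg$max_af &
    z(records$af_esp) <= cfg$max_af &
    z(records$af_gnomad) <= cfg$max_af &
    z(records$cohort_hets) <= cfg$max_cohort_hets
  if (cfg$disallow_cohort_hom_hemi)
    keep <- keep & z(records$cohort_hom_hemi) == 0
  if (cfg$disallow_gnomad_hom_hemi)
    keep <- keep & !(records$gnomad_hom_hemi %in% TRUE)
  records[keep, , drop = FALSE]
}

.is_het <- function(g) g %in% c("0/1", "1/0")
.is_hom_ref <- function(g) g %in% "0/0"
.is_hom_alt <- function(g) g %in% "1/1"
.is_hemi_ref <- function(g) g %in% "0"
.is_hemi_alt <- function(g) g %in% "1"

#' Apply quartet inheritance models
#'
#' Tests every record against the four inheritance models for a family
#' with two affected brothers and unaffected parents:
#'
#' * **simple recessive** — both sons homozygous-alternate, both parents
#'   heterozygous (autosomes);
#' * **compound heterozygous** — a gene carrying two or more passing
#'   variants, each heterozygous in both sons and in exactly one parent,
#'   with at least one variant from each parent (the sons carry both
#'   alleles of a trans pair);
#' * **X-linked recessive** — chrX, both sons hemizygous-alternate,
#'   mother heterozygous, father hemizygous-reference;
#' * **shared de novo** — both sons heterozygous, both parents
#'   homozygous-reference, with genotype log-likelihood ratio below the
#'   threshold in all four members (confident calls only).
#'
#' A missing genotype in any member makes the record ineligible for the
#' affected model (not an error).
#'
#' @param records variant-record data frame (normally already consequence-
#'   and frequency-filtered).
#' @param pedigree the quartet [quartet_pedigree()] (sex is required for
#'   the X-linked model).
#' @param cfg a [filter_config()].
#' @return A `candidate_set`: list with elements `recessive`,
#'   `compound_het` (gene-level list of record pairs), `x_linked`,
#'   `shared_denovo`, each a subset of `records`.
#' @export
apply_inheritance_models <- function(records, pedigree = quartet_pedigree(),
                                     cfg = filter_config()) {
  roles <- .quartet_roles(pedigree)
  fa <- records$gt_father; mo <- records$gt_mother
  s1 <- records$gt_son1; s2 <- records$gt_son2
  on_x <- records$chrom %in% c("X", "chrX")

  recessive <- !on_x & .is_het(fa) & .is_het(mo) &
    .is_hom_alt(s1) & .is_hom_alt(s2)

  x_linked <- on_x & .is_hemi_ref(fa) & .is_het(mo) &
    .is_hemi_alt(s1) & .is_hemi_alt(s2)

  gll_ok <- !is.na(records$gll_father) & !is.na(records$gll_mother) &
    !is.na(records$gll_son1) & !is.na(records$gll_son2) &
    records$gll_father < cfg$denovo_gll_threshold &
    records$gll_mother < cfg$denovo_gll_threshold &
    records$gll_son1 < cfg$denovo_gll_threshold &
    records$gll_son2 < cfg$denovo_gll_threshold
  shared_denovo <- !on_x & .is_hom_ref(fa) & .is_hom_ref(mo) &
    .is_het(s1) & .is_het(s2) & gll_ok

  # compound het: per gene, >= 2 variants het in both sons, each from
  # exactly one het parent, with both parents represented
  ch_eligible <- !on_x & .is_het(s1) & .is_het(s2) &
    ((.is_het(fa) & .is_hom_ref(mo)) | (.is_hom_ref(fa) & .is_het(mo)))
  compound_het <- list()
  if (any(ch_eligible)) {
    elig <- records[ch_eligible, , drop = FALSE]
    from_father <- .is_het(elig$gt_father)
    for (g in unique(elig$gene)) {
      in_g <- elig$gene == g
      if (sum(in_g) >= 2 && any(from_father[in_g]) &&
          any(!from_father[in_g]))
        compound_het[[g]] <- elig[in_g, , drop = FALSE]
    }
  }

  structure(list(recessive = records[recessive, , drop = FALSE],
                 compound_het = compound_het,
                 x_linked = records[x_linked, , drop = FALSE],
                 shared_denovo = records[shared_denovo, , drop = FALSE]),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate variants by inheritance model:\n")
  cat(sprintf("  simple recessive : %d\n", nrow(x$recessive)))
  cat(sprintf("  compound het     : %d gene(s)\n", length(x$compound_het)))
  cat(sprintf("  X-linked         : %d\n", nrow(x$x_linked)))
  cat(sprintf("  shared de novo   : %d\n", nrow(x$shared_denovo)))
  invisible(x)
}

#' Count candidates in a candidate set
#'
#' @param cs a `candidate_set`.
#' @return named integer vector of per-model candidate counts
#'   (compound-het counted as genes).
#' @export
candidate_counts <- function(cs) {
  c(recessive = nrow(cs$recessive),
    compound_het = length(cs$compound_het),
    x_linked = nrow(cs$x_linked),
    shared_denovo = nrow(cs$shared_denovo))
}

#' Run the full variant-filter funnel
#'
#' Consequence filter, then frequency filter, then the inheritance
#' models, with per-stage record counts logged in a funnel table.
#'
#' @param records variant-record data frame (e.g. from [read_vcf()] or
#'   [make_toy_pedigree_vcf()]).
#' @param pedigree the quartet pedigree.
#' @param cfg a [filter_config()].
#' @return list with `candidates` (a `candidate_set`) and `funnel`
#'   (data frame `stage`, `records_in`, `records_out`, `removed`).
#' @export
run_full_filter <- function(records, pedigree = quartet_pedigree(),
                            cfg = filter_config()) {
  n0 <- nrow(records)
  after_csq <- suppressWarnings(filter_consequence(records, cfg))
  after_frq <- filter_frequency(after_csq, cfg)
  cands <- apply_inheritance_models(after_frq, pedigree, cfg)
  n_models <- sum(candidate_counts(cands))
  funnel <- data.frame(
    stage = c("input", "consequence", "frequency", "inheritance"),
    records_in = c(n0, n0, nrow(after_csq), nrow(after_frq)),
    records_out = c(n0, nrow(after_csq), nrow(after_frq), n_models),
    stringsAsFactors = FALSE)
  funnel$removed <- funnel$records_in - funnel$records_out
  list(candidates = cands, funnel = funnel)
}
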