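# VCF v4.2 writer/reader for annotated quartet records.  Parsing is done
# with vcfR; this file only maps between the package's flat variant-record
# table and the VCF representation (INFO annotations, GT/PL fields).

.info_encode <- function(x) gsub(" ", "_", x)
.info_decode <- function(x) gsub("_", " ", x)

# resolve quartet roles from a pedigree: two parents, two affected sons
.quartet_roles <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("member", "sex", "affected", "father", "mother")
                %in% names(ped)))
  kids <- ped$member[!is.na(ped$father) & !is.na(ped$mother) & ped$affected]
  if (length(kids) != 2)
    stop("pedigree must contain exactly two affected children with both parents")
  father <- unique(ped$father[ped$member %in% kids])
  mother <- unique(ped$mother[ped$member %in% kids])
  if (length(father) != 1 || length(mother) != 1)
    stop("the two affected children must share both parents (quartet)")
  if (ped$sex[ped$member == father] != "M" ||
      ped$sex[ped$member == mother] != "F")
    stop("parent sexes inconsistent with father/mother links")
  list(father = father, mother = mother, sons = sort(kids))
}

#' Write quartet variant records as a VCF v4.2 file
#'
#' Annotations travel in INFO (`GENE`, `CSQ` consequence class, `AF1KG`,
#' `AFESP`, `AFGNOMAD` population frequencies, `GHH` gnomAD hom/hemi flag,
#' `CHET`/`CHH` internal-cohort het and hom/hemi counts) and genotypes as
#' `GT:PL` per sample.  PL margins are reconstructed from the stored
#' genotype log-likelihood ratios.
#'
#' @param records variant-record data frame (see [make_toy_pedigree_vcf()]).
#' @param pedigree the quartet [quartet_pedigree()].
#' @param path output path (plain text, uncompressed).
#' @return `path`, invisibly.
#' @export
write_pedigree_vcf <- function(records, pedigree, path) {
  roles <- .quartet_roles(pedigree)
  samples <- c(roles$father, roles$mother, roles$sons)
  role_cols <- c("father", "mother", "son1", "son2")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=AF1KG,Number=1,Type=Float,Description=\"1000 Genomes allele frequency\">",
    "##INFO=<ID=AFESP,Number=1,Type=Float,Description=\"NHLBI ESP allele frequency\">",
    "##INFO=<ID=AFGNOMAD,Number=1,Type=Float,Description=\"gnomAD allele frequency\">",
    "##INFO=<ID=GHH,Number=1,Type=Integer,Description=\"Seen hom/hemi in gnomAD (0/1)\">",
    "##INFO=<ID=CHET,Number=1,Type=Integer,Description=\"Internal cohort heterozygote count\">",
    "##INFO=<ID=CHH,Number=1,Type=Integer,Description=\"Internal cohort hom/hemi count\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  fmt_sample <- function(gt, gll) {
    if (is.na(gt) || gt %in% c("./.", ".")) return("./.:.")
    margin <- as.integer(round(-10 * gll))
    pl <- if (gt %in% c("0", "1")) {       # haploid (chrX male)
      p <- c(margin, margin); p[as.integer(gt) + 1L] <- 0L; p
    } else {
      p <- rep(margin, 3L)
      i <- switch(gt, "0/0" = 1L, "0/1" = 2L, "1/0" = 2L, "1/1" = 3L,
                  stop("unsupported genotype: ", gt))
      p[i] <- 0L; p
    }
    paste0(gt, ":", paste(pl, collapse = ","))
  }
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    info <- sprintf(
      "GENE=%s;CSQ=%s;AF1KG=%g;AFESP=%g;AFGNOMAD=%g;GHH=%d;CHET=%d;CHH=%d",
      r$gene, .info_encode(r$consequence), r$af_1000g, r$af_esp,
      r$af_gnomad, as.integer(r$gnomad_hom_hemi), r$cohort_hets,
      r$cohort_hom_hemi)
    cells <- vapply(role_cols, function(rc)
      fmt_sample(r[[paste0("gt_", rc)]], r[[paste0("gll_", rc)]]),
      character(1))
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", info,
            "GT:PL", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# PL indices for the ref/alt-k biallelic sub-genotypes of a multiallelic
# diploid PL vector (VCF ordering: index of (i,j) is j(j+1)/2 + i).
.pl_subset_idx <- function(k) c(1L, k * (k + 1L) / 2L + 1L,
                                k * (k + 1L) / 2L + k + 1L)

#' Read an annotated quartet VCF
#'
#' Parses a VCF v4.2 (via vcfR), maps sample columns onto the pedigree
#' roles, splits multi-allelic sites into one biallelic record per
#' alternate allele (alleles other than the focal alternate are recoded
#' as reference; PL values are subset to the matching sub-genotypes when
#' present) and recomputes genotype log-likelihood ratios.
#'
#' The genotype log-likelihood ratio is the log10 likelihood of the best
#' alternative genotype minus that of the called genotype, i.e.
#' `-(second-smallest PL)/10`; it is always <= 0, and more negative means
#' a more confident call.  Records without PL carry `NA` ratios
#' (likelihoods absent).
#'
#' @param path path to an uncompressed VCF with GT (PL optional; needed
#'   only for the shared-de-novo inheritance model).
#' @param pedigree the quartet [quartet_pedigree()]; every member must be
#'   a sample in the VCF.
#' @return variant-record data frame: `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`, `af_1000g`, `af_esp`, `af_gnomad`,
#'   `gnomad_hom_hemi`, `cohort_hets`, `cohort_hom_hemi`, per-role `gt_*`
#'   genotype and `gll_*` log-likelihood-ratio columns.
#' @export
read_vcf <- function(path, pedigree) {
  roles <- .quartet_roles(pedigree)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  needed <- c(roles$father, roles$mother, roles$sons)
  missing <- setdiff(needed, samples)
  if (length(missing))
    stop("pedigree sample(s) absent from VCF: ",
         paste(missing, collapse = ", "))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  pl <- tryCatch(vcfR::extract.gt(vcf, element = "PL"),
                 error = function(e) NULL)
  info_num <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = key)))
  info_chr <- function(key) vcfR::extract.info(vcf, element = key)
  gene <- info_chr("GENE")
  csq <- .info_decode(info_chr("CSQ"))
  af1 <- info_num("AF1KG"); afe <- info_num("AFESP"); afg <- info_num("AFGNOMAD")
  ghh <- info_num("GHH"); chet <- info_num("CHET"); chh <- info_num("CHH")
  role_cols <- c("father", "mother", "son1", "son2")
  role_samples <- c(roles$father, roles$mother, roles$sons)

  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      gts <- stats::setNames(rep(NA_character_, 4), role_cols)
      glls <- stats::setNames(rep(NA_real_, 4), role_cols)
      for (j in seq_along(role_cols)) {
        raw_gt <- gt[i, role_samples[j]]
        gts[j] <- .recode_gt(raw_gt, k)
        raw_pl <- if (is.null(pl)) NA_character_ else pl[i, role_samples[j]]
        glls[j] <- .gll_from_pl(raw_pl, k, haploid = !grepl("[/|]",
                                                            gts[j]))
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = sub("^chr", "", fix[i, "CHROM"]),
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        gene = gene[i], consequence = csq[i],
        af_1000g = ifelse(is.na(af1[i]), 0, af1[i]),
        af_esp = ifelse(is.na(afe[i]), 0, afe[i]),
        af_gnomad = ifelse(is.na(afg[i]), 0, afg[i]),
        gnomad_hom_hemi = !is.na(ghh[i]) && ghh[i] > 0,
        cohort_hets = ifelse(is.na(chet[i]), 0L, as.integer(chet[i])),
        cohort_hom_hemi = ifelse(is.na(chh[i]), 0L, as.integer(chh[i])),
        gt_father = gts[["father"]], gt_mother = gts[["mother"]],
        gt_son1 = gts[["son1"]], gt_son2 = gts[["son2"]],
        gll_father = glls[["father"]], gll_mother = glls[["mother"]],
        gll_son1 = glls[["son1"]], gll_son2 = glls[["son2"]],
        planted_model = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# recode a raw GT string against focal alternate allele k:
# allele == k -> 1, any other allele (ref or other alt) -> 0
.recode_gt <- function(raw, k) {
  if (is.na(raw) || raw %in% c(".", "./.", ".|.")) return("./.")
  alleles <- strsplit(raw, "[/|]")[[1]]
  if (any(alleles == ".")) return("./.")
  coded <- ifelse(alleles == as.character(k), "1", "0")
  if (length(alleles) == 1) return(coded)
  # canonical unordered diploid form: 1/0 -> 0/1
  paste(sort(coded), collapse = "/")
}

# genotype log-likelihood ratio (log10, next-best minus called) from a
# raw PL string; k = focal alternate index; NA when PL absent or the
# multiallelic subset cannot be taken (haploid multiallelic)
.gll_from_pl <- function(raw, k, haploid) {
  if (is.na(raw) || raw == ".") return(NA_real_)
  pls <- suppressWarnings(as.numeric(strsplit(raw, ",", fixed = TRUE)[[1]]))
  if (anyNA(pls)) return(NA_real_)
  if (haploid) {
    idx <- c(1L, k + 1L)
    if (max(idx) > length(pls)) return(NA_real_)
    pls <- pls[idx]
  } else {
    idx <- .pl_subset_idx(k)
    if (max(idx) > length(pls)) return(NA_real_)
    pls <- pls[idx]
  }
  pls <- pls - min(pls)
  -sort(pls)[2] / 10
}
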