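#' Specification of a synthetic mouse actigraphy cohort
#'
#' The generator emulates polyphasic nocturnal mouse behaviour as a
#' two-state alternating-renewal process (active / immobile).  Run lengths
#' are drawn from a four-component mixture matching the canonical bout
#' length classes (<1 min, 1-10 min, 10 min-1 h, >1 h), log-normal within
#' each class and truncated to the class interval, so class-conditional
#' length distributions stay fixed while circadian phase and genotype act
#' only on class weights.
#'
#' Circadian structure: the internal phase advances at period
#' `tau(lux) = intrinsic_tau_h + aschoff_slope * log10(lux + 1)` in
#' constant conditions (an Aschoff-rule-like lengthening of tau with
#' light) and is entrained to the light cycle in LD blocks (subjective
#' night = scotophase).  During subjective night the class weights of
#' activity runs are tilted toward longer runs and immobility runs toward
#' shorter ones (and conversely by day); the tilt strength grows with
#' `nocturnality`, the desired dark/light activity balance.
#'
#' The planted genotype effect `brief_bout_deficit` multiplies the weight
#' of the sub-minute class for both activity and immobility runs, so a
#' value of 0.6 models a 40% deficit in brief bouts of activity and sleep.
#'
#' @param n_per_genotype subjects per genotype.
#' @param genotypes character vector of genotype labels.
#' @param intrinsic_tau_h free-running period in darkness, hours; recycled
#'   across genotypes.
#' @param aschoff_slope hours of tau lengthening per log10(lux + 1);
#'   recycled across genotypes.
#' @param brief_bout_deficit multiplier in (0, 1] on the sub-minute run
#'   class weight; recycled across genotypes (1 = no deficit).
#' @param nocturnality target dark/light activity balance (> 1 =
#'   nocturnal); must be > 0.
#' @param activity_mix,immobility_mix positive class weights (length 4)
#'   for activity and immobility runs.
#' @param mean_intensity,noise_sd mean and SD of per-bin percent-active in
#'   active bins (values are clamped to \[0.5, 100\] so active bins stay
#'   active).
#' @param bin_seconds sensor bin width; must divide 60 (default 10).
#' @param seed single global seed; per-subject streams are split from it
#'   deterministically so cohorts are reproducible subject-wise.
#' @return A `mouse_cohort_spec` object.
#' @export
mouse_cohort_spec <- function(n_per_genotype = 6,
                              genotypes = c("WT", "MUT"),
                              intrinsic_tau_h = 23.8,
                              aschoff_slope = 0.4,
                              brief_bout_deficit = 1,
                              nocturnality = 6,
                              activity_mix = c(0.55, 0.30, 0.13, 0.02),
                              immobility_mix = c(0.45, 0.33, 0.19, 0.03),
                              mean_intensity = 55,
                              noise_sd = 18,
                              bin_seconds = 10,
                              seed = 1L) {
  ng <- length(genotypes)
  intrinsic_tau_h <- rep_len(intrinsic_tau_h, ng)
  aschoff_slope <- rep_len(aschoff_slope, ng)
  brief_bout_deficit <- rep_len(brief_bout_deficit, ng)
  if (n_per_genotype < 1) stop("n_per_genotype must be >= 1")
  if (any(intrinsic_tau_h <= 0)) stop("intrinsic tau must be positive")
  if (any(brief_bout_deficit <= 0 | brief_bout_deficit > 1))
    stop("brief_bout_deficit must be in (0, 1]")
  if (nocturnality <= 0) stop("nocturnality must be > 0")
  if (any(activity_mix <= 0) || any(immobility_mix <= 0))
    stop("all class weights must be > 0")
  if (length(activity_mix) != 4 || length(immobility_mix) != 4)
    stop("class weight vectors must have length 4")
  if (bin_seconds <= 0 || 60 %% bin_seconds != 0)
    stop("bin_seconds must divide 60")
  structure(list(n_per_genotype = as.integer(n_per_genotype),
                 genotypes = genotypes,
                 intrinsic_tau_h = intrinsic_tau_h,
                 aschoff_slope = aschoff_slope,
                 brief_bout_deficit = brief_bout_deficit,
                 nocturnality = nocturnality,
                 activity_mix = activity_mix,
                 immobility_mix = immobility_mix,
                 mean_intensity = mean_intensity,
                 noise_sd = noise_sd,
                 bin_seconds = bin_seconds,
                 seed = as.integer(seed)),
            class = "mouse_cohort_spec")
}

# Class-conditional run-length distributions: log-normal truncated to the
# canonical length classes (seconds).  meanlog at the geometric mid of
# each class.
.run_class_lo <- c(10, 60, 600, 3600)
.run_class_hi <- c(60, 600, 3600, 21600)
.run_meanlog <- log(c(25, 190, 1470, 5400))
.run_sdlog <- c(0.6, 0.6, 0.6, 0.5)

# inverse-CDF sampling from a lognormal truncated to [lo, hi)
rtrunc_lnorm <- function(n, class_idx) {
  lo <- .run_class_lo[class_idx]; hi <- .run_class_hi[class_idx]
  ml <- .run_meanlog[class_idx]; sl <- .run_sdlog[class_idx]
  p0 <- stats::plnorm(lo, ml, sl)
  p1 <- stats::plnorm(hi, ml, sl)
  stats::qlnorm(p0 + stats::runif(n) * (p1 - p0), ml, sl)
}

# circadian phase (fraction of cycle, in [0,1)) for times t_s under a
# schedule; phase 0.5 marks subjective night onset. LD blocks entrain
# (night = scotophase); free-running blocks advance at tau(lux).
.phase_fun <- function(schedule, intrinsic_tau_h, aschoff_slope) {
  taus <- ifelse(schedule$condition == "LD", 24,
                 intrinsic_tau_h + aschoff_slope * log10(schedule$lux + 1))
  force(taus)
  function(t_s) {
    ph <- numeric(length(t_s))
    ph0 <- 0
    for (b in seq_len(nrow(schedule))) {
      in_b <- t_s >= schedule$start_s[b] & t_s < schedule$end_s[b]
      if (schedule$condition[b] == "LD") {
        # entrained: phase locked to wall clock, lights-on = phase 0
        ph[in_b] <- ((t_s[in_b] - schedule$start_s[b]) / 3600 / 24) %% 1
        ph0 <- ((schedule$end_s[b] - schedule$start_s[b]) / 3600 / 24) %% 1
      } else {
        ph[in_b] <- (ph0 + (t_s[in_b] - schedule$start_s[b]) /
                       3600 / taus[b]) %% 1
        ph0 <- (ph0 + (schedule$end_s[b] - schedule$start_s[b]) /
                  3600 / taus[b]) %% 1
      }
    }
    ph
  }
}

#' Simulate a cohort of mouse activity traces
#'
#' Runs the alternating-renewal generator described in
#' [mouse_cohort_spec()] over the given lighting schedule.  Every bin of a
#' trace is exactly one of active (percent-active drawn around
#' `mean_intensity`, clamped to stay positive) or immobile (exactly 0), so
#' active and immobile durations always sum to the trace length.
#'
#' @param spec a [mouse_cohort_spec()].
#' @param schedule a [lighting_schedule()]; the traces span the whole
#'   schedule.
#' @return list of [activity_trace()] objects, `n_per_genotype` per
#'   genotype, subject ids `"<genotype><i>"`.
#' @export
simulate_mouse_activity <- function(spec, schedule) {
  stopifnot(inherits(spec, "mouse_cohort_spec"),
            inherits(schedule, "lighting_schedule"))
  total_days <- sum(schedule$days)
  n_bins <- as.integer(round(total_days * 86400 / spec$bin_seconds))
  if (n_bins < 1) stop("schedule covers no time")
  n_subj <- spec$n_per_genotype * length(spec$genotypes)
  set.seed(spec$seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subj)
  traces <- vector("list", n_subj)
  k <- 0L
  g_tilt <- log(spec$nocturnality) / 4
  for (gi in seq_along(spec$genotypes)) {
    phase_of <- .phase_fun(schedule, spec$intrinsic_tau_h[gi],
                           spec$aschoff_slope[gi])
    a_mix <- spec$activity_mix
    i_mix <- spec$immobility_mix
    a_mix[1] <- a_mix[1] * spec$brief_bout_deficit[gi]
    i_mix[1] <- i_mix[1] * spec$brief_bout_deficit[gi]
    for (si in seq_len(spec$n_per_genotype)) {
      k <- k + 1L
      set.seed(subj_seeds[k])
      traces[[k]] <- .simulate_one_trace(
        n_bins, spec$bin_seconds, phase_of, a_mix, i_mix, g_tilt,
        spec$mean_intensity, spec$noise_sd,
        subject_id = sprintf("%s%d", spec$genotypes[gi], si),
        genotype = spec$genotypes[gi], schedule = schedule)
    }
  }
  traces
}

.simulate_one_trace <- function(n_bins, bin_s, phase_of, a_mix, i_mix,
                                g_tilt, mean_intensity, noise_sd,
                                subject_id, genotype, schedule) {
  # tilt exponent per class: negative classes are short, positive long
  u <- c(-1.5, -0.5, 0.5, 1.5)
  # per-bin subjective night flag (active phase for a nocturnal animal);
  # state runs are clock-gated: a run cannot cross a subjective day/night
  # transition, giving the sharp activity onsets real actograms show
  night_bin <- phase_of((seq_len(n_bins) - 0.5) * bin_s) >= 0.5
  r <- rle(night_bin)
  seg_end <- cumsum(r$lengths)                     # last bin of each segment
  next_gate <- rep.int(seg_end, r$lengths)         # gate bin for every bin
  state <- logical(n_bins)  # TRUE = active
  pos <- 0L
  cur_active <- stats::runif(1) < 0.5
  while (pos < n_bins) {
    night <- night_bin[pos + 1L]
    c_sign <- if (night) 1 else -1
    w <- if (cur_active) a_mix * exp(g_tilt * c_sign * u)
         else i_mix * exp(-g_tilt * c_sign * u)
    cls <- sample.int(4L, 1L, prob = w)
    dur_s <- rtrunc_lnorm(1L, cls)
    nb <- max(1L, as.integer(round(dur_s / bin_s)))
    nb <- min(nb, n_bins - pos, next_gate[pos + 1L] - pos)
    if (cur_active) state[(pos + 1L):(pos + nb)] <- TRUE
    pos <- pos + nb
    cur_active <- !cur_active
  }
  vals <- numeric(n_bins)
  na <- sum(state)
  if (na > 0) {
    v <- stats::rnorm(na, mean_intensity, noise_sd)
    vals[state] <- pmin(100, pmax(0.5, v))
  }
  activity_trace(vals, bin_seconds = bin_s, subject_id = subject_id,
                 genotype = genotype, start_s = 0, schedule = schedule)
}

#' Specification of a synthetic ultra-long sleep-wake diary
#'
#' Emulates an hourly caregiver sleep diary of a subject with a greatly
#' lengthened sleep-wake cycle (e.g. 56-106 h): wake and sleep episodes
#' alternate with mean durations `cycle_length_h * (1 - sleep_fraction)`
#' and `cycle_length_h * sleep_fraction`, each jittered by a log-normal
#' factor so successive cycles vary as real records do.
#'
#' @param cycle_length_h mean sleep-wake cycle length, hours; must exceed
#'   24 (or equal 24 for a control diary).
#' @param sleep_fraction fraction of the cycle asleep, in (0, 1).
#' @param days diary length in days; 27 or 28.
#' @param jitter_sdlog log-scale SD of episode-duration jitter
#'   (default 0.08; keeps the realised duty cycle within a few percent of
#'   `sleep_fraction`).
#' @param resolution_h diary resolution; only 1 h is supported.
#' @param seed RNG seed.
#' @return A `diary_spec` object.
#' @export
diary_spec <- function(cycle_length_h = 72, sleep_fraction = 0.35,
                       days = 28, jitter_sdlog = 0.08,
                       resolution_h = 1, seed = 1L) {
  if (resolution_h != 1) stop("only hourly resolution is supported")
  if (!days %in% c(27, 28)) stop("diary length must be 27 or 28 days")
  if (cycle_length_h < 24) stop("cycle_length_h must be >= 24")
  if (sleep_fraction <= 0 || sleep_fraction >= 1)
    stop("sleep_fraction must be in (0, 1)")
  structure(list(cycle_length_h = cycle_length_h,
                 sleep_fraction = sleep_fraction,
                 days = as.integer(days),
                 jitter_sdlog = jitter_sdlog,
                 seed = as.integer(seed)),
            class = "diary_spec")
}

#' Simulate an hourly sleep diary
#'
#' @param spec a [diary_spec()].
#' @return A [diary_series()] of `24 * days` binary flags.
#' @export
simulate_sleep_diary <- function(spec) {
  stopifnot(inherits(spec, "diary_spec"))
  set.seed(spec$seed)
  n_h <- 24L * spec$days
  wake_mean <- spec$cycle_length_h * (1 - spec$sleep_fraction)
  sleep_mean <- spec$cycle_length_h * spec$sleep_fraction
  flags <- integer(0)
  asleep <- FALSE
  while (length(flags) < n_h) {
    m <- if (asleep) sleep_mean else wake_mean
    dur <- m * stats::rlnorm(1, -spec$jitter_sdlog^2 / 2, spec$jitter_sdlog)
    flags <- c(flags, rep(as.integer(asleep), max(1L, round(dur))))
    asleep <- !asleep
  }
  diary_series(flags[seq_len(n_h)], subject_id = "diary1")
}

#' Specification of a synthetic family-quartet VCF
#'
#' Builds an annotated multi-sample VCF for a father-mother-two-affected-
#' sons quartet: `n_background_variants` variants that each violate at
#' least one downstream filter (wrong consequence class, common allele,
#' internal-cohort recurrence, or a genotype pattern fitting no
#' inheritance model), plus planted candidates that satisfy exactly the
#' tagged inheritance model.
#'
#' Planting is specified as a data frame with one row per planted variant
#' (two rows, same gene, for `compound_het`): columns `model` (one of
#' `"x_linked"`, `"recessive"`, `"compound_het"`, `"shared_denovo"`),
#' and optionally `af` (population allele frequency, default 0),
#' `consequence` (default `"nonsynonymous SNV"`), `gene`, and
#' `gll_margin` (phred PL margin of the called genotype over the next
#' best; default 99, i.e. log-likelihood ratio -9.9).
#'
#' @param n_background_variants number of background variants.
#' @param planted `NULL` (plant nothing) or a data frame as above.
#' @param seed RNG seed.
#' @return A `pedigree_vcf_spec` object.
#' @export
pedigree_vcf_spec <- function(n_background_variants = 500, planted = NULL,
                              seed = 1L) {
  if (n_background_variants < 0) stop("negative background count")
  if (!is.null(planted)) {
    if (!is.data.frame(planted) || !"model" %in% names(planted))
      stop("planted must be a data frame with a 'model' column")
    ok <- c("x_linked", "recessive", "compound_het", "shared_denovo")
    if (!all(planted$model %in% ok))
      stop("unknown inheritance model tag in planted")
    ch <- sum(planted$model == "compound_het")
    if (ch %% 2 != 0)
      stop("compound_het planting needs pairs of variants (one per parent)")
  }
  structure(list(n_background_variants = as.integer(n_background_variants),
                 planted = planted, seed = as.integer(seed)),
            class = "pedigree_vcf_spec")
}

#' The canonical quartet pedigree
#'
#' Father, mother and two affected sons — the family structure all
#' inheritance-model filters assume.
#'
#' @return A `pedigree` data frame with columns `member`, `sex`,
#'   `affected`, `father`, `mother`.
#' @export
quartet_pedigree <- function() {
  ped <- data.frame(
    member = c("father", "mother", "son1", "son2"),
    sex = c("M", "F", "M", "M"),
    affected = c(FALSE, FALSE, TRUE, TRUE),
    father = c(NA, NA, "father", "father"),
    mother = c(NA, NA, "mother", "mother"),
    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

.consequence_whitelist <- c("nonsynonymous SNV", "stopgain", "stoploss",
                            "frameshift indel", "inframe indel",
                            "splice site")

# genotype patterns per model, as named character vectors
.model_genotypes <- function(model, which_parent = "mother") {
  switch(model,
    x_linked = c(father = "0", mother = "0/1", son1 = "1", son2 = "1"),
    recessive = c(father = "0/1", mother = "0/1", son1 = "1/1",
                  son2 = "1/1"),
    shared_denovo = c(father = "0/0", mother = "0/0", son1 = "0/1",
                      son2 = "0/1"),
    compound_het = {
      g <- c(father = "0/0", mother = "0/0", son1 = "0/1", son2 = "0/1")
      g[which_parent] <- "0/1"
      g
    },
    stop("unknown model"))
}

#' Generate a toy annotated quartet VCF
#'
#' @param spec a [pedigree_vcf_spec()].
#' @return list with `records` (a variant-record data frame, see
#'   [read_vcf()]), `pedigree` (the quartet), and `planted_keys`
#'   (chrom:pos of each planted variant).
#' @export
make_toy_pedigree_vcf <- function(spec) {
  stopifnot(inherits(spec, "pedigree_vcf_spec"))
  set.seed(spec$seed)
  ped <- quartet_pedigree()
  nb <- spec$n_background_variants
  rows <- list()

  # background variants: each violates >= 1 downstream filter by design
  if (nb > 0) {
    kill <- sample(c("consequence", "frequency", "cohort", "genotype"),
                   nb, replace = TRUE, prob = c(0.3, 0.25, 0.15, 0.3))
    for (i in seq_len(nb)) {
      chrom <- sample(c(as.character(1:22), "X"), 1)
      gene <- sprintf("BGGENE%04d", i)
      cons <- sample(.consequence_whitelist, 1)
      af <- 0
      cohort_hets <- sample(0:3, 1)
      cohort_hom_hemi <- 0L
      gnomad_hom_hemi <- FALSE
      # an unremarkable inherited-het pattern fits no model
      gts <- if (chrom == "X") c(father = "0", mother = "0/1",
                                 son1 = sample(c("0", "1"), 1), son2 = "0")
             else c(father = sample(c("0/0", "0/1"), 1), mother = "0/0",
                    son1 = sample(c("0/0", "0/1"), 1), son2 = "0/0")
      if (kill[i] == "consequence") {
        cons <- sample(c("synonymous SNV", "intronic", "UTR3", "intergenic"), 1)
      } else if (kill[i] == "frequency") {
        af <- stats::runif(1, 0.006, 0.2)
      } else if (kill[i] == "cohort") {
        if (stats::runif(1) < 0.5) cohort_hets <- sample(6:40, 1)
        else if (stats::runif(1) < 0.5) cohort_hom_hemi <- sample(1:3, 1)
        else gnomad_hom_hemi <- TRUE
      }
      rows[[length(rows) + 1L]] <- .variant_row(
        chrom, pos = NA, gene = gene, consequence = cons, af = af,
        cohort_hets = cohort_hets, cohort_hom_hemi = cohort_hom_hemi,
        gnomad_hom_hemi = gnomad_hom_hemi, genotypes = gts,
        gll_margin = 99, planted_model = NA_character_)
    }
  }

  # planted candidates
  planted_keys <- character(0)
  if (!is.null(spec$planted) && nrow(spec$planted) > 0) {
    pl <- spec$planted
    ch_parent <- "father"  # alternate parents across a compound-het pair
    for (i in seq_len(nrow(pl))) {
      model <- pl$model[i]
      af <- if ("af" %in% names(pl) && !is.na(pl$af[i])) pl$af[i] else 0
      cons <- if ("consequence" %in% names(pl) && !is.na(pl$consequence[i]))
        pl$consequence[i] else "nonsynonymous SNV"
      gene <- if ("gene" %in% names(pl) && !is.na(pl$gene[i])) pl$gene[i]
              else sprintf("PLGENE%02d", i)
      margin <- if ("gll_margin" %in% names(pl) && !is.na(pl$gll_margin[i]))
        pl$gll_margin[i] else 99
      chrom <- if (model == "x_linked") "X"
               else sample(as.character(1:22), 1)
      if (model == "compound_het") {
        ch_parent <- if (ch_parent == "father") "mother" else "father"
        gts <- .model_genotypes(model, ch_parent)
      } else {
        gts <- .model_genotypes(model)
      }
      rows[[length(rows) + 1L]] <- .variant_row(
        chrom, pos = NA, gene = gene, consequence = cons, af = af,
        cohort_hets = 0L, cohort_hom_hemi = 0L, gnomad_hom_hemi = FALSE,
        genotypes = gts, gll_margin = margin, planted_model = model)
    }
  }

  rec <- do.call(rbind, rows)
  # assign unique sorted positions per chromosome
  rec <- rec[order(rec$chrom), , drop = FALSE]
  for (ch in unique(rec$chrom)) {
    idx <- which(rec$chrom == ch)
    rec$pos[idx] <- sort(sample.int(2e8, length(idx)))
  }
  rownames(rec) <- NULL
  planted_keys <- with(rec[!is.na(rec$planted_model), , drop = FALSE],
                       paste0(chrom, ":", pos))
  list(records = rec, pedigree = ped, planted_keys = planted_keys)
}

.variant_row <- function(chrom, pos, gene, consequence, af, cohort_hets,
                         cohort_hom_hemi, gnomad_hom_hemi, genotypes,
                         gll_margin, planted_model) {
  data.frame(
    chrom = chrom, pos = pos, ref = "G", alt = "A", gene = gene,
    consequence = consequence,
    af_1000g = af, af_esp = af, af_gnomad = af,
    gnomad_hom_hemi = gnomad_hom_hemi,
    cohort_hets = as.integer(cohort_hets),
    cohort_hom_hemi = as.integer(cohort_hom_hemi),
    gt_father = genotypes[["father"]], gt_mother = genotypes[["mother"]],
    gt_son1 = genotypes[["son1"]], gt_son2 = genotypes[["son2"]],
    gll_father = -gll_margin / 10, gll_mother = -gll_margin / 10,
    gll_son1 = -gll_margin / 10, gll_son2 = -gll_margin / 10,
    planted_model = planted_model,
    stringsAsFactors = FALSE)
}

#' Simulate an agonist dose-response table
#'
#' Generates relative peak-current responses from the three-parameter
#' dose-response model
#' `Y = bottom + (top - bottom) / (1 + 10^(log10(EC50) - X))`,
#' `X = log10(concentration)`, with Hill slope 1.  Responses are in the
#' relative units of the 10 mM reference-agonist convention (a response of
#' 1 equals the current at the near-saturating reference application), so
#' the noiseless response at `concentration = ec50` is exactly
#' `(top + bottom) / 2`.
#'
#' @param ec50_mM true EC50 in mM (the recombinant-receptor generator
#'   settings of interest are 0.53 and 1.65 mM).
#' @param top,bottom asymptotes of the relative response (defaults 1, 0).
#' @param concentrations_mM agonist concentrations in mM; must be positive
#'   and span `ec50_mM`.
#' @param noise_sd SD of additive Gaussian noise on the responses
#'   (0 = noiseless).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return data frame `concentration_mM`, `response`.
#' @export
simulate_dose_response <- function(ec50_mM = 0.53, top = 1, bottom = 0,
                                   concentrations_mM =
                                     c(0.001, 0.003, 0.01, 0.03, 0.1,
                                       0.3, 1, 3, 10, 30),
                                   noise_sd = 0, seed = 1L) {
  if (any(concentrations_mM <= 0)) stop("concentrations must be positive")
  if (ec50_mM <= 0) stop("EC50 must be positive")
  if (min(concentrations_mM) > ec50_mM || max(concentrations_mM) < ec50_mM)
    stop("concentrations must span the EC50")
  y <- .dose_response_model(concentrations_mM, bottom, top, log10(ec50_mM))
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  data.frame(concentration_mM = concentrations_mM, response = y)
}
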