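#' Two-way repeated-measures ANOVA with Bonferroni post-hocs
#'
#' Mixed-design decomposition for a balanced table of one value per
#' subject x within-subject level, with subjects nested in a
#' between-subject genotype factor.  The classical univariate strata are
#' used (no sphericity correction; equal variance assumed): the genotype
#' effect is tested against subject-within-genotype, the within factor
#' and the interaction against the subject x level residual.  Alongside
#' each F and P the percent of variation explained is reported as
#' 100 * SS_effect / SS_total, with SS_total the sum over all strata
#' (so the percentages, with the residuals, sum to 100).
#'
#' Post-hoc genotype comparisons are made at each within-subject level by
#' a pooled-variance two-sample t test on that level's values, with the
#' Bonferroni correction multiplying each raw P by the number of levels
#' (capped at 1).
#'
#' @param table data frame with columns `subject`, `genotype`, `level`
#'   (within-subject factor: bout category, light level, hour, ...) and
#'   `value`.  Every subject must have exactly one value at every level
#'   (missing cells are an error; no imputation).
#' @return An `anova_rm` list: `effects` (data frame with `effect`, `SS`,
#'   `df`, `MS`, `F`, `P`, `pct_variation`), `posthoc` (data frame with
#'   `level`, group means, `t`, `df`, `P_raw`, `P_bonferroni`),
#'   `n_levels`, `n_subjects`.
#' @export
two_way_rm_anova <- function(table) {
  need <- c("subject", "genotype", "level", "value")
  if (!all(need %in% names(table)))
    stop("table needs columns subject, genotype, level, value")
  tab <- data.frame(subject = factor(table$subject),
                    genotype = factor(table$genotype),
                    level = factor(table$level),
                    value = as.numeric(table$value))
  if (nlevels(tab$genotype) < 2) stop("need at least two genotypes")
  counts <- base::table(tab$subject, tab$level)
  if (any(counts != 1))
    stop("unbalanced table: every subject needs one value per level")
  subj_geno <- unique(tab[, c("subject", "genotype")])
  if (anyDuplicated(subj_geno$subject))
    stop("a subject appears under more than one genotype")
  n_per <- base::table(subj_geno$genotype)
  if (any(n_per < 2)) stop("need at least two subjects per genotype")

  fit <- stats::aov(value ~ genotype * level + Error(subject),
                    data = tab)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: subject"]][[1]])
  wth <- as.data.frame(sm[["Error: Within"]][[1]])
  pick <- function(df, nm) {
    i <- match(nm, trimws(rownames(df)))
    c(SS = df[i, "Sum Sq"], df = df[i, "Df"],
      F = if ("F value" %in% names(df)) df[i, "F value"] else NA,
      P = if ("Pr(>F)" %in% names(df)) df[i, "Pr(>F)"] else NA)
  }
  eff <- rbind(
    genotype = pick(btw, "genotype"),
    subject = pick(btw, "Residuals"),
    level = pick(wth, "level"),
    `genotype:level` = pick(wth, "genotype:level"),
    residual = pick(wth, "Residuals"))
  effects <- data.frame(effect = rownames(eff),
                        SS = eff[, "SS"], df = eff[, "df"],
                        MS = eff[, "SS"] / eff[, "df"],
                        F = eff[, "F"], P = eff[, "P"],
                        row.names = NULL)
  # subject stratum has no F against a lower stratum in this design
  effects$F[effects$effect == "subject"] <- NA
  effects$P[effects$effect == "subject"] <- NA
  ss_total <- sum(effects$SS)
  effects$pct_variation <- 100 * effects$SS / ss_total

  genos <- levels(tab$genotype)
  lvls <- levels(tab$level)
  k <- length(lvls)
  posthoc <- do.call(rbind, lapply(lvls, function(lv) {
    a <- tab$value[tab$level == lv & tab$genotype == genos[1]]
    b <- tab$value[tab$level == lv & tab$genotype == genos[2]]
    tt <- .pooled_t(a, b)
    data.frame(level = lv,
               mean_1 = mean(a), mean_2 = mean(b),
               t = tt$t, df = tt$df, P_raw = tt$P,
               P_bonferroni = min(1, k * tt$P),
               stringsAsFactors = FALSE)
  }))
  names(posthoc)[2:3] <- paste0("mean_", genos[1:2])
  structure(list(effects = effects, posthoc = posthoc,
                 n_levels = k, n_subjects = nrow(subj_geno)),
            class = "anova_rm")
}

.pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (sp2 == 0) {
    return(list(t = if (mean(a) == mean(b)) 0 else Inf *
                  sign(mean(a) - mean(b)),
                df = na + nb - 2,
                P = if (mean(a) == mean(b)) 1 else 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, P = 2 * stats::pt(-abs(t), df))
}

#' @export
print.anova_rm <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA (between: genotype; within: level)\n")
  print(x$effects, digits = 4)
  cat("\nBonferroni post-hoc genotype comparisons per level:\n")
  print(x$posthoc, digits = 4)
  invisible(x)
}

#' Welch's unpaired t test
#'
#' Two-sample t test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom).  If both groups are constant
#' with equal means, P = 1 by convention.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @return list with `t`, `df`, `P`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2,
                P = if (eq) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       P = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' t test on log-transformed observations (geometric means)
#'
#' For strictly positive measurements whose natural summary is the
#' geometric mean (e.g. flow-cytometry fluorescence), the comparison is a
#' two-sample t test on the logs; geometric means are reported.  Scaling
#' both groups by a common factor shifts both log-means equally and
#' leaves the statistic unchanged.
#'
#' @param a,b strictly positive numeric vectors.
#' @param var_equal pool variances (classical t test, default) or use
#'   Welch's correction.
#' @return list with `t`, `df`, `P`, `geomean_a`, `geomean_b`.
#' @export
log_geomean_t_test <- function(a, b, var_equal = TRUE) {
  if (any(a <= 0) || any(b <= 0))
    stop("log-scale comparison requires strictly positive values")
  la <- log(a); lb <- log(b)
  if (stats::var(la) == 0 && stats::var(lb) == 0) {
    eq <- isTRUE(all.equal(mean(la), mean(lb)))
    return(list(t = if (eq) 0 else Inf * sign(mean(la) - mean(lb)),
                df = length(a) + length(b) - 2,
                P = if (eq) 1 else 0,
                geomean_a = exp(mean(la)), geomean_b = exp(mean(lb))))
  }
  tt <- stats::t.test(la, lb, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       P = tt$p.value,
       geomean_a = exp(mean(la)), geomean_b = exp(mean(lb)))
}

# skew-normal density: location xi, scale omega (> 0), shape alpha
dskewnorm <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

# least-squares fit of a skew-normal curve to (x, y) histogram points;
# returns par = c(xi, log_omega, alpha) and residual SS
.fit_skewnorm_ls <- function(x, y, start) {
  obj <- function(p) sum((y - dskewnorm(x, p[1], exp(p[2]), p[3]))^2)
  best <- NULL
  for (s in start) {
    fit <- tryCatch(stats::optim(s, obj, method = "Nelder-Mead",
                                 control = list(maxit = 2000,
                                                reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  best
}

#' Compare two event-amplitude distributions via skew-normal fits
#'
#' Both samples are binned into relative-frequency histograms (density
#' scale) on a shared range with `n_bins` bins per group.  A
#' three-parameter skew-normal curve (location, scale, shape) is fitted
#' by least squares to the pooled histogram points and separately per
#' group, and the fits are compared with an extra-sum-of-squares F test:
#' F = ((SS_pooled - SS_separate) / 3) / (SS_separate / (2 n_bins - 6)),
#' i.e. numerator df 3 (the shared parameters released) and denominator
#' df the total histogram points minus the 6 separately-fitted
#' parameters.  With 21 bins per group the df pair is (3, 36).
#'
#' Event samples are expected to be pre-filtered (e.g. rise-time rule via
#' [filter_events_by_rise_time()]) before binning.
#'
#' @param sample_a,sample_b numeric event-amplitude samples.
#' @param n_bins histogram bins per group (default 21).
#' @return A `dist_comparison` list: `ss_pooled`, `ss_separate`, `F`,
#'   `df1`, `df2`, `P`, `converged`.  On fit non-convergence `F` and `P`
#'   are `NA` with `converged = FALSE`.
#' @export
compare_distributions_skewnormal <- function(sample_a, sample_b,
                                             n_bins = 21) {
  if (length(sample_a) < 10 || length(sample_b) < 10)
    stop("need at least 10 events per sample")
  rng <- range(c(sample_a, sample_b))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  hist_pts <- function(s) {
    h <- graphics::hist(s, breaks = breaks, plot = FALSE)
    list(x = h$mids, y = h$density)
  }
  ha <- hist_pts(sample_a); hb <- hist_pts(sample_b)
  moment_start <- function(s) {
    sk <- mean(((s - mean(s)) / stats::sd(s))^3)
    list(c(mean(s), log(stats::sd(s)), 0),
         c(mean(s) - stats::sd(s) * sign(sk), log(stats::sd(s)),
           3 * sign(if (sk == 0) 1 else sk)))
  }
  pooled <- .fit_skewnorm_ls(c(ha$x, hb$x), c(ha$y, hb$y),
                             moment_start(c(sample_a, sample_b)))
  fa <- .fit_skewnorm_ls(ha$x, ha$y, moment_start(sample_a))
  fb <- .fit_skewnorm_ls(hb$x, hb$y, moment_start(sample_b))
  df1 <- 3L
  df2 <- 2L * n_bins - 6L
  if (is.null(pooled) || is.null(fa) || is.null(fb) ||
      pooled$convergence != 0 || fa$convergence != 0 ||
      fb$convergence != 0) {
    return(structure(list(ss_pooled = NA_real_, ss_separate = NA_real_,
                          F = NA_real_, df1 = df1, df2 = df2,
                          P = NA_real_, converged = FALSE),
                     class = "dist_comparison"))
  }
  ss_pooled <- pooled$value
  ss_separate <- fa$value + fb$value
  # separate fits nest the pooled one; numerical optimisers can land a
  # hair above, so clamp the improvement at zero
  f_stat <- max(0, (ss_pooled - ss_separate) / df1) / (ss_separate / df2)
  structure(list(ss_pooled = ss_pooled, ss_separate = ss_separate,
                 F = f_stat, df1 = df1, df2 = df2,
                 P = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
                 converged = TRUE),
            class = "dist_comparison")
}

#' @export
print.dist_comparison <- function(x, ...) {
  if (!x$converged) {
    cat("Skew-normal distribution comparison: fit did not converge\n")
  } else {
    cat(sprintf(
      "Skew-normal distribution comparison: F(%d, %d) = %.3f, P = %.4g\n",
      x$df1, x$df2, x$F, x$P))
  }
  invisible(x)
}

#' Exclude slow-rising events
#'
#' Removes events whose rise time exceeds the cutoff (default 2 ms), the
#' standard guard against dendritically filtered synaptic events before
#' amplitude comparisons.
#'
#' @param events data frame with at least a `rise_time_ms` column.
#' @param max_rise_ms inclusive rise-time cutoff in ms (default 2).
#' @return the subset with `rise_time_ms <= max_rise_ms`.
#' @export
filter_events_by_rise_time <- function(events, max_rise_ms = 2) {
  if (!"rise_time_ms" %in% names(events))
    stop("events need a 'rise_time_ms' column")
  events[events$rise_time_ms <= max_rise_ms, , drop = FALSE]
}
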