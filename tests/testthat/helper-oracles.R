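# Independent brute-force oracles used to cross-check the vectorised
# implementations.  These deliberately use plain element-by-element loops.

# sleep scorer: scan runs of zero activity with an explicit while loop
oracle_score_sleep <- function(values, onset = "fourth_bin", thr = 4L) {
  n <- length(values)
  flags <- logical(n)
  i <- 1L
  while (i <= n) {
    if (values[i] == 0) {
      j <- i
      while (j <= n && values[j] == 0) j <- j + 1L
      if (j - i >= thr) {
        from <- if (onset == "fourth_bin") i + thr - 1L else i
        flags[from:(j - 1L)] <- TRUE
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  flags
}

# activity-bout scanner: returns data frame of maximal active runs
oracle_active_runs <- function(values) {
  n <- length(values)
  starts <- integer(0); lens <- integer(0)
  i <- 1L
  while (i <= n) {
    if (values[i] > 0) {
      j <- i
      while (j <= n && values[j] > 0) j <- j + 1L
      starts <- c(starts, i - 1L)
      lens <- c(lens, j - i)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  data.frame(start_bin = starts, n_bins = lens)
}

# random short trace with plenty of zero runs
random_trace <- function(n_bins = 200, p_zero = 0.55) {
  v <- ifelse(stats::runif(n_bins) < p_zero, 0,
              stats::runif(n_bins, 1, 100))
  activity_trace(v, bin_seconds = 10, subject_id = "rand")
}

# mixed-design two-way RM ANOVA sums of squares by direct mean
# decomposition (balanced table)
oracle_rm_anova_ss <- function(tab) {
  y <- tab$value
  gm <- mean(y)
  gmean <- stats::ave(y, tab$genotype)
  lmean <- stats::ave(y, tab$level)
  smean <- stats::ave(y, tab$subject)
  cmean <- stats::ave(y, tab$genotype, tab$level)
  c(genotype = sum((gmean - gm)^2),
    subject = sum((smean - gmean)^2),
    level = sum((lmean - gm)^2),
    `genotype:level` = sum((cmean - gmean - lmean + gm)^2),
    residual = sum((y - cmean - smean + gmean)^2))
}

# skew-normal sampler (Azzalini representation), for distribution tests
rskewnorm <- function(n, xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  z1 <- abs(stats::rnorm(n)); z2 <- stats::rnorm(n)
  xi + omega * (delta * z1 + sqrt(1 - delta^2) * z2)
}

# noiseless three-parameter dose-response curve (independent of package
# internals)
oracle_dose_response <- function(conc, bottom, top, ec50) {
  bottom + (top - bottom) / (1 + ec50 / conc)
}
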