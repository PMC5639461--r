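#' Chi-square periodogram (Sokolove-Bushell)
#'
#' For each candidate period of P analysis bins, the series of N bins is
#' folded into P phase columns and the rhythm power is
#' \deqn{Q_p = N \sum_h n_h (\bar x_h - \bar x)^2 / \sum_i (x_i - \bar x)^2,}
#' where \eqn{\bar x_h} are the column means over \eqn{n_h} entries and
#' \eqn{\bar x} the grand mean.  Under the white-noise null, Qp is
#' approximately chi-square distributed with P - 1 degrees of freedom; the
#' per-period significance line is the chi-square quantile at 1 - alpha.
#' No multiple-testing correction is applied across periods, matching the
#' single plotted significance line of conventional actigraphy software.
#'
#' An incomplete final cycle is used as-is (column means over unequal
#' counts, the standard treatment); `complete_cycles = TRUE` truncates the
#' series to whole cycles of each candidate period instead.
#'
#' A constant series has zero variance; Qp is defined as 0 everywhere in
#' that degenerate case.
#'
#' @param x numeric series on a uniform grid (e.g. activity per analysis
#'   bin, or hourly sleep flags), or an [activity_trace()] (down-binned to
#'   `analysis_bin_s` first).
#' @param period_range_h numeric length-2, candidate period range in hours.
#' @param analysis_bin_s width of the analysis bins in seconds (default
#'   360 s = 6 min for traces, giving 0.1-h period resolution; for plain
#'   vectors it declares the grid of `x`).
#' @param step_bins period step in analysis bins (default 1).
#' @param alpha per-period significance level (default 0.01).
#' @param complete_cycles truncate to whole cycles per period?
#' @return A `periodogram`: data frame with `period_h`, `period_bins`,
#'   `Qp`, `df`, `threshold`, plus attributes `alpha` and
#'   `analysis_bin_s`.
#' @export
chi_square_periodogram <- function(x, period_range_h,
                                   analysis_bin_s = 360,
                                   step_bins = 1, alpha = 0.01,
                                   complete_cycles = FALSE) {
  if (inherits(x, "activity_trace")) {
    x <- downbin(x$values, x$bin_seconds, analysis_bin_s)
  }
  x <- as.numeric(x)
  n <- length(x)
  if (length(period_range_h) != 2 || diff(period_range_h) < 0)
    stop("period_range_h must be (lo, hi) with lo <= hi")
  p_lo <- max(2L, as.integer(round(period_range_h[1] * 3600 / analysis_bin_s)))
  p_hi <- as.integer(round(period_range_h[2] * 3600 / analysis_bin_s))
  if (2L * p_hi > n)
    stop("series too short: need at least two cycles of the longest period")
  periods <- seq.int(p_lo, p_hi, by = as.integer(step_bins))
  grand <- mean(x)
  ss_tot_full <- sum((x - grand)^2)
  qp <- numeric(length(periods))
  for (k in seq_along(periods)) {
    p <- periods[k]
    if (complete_cycles) {
      nn <- (n %/% p) * p
      xx <- x[seq_len(nn)]
      m <- mean(xx)
      ss <- sum((xx - m)^2)
      if (ss <= 0) { qp[k] <- 0; next }
      col <- (seq_len(nn) - 1L) %% p
      nh <- tabulate(col + 1L, nbins = p)
      mh <- rowsum(xx, col)[, 1] / nh
      qp[k] <- nn * sum(nh * (mh - m)^2) / ss
    } else {
      if (ss_tot_full <= 0) { qp[k] <- 0; next }
      col <- (seq_len(n) - 1L) %% p
      nh <- tabulate(col + 1L, nbins = p)
      mh <- rowsum(x, col)[, 1] / nh
      qp[k] <- n * sum(nh * (mh - grand)^2) / ss_tot_full
    }
  }
  dfree <- periods - 1L
  pg <- data.frame(period_h = periods * analysis_bin_s / 3600,
                   period_bins = periods,
                   Qp = qp,
                   df = dfree,
                   threshold = stats::qchisq(1 - alpha, dfree))
  attr(pg, "alpha") <- alpha
  attr(pg, "analysis_bin_s") <- analysis_bin_s
  class(pg) <- c("periodogram", "data.frame")
  pg
}

# Aggregate fine bins into coarser analysis bins (mean); trailing partial
# analysis bin is dropped.
downbin <- function(values, bin_s, analysis_bin_s) {
  if (analysis_bin_s == bin_s) return(values)
  if (analysis_bin_s %% bin_s != 0)
    stop("analysis_bin_s must be a multiple of the trace bin width")
  k <- analysis_bin_s %/% bin_s
  n <- (length(values) %/% k) * k
  colMeans(matrix(values[seq_len(n)], nrow = k))
}

#' @export
print.periodogram <- function(x, ...) {
  i <- which.max(x$Qp)
  cat(sprintf(
    "Chi-square periodogram: %d periods in [%.2f, %.2f] h; peak Qp %.1f at %.2f h (%s threshold)\n",
    nrow(x), min(x$period_h), max(x$period_h), x$Qp[i], x$period_h[i],
    if (x$Qp[i] > x$threshold[i]) "above" else "below"))
  invisible(x)
}

#' Estimate the free-running period (tau) from a periodogram
#'
#' Tau is the candidate period with the largest Qp inside the search
#' range, reported only when that Qp exceeds its per-period significance
#' line; otherwise the series is called arrhythmic and `NA` is returned.
#' Ties are broken toward the shorter period (deterministic).
#'
#' @param pg a `periodogram` from [chi_square_periodogram()].
#' @param search_range_h period range searched, in hours.  Typical ranges:
#'   c(20, 28) for mouse actigraphy, c(16, 120) for ultra-long human
#'   sleep-wake diaries.
#' @return list with `tau_h` (or `NA`), `peak_Qp`, `threshold`,
#'   `significant`.
#' @export
estimate_tau <- function(pg, search_range_h = c(20, 28)) {
  stopifnot(inherits(pg, "periodogram"))
  sel <- pg$period_h >= search_range_h[1] & pg$period_h <= search_range_h[2]
  if (!any(sel)) stop("periodogram does not cover the search range")
  sub <- pg[sel, ]
  i <- which.max(sub$Qp)  # which.max returns the first (shortest) maximum
  sig <- sub$Qp[i] > sub$threshold[i]
  list(tau_h = if (sig) sub$period_h[i] else NA_real_,
       peak_Qp = sub$Qp[i],
       threshold = sub$threshold[i],
       significant = sig)
}

#' Double-plotted actogram matrix
#'
#' Row i of a double-plotted actogram shows day i followed by day i + 1
#' (each "day" being one modulo period, 24 h by default), so that a rhythm
#' with period different from the modulo drifts as a visible diagonal.
#' Values are normalised to \[0, 1\]; the right half of the last row is
#' padded with `NA`.
#'
#' @param x numeric series, or an [activity_trace()].
#' @param modulo_h fold period in hours (default 24; set to an estimated
#'   tau to straighten a free-running rhythm into a vertical band).
#' @param analysis_bin_s analysis bin width in seconds (declares the grid
#'   of plain vectors; traces are down-binned).
#' @return numeric matrix, one row per plotted day, `2 * modulo_h`-worth
#'   of columns.
#' @export
double_plot_actogram <- function(x, modulo_h = 24, analysis_bin_s = 360) {
  if (inherits(x, "activity_trace"))
    x <- downbin(x$values, x$bin_seconds, analysis_bin_s)
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty series")
  p <- as.integer(round(modulo_h * 3600 / analysis_bin_s))
  n_days <- ceiling(length(x) / p)
  if (n_days < 2) stop("need at least two days (modulo periods) to plot")
  rng <- range(x)
  xn <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else rep(0, length(x))
  padded <- c(xn, rep(NA_real_, n_days * p - length(x)))
  m <- matrix(NA_real_, nrow = n_days, ncol = 2L * p)
  for (i in seq_len(n_days)) {
    m[i, seq_len(p)] <- padded[((i - 1L) * p + 1L):(i * p)]
    if (i < n_days)
      m[i, (p + 1L):(2L * p)] <- padded[(i * p + 1L):((i + 1L) * p)]
  }
  m
}

#' Tau-adjusted mean daily activity
#'
#' Under a free-running period tau different from 24 h, raw per-24-h
#' activity means are biased by the drifting subjective day; the adjusted
#' value rescales the daily average by 24/tau.
#'
#' @param trace an [activity_trace()] or plain numeric series of
#'   percent-active values.
#' @param tau_h estimated period in hours; if `NA`, the unadjusted mean is
#'   returned with `adjusted = FALSE`.
#' @return list with `value` (mean activity per 24 h, rescaled by
#'   24/tau when tau is known), `daily_mean`, `tau_h`, `adjusted`.
#' @export
tau_adjusted_daily_activity <- function(trace, tau_h) {
  vals <- if (inherits(trace, "activity_trace")) trace$values
          else as.numeric(trace)
  daily <- mean(vals)
  if (is.na(tau_h)) {
    return(list(value = daily, daily_mean = daily, tau_h = NA_real_,
                adjusted = FALSE))
  }
  if (tau_h <= 0) stop("tau must be positive")
  list(value = 24 / tau_h * daily, daily_mean = daily, tau_h = tau_h,
       adjusted = TRUE)
}

#' Per-subject, per-lighting-block rhythm summary
#'
#' For every analysis-grade block (>= 9 uninterrupted days) of the
#' schedule, estimates tau by chi-square periodogram on the block's
#' portion of each trace and computes the tau-adjusted daily activity.
#' Short blocks are excluded with a warning; a subject whose trace does
#' not cover a block simply contributes no row for it.
#'
#' @param traces list of [activity_trace()] objects (cohort).
#' @param schedule a [lighting_schedule()] shared by the cohort.
#' @param search_range_h tau search range in hours.
#' @param analysis_bin_s periodogram analysis bin width (default 360 s).
#' @param alpha per-period significance level.
#' @return tidy data frame: `subject`, `genotype`, `block`, `condition`,
#'   `lux`, `tau_h`, `peak_Qp`, `significant`, `adjusted_activity`.
#' @export
light_response_table <- function(traces, schedule,
                                 search_range_h = c(20, 28),
                                 analysis_bin_s = 360, alpha = 0.01) {
  stopifnot(inherits(schedule, "lighting_schedule"))
  short <- which(!schedule$analysis_grade)
  if (length(short))
    warning(sprintf("excluding %d block(s) shorter than 9 days", length(short)))
  rows <- list()
  for (tr in traces) {
    t0 <- tr$start_s
    t1 <- t0 + length(tr$values) * tr$bin_seconds
    for (b in seq_len(nrow(schedule))) {
      if (!schedule$analysis_grade[b]) next
      if (schedule$start_s[b] < t0 || schedule$end_s[b] > t1) next
      i0 <- (schedule$start_s[b] - t0) / tr$bin_seconds + 1
      i1 <- (schedule$end_s[b] - t0) / tr$bin_seconds
      seg <- tr$values[i0:i1]
      pg <- chi_square_periodogram(
        downbin(seg, tr$bin_seconds, analysis_bin_s),
        period_range_h = search_range_h,
        analysis_bin_s = analysis_bin_s, alpha = alpha)
      est <- estimate_tau(pg, search_range_h)
      adj <- tau_adjusted_daily_activity(seg, est$tau_h)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = tr$subject_id, genotype = tr$genotype, block = b,
        condition = schedule$condition[b], lux = schedule$lux[b],
        tau_h = est$tau_h, peak_Qp = est$peak_Qp,
        significant = est$significant,
        adjusted_activity = adj$value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no analysis-grade block covered by any trace")
  do.call(rbind, rows)
}
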