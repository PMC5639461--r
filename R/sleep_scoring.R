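#' Score behavioural sleep from immobility
#'
#' Sustained immobility of at least 40 s (4 consecutive 10-s bins with no
#' detected movement) is scored as behavioural sleep, a rule validated
#' against EEG-defined sleep in mice.  Two onset conventions are exposed:
#'
#' * `"fourth_bin"` (default, the literal rule): sleep starts at the 4th
#'   immobile bin, so a maximal immobile run of R >= 4 bins contributes
#'   R - 3 sleep bins;
#' * `"run_start"`: the whole qualifying run (R bins) is scored, as is
#'   common in the 40-s immobility literature.
#'
#' Runs of 3 or fewer immobile bins (<= 30 s) are never sleep.  Runs
#' truncated by the trace edges are scored from the observed bins only.
#'
#' @param trace an [activity_trace()] on a 10-s grid.
#' @param onset `"fourth_bin"` or `"run_start"`.
#' @param immobility_threshold_bins minimum immobile run length in bins
#'   (default 4, i.e. 40 s at 10-s bins).
#' @param epsilon activity at or below this percent counts as immobile
#'   (default 0: any detected movement breaks a run).
#' @return A `sleep_series`: logical per-bin sleep flags on the parent
#'   grid, with the scoring parameters attached.
#' @export
score_sleep <- function(trace, onset = c("fourth_bin", "run_start"),
                        immobility_threshold_bins = 4, epsilon = 0) {
  stopifnot(inherits(trace, "activity_trace"))
  onset <- match.arg(onset)
  if (trace$bin_seconds != 10)
    stop("sleep scoring is defined on 10-s bins (thresholds are in bins)")
  immobile <- trace$values <= epsilon
  r <- rle(immobile)
  flags <- logical(length(trace$values))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- r$values & r$lengths >= immobility_threshold_bins
  for (i in which(qual)) {
    from <- if (onset == "fourth_bin")
      starts[i] + immobility_threshold_bins - 1L else starts[i]
    flags[from:ends[i]] <- TRUE
  }
  structure(list(flags = flags,
                 subject_id = trace$subject_id,
                 genotype = trace$genotype,
                 bin_seconds = trace$bin_seconds,
                 start_s = trace$start_s,
                 onset = onset,
                 immobility_threshold_bins = immobility_threshold_bins,
                 epsilon = epsilon),
            class = "sleep_series")
}

#' @export
print.sleep_series <- function(x, ...) {
  cat(sprintf(
    "Sleep series '%s': %d bins, %.1f%% asleep (%s onset, >=%d immobile bins)\n",
    x$subject_id, length(x$flags), 100 * mean(x$flags), x$onset,
    x$immobility_threshold_bins))
  invisible(x)
}

#' 24-h profiles of activity and sleep
#'
#' Folds a trace and its sleep series onto the 24-h day: hourly means
#' (with SEM across days) of percent-active and of fraction-asleep, plus
#' per-day light-period and dark-period totals from the lighting schedule.
#' Only complete days enter the profile; a trailing partial day is dropped
#' with a warning.
#'
#' @param trace an [activity_trace()].
#' @param sleep the matching `sleep_series` from [score_sleep()].
#' @param schedule a [lighting_schedule()]; required for the light/dark
#'   split.
#' @return list with `hourly` (hour 0-23, mean/SEM of activity and sleep)
#'   and `light_dark` (per-day totals of activity and sleep hours split by
#'   photophase/scotophase).
#' @export
daily_sleep_activity_profile <- function(trace, sleep, schedule = trace$schedule) {
  stopifnot(inherits(trace, "activity_trace"), inherits(sleep, "sleep_series"))
  if (is.null(schedule)) stop("a lighting schedule is required")
  if (length(sleep$flags) != length(trace$values))
    stop("sleep series does not match trace grid")
  bins_per_day <- 86400 / trace$bin_seconds
  n_days <- length(trace$values) %/% bins_per_day
  if (n_days < 1) stop("need at least one complete day")
  n_used <- n_days * bins_per_day
  if (n_used < length(trace$values))
    warning(sprintf("dropping trailing partial day (%d bins)",
                    length(trace$values) - n_used))
  vals <- trace$values[seq_len(n_used)]
  slp <- sleep$flags[seq_len(n_used)]
  t_s <- trace$start_s + (seq_len(n_used) - 1) * trace$bin_seconds
  hour <- floor((t_s %% 86400) / 3600)
  day <- floor(t_s / 86400)

  sem <- function(x) stats::sd(x) / sqrt(length(x))
  # per-day hourly means, then mean/SEM across days
  act_dh <- tapply(vals, list(day, hour), mean)
  slp_dh <- tapply(as.numeric(slp), list(day, hour), mean)
  hourly <- data.frame(
    hour = as.integer(colnames(act_dh)),
    activity_mean = apply(act_dh, 2, mean),
    activity_sem = apply(act_dh, 2, sem),
    sleep_mean = apply(slp_dh, 2, mean),
    sleep_sem = apply(slp_dh, 2, sem),
    row.names = NULL)

  dark <- is_dark_at(schedule, t_s)
  hrs_per_bin <- trace$bin_seconds / 3600
  agg <- function(x, keep) tapply(x[keep], day[keep], sum)
  days_idx <- sort(unique(day))
  z <- function(v) { out <- setNames(numeric(length(days_idx)),
                                     days_idx); out[names(v)] <- v; out }
  light_dark <- data.frame(
    day = days_idx,
    activity_light = z(agg(vals * hrs_per_bin, !dark)),
    activity_dark = z(agg(vals * hrs_per_bin, dark)),
    sleep_h_light = z(agg(as.numeric(slp) * hrs_per_bin, !dark)),
    sleep_h_dark = z(agg(as.numeric(slp) * hrs_per_bin, dark)),
    row.names = NULL)
  list(hourly = hourly, light_dark = light_dark, n_days = n_days)
}
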