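#' Segment a trace into bouts of activity
#'
#' A bout of activity is a maximal run of one or more consecutive bins in
#' which the animal was active (percent-active above `epsilon`).  Bout
#' intensity is the mean per-bin percent-active over the bout: six
#' consecutive active bins with the sensor active 30 s in total give a
#' 1-min bout at 50% intensity.
#'
#' @param trace an [activity_trace()].
#' @param epsilon activity strictly above this percent counts as active
#'   (default 0).
#' @return data frame of bouts: `kind` (`"activity"`), `start_bin`
#'   (0-based), `n_bins`, `duration_s`, `intensity`.
#' @export
segment_activity_bouts <- function(trace, epsilon = 0) {
  stopifnot(inherits(trace, "activity_trace"))
  active <- trace$values > epsilon
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty_bouts("activity"))
  s <- starts[keep]; e <- ends[keep]; n <- r$lengths[keep]
  intensity <- vapply(seq_along(s),
                      function(i) mean(trace$values[s[i]:e[i]]), numeric(1))
  data.frame(kind = "activity",
             start_bin = s - 1L,
             n_bins = n,
             duration_s = n * trace$bin_seconds,
             intensity = intensity,
             stringsAsFactors = FALSE)
}

#' Segment a sleep series into bouts of sleep
#'
#' Maximal runs of sleep-flagged bins from [score_sleep()].  Under the
#' `fourth_bin` onset convention an immobile run of R >= 4 bins yields a
#' sleep bout of R - 3 bins.
#'
#' @param sleep a `sleep_series`.
#' @return data frame of bouts: `kind` (`"sleep"`), `start_bin` (0-based),
#'   `n_bins`, `duration_s` (`intensity` is `NA` for sleep).
#' @export
segment_sleep_bouts <- function(sleep) {
  stopifnot(inherits(sleep, "sleep_series"))
  r <- rle(sleep$flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty_bouts("sleep"))
  s <- starts[keep]; n <- r$lengths[keep]
  data.frame(kind = "sleep",
             start_bin = s - 1L,
             n_bins = n,
             duration_s = n * sleep$bin_seconds,
             intensity = NA_real_,
             stringsAsFactors = FALSE)
}

empty_bouts <- function(kind) {
  data.frame(kind = character(0), start_bin = integer(0),
             n_bins = integer(0), duration_s = numeric(0),
             intensity = numeric(0), stringsAsFactors = FALSE)
}

#' Default bout-length category edges, in seconds
#'
#' The four canonical length classes: <1 min, 1-10 min, 10 min-1 h, >1 h,
#' as half-open intervals \[lo, hi).
#' @export
bout_length_edges <- c(0, 60, 600, 3600, Inf)

#' Labels for the default length categories
#' @export
bout_length_labels <- c("<1min", "1-10min", "10min-1h", ">1h")

#' Categorise bouts by length (and optionally intensity)
#'
#' Bins bout durations into half-open categories \[lo, hi); the last
#' category is open-ended, so every bout lands in exactly one class and
#' counts are conserved.  A 50-s bout is `<1min`; a 60-s bout falls in
#' `1-10min` under the half-open convention.
#'
#' @param bouts data frame from [segment_activity_bouts()] or
#'   [segment_sleep_bouts()].
#' @param length_edges strictly increasing numeric edges in seconds,
#'   ending in `Inf` (default [bout_length_edges]).
#' @param length_labels labels, one fewer than edges.
#' @param intensity_edges optional strictly increasing percent edges for
#'   activity-bout intensity classes (e.g. `seq(0, 100, 10)`); when given,
#'   an `intensity_counts` table is also returned.
#' @param days_observed if supplied, per-day counts (`count / days`) are
#'   added alongside raw totals.
#' @return list with `length_counts` (data frame `category`, `count`,
#'   and `count_per_day` when `days_observed` is given) and optionally
#'   `intensity_counts`.
#' @export
categorize_bouts <- function(bouts, length_edges = bout_length_edges,
                             length_labels = NULL,
                             intensity_edges = NULL,
                             days_observed = NULL) {
  if (is.unsorted(length_edges, strictly = TRUE))
    stop("length edges must be strictly increasing")
  k <- length(length_edges) - 1
  if (is.null(length_labels)) {
    length_labels <- if (identical(length_edges, bout_length_edges))
      bout_length_labels
    else paste0("[", length_edges[-length(length_edges)], ",",
                length_edges[-1], ")")
  }
  stopifnot(length(length_labels) == k)
  cat_idx <- findInterval(bouts$duration_s, length_edges,
                          rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(cat_idx, nbins = k)
  length_counts <- data.frame(category = factor(length_labels,
                                                levels = length_labels),
                              count = counts)
  if (!is.null(days_observed))
    length_counts$count_per_day <- counts / days_observed
  out <- list(length_counts = length_counts, total = nrow(bouts))
  if (!is.null(intensity_edges)) {
    if (is.unsorted(intensity_edges, strictly = TRUE))
      stop("intensity edges must be strictly increasing")
    ib <- bouts[bouts$kind == "activity", , drop = FALSE]
    ki <- length(intensity_edges) - 1
    ii <- findInterval(pmin(ib$intensity, intensity_edges[ki + 1] - 1e-9),
                       intensity_edges)
    out$intensity_counts <- data.frame(
      category = paste0("[", intensity_edges[-(ki + 1)], ",",
                        intensity_edges[-1], ")"),
      count = tabulate(ii, nbins = ki))
  }
  out
}

#' Per-subject bout category table for a cohort
#'
#' Runs sleep scoring, bout segmentation and length categorisation for a
#' list of traces and returns a tidy table ready for the repeated-measures
#' ANOVA: one row per subject x bout kind x length category.
#'
#' @param traces list of [activity_trace()] objects.
#' @param onset sleep-onset convention passed to [score_sleep()].
#' @param length_edges category edges in seconds.
#' @return data frame with columns `subject`, `genotype`, `kind`,
#'   `category`, `count`, `count_per_day`, `days_observed`.
#' @export
cohort_bout_table <- function(traces, onset = "fourth_bin",
                              length_edges = bout_length_edges) {
  rows <- lapply(traces, function(tr) {
    days <- length(tr$values) * tr$bin_seconds / 86400
    ab <- segment_activity_bouts(tr)
    sl <- score_sleep(tr, onset = onset)
    sb <- segment_sleep_bouts(sl)
    a <- categorize_bouts(ab, length_edges, days_observed = days)$length_counts
    s <- categorize_bouts(sb, length_edges, days_observed = days)$length_counts
    a$kind <- "activity"; s$kind <- "sleep"
    out <- rbind(a, s)
    out$subject <- tr$subject_id
    out$genotype <- tr$genotype
    out$days_observed <- days
    out
  })
  out <- do.call(rbind, rows)
  out[, c("subject", "genotype", "kind", "category", "count",
          "count_per_day", "days_observed")]
}
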