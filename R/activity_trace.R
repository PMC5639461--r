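#' Construct an activity trace
#'
#' An activity trace is a uniformly-gridded series of percent-active values
#' from a passive-infrared sensor: the sensor is polled at high frequency
#' and the fraction of polls with movement in each bin (canonically 10 s)
#' is reported as a percentage in \[0, 100\].  Bins are half-open
#' \[t, t + bin_seconds) and indexed from 0.
#'
#' @param values numeric vector of percent-active per bin, each in
#'   \[0, 100\].
#' @param bin_seconds bin width in seconds (default 10); must divide 60.
#' @param subject_id subject identifier.
#' @param genotype genotype label (free text, e.g. `"WT"` / `"MUT"`).
#' @param start_s trace start in seconds (offset into the lighting
#'   schedule; default 0).
#' @param schedule optional [lighting_schedule()] covering the trace.
#' @return An `activity_trace` object.
#' @export
activity_trace <- function(values, bin_seconds = 10, subject_id = "s1",
                           genotype = NA_character_, start_s = 0,
                           schedule = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty activity trace")
  bad <- which(!is.finite(values) | values < 0 | values > 100)
  if (length(bad))
    stop(sprintf("percent-active out of [0,100] at bin %d (value %s)",
                 bad[1] - 1L, format(values[bad[1]])))
  if (bin_seconds <= 0 || 60 %% bin_seconds != 0)
    stop("bin_seconds must be positive and divide 60")
  structure(
    list(subject_id = as.character(subject_id),
         genotype = as.character(genotype),
         start_s = as.numeric(start_s),
         bin_seconds = as.numeric(bin_seconds),
         values = values,
         schedule = schedule),
    class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf(
    "Activity trace '%s' (%s): %d bins of %gs (%.2f days), mean %.1f%% active\n",
    x$subject_id, x$genotype, length(x$values), x$bin_seconds,
    length(x$values) * x$bin_seconds / 86400, mean(x$values)))
  invisible(x)
}

#' @export
length.activity_trace <- function(x) length(x$values)

#' Bin-start times of a trace, in seconds
#'
#' @param trace an [activity_trace()].
#' @return numeric vector, one entry per bin.
#' @export
trace_times <- function(trace) {
  trace$start_s + (seq_along(trace$values) - 1) * trace$bin_seconds
}

#' Write an activity trace to CSV
#'
#' Metadata (subject, genotype, bin width, start offset) is echoed as
#' commented header lines, followed by a two-column table `bin_index`,
#' `percent_active`.
#'
#' @param trace an [activity_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(trace, path) {
  stopifnot(inherits(trace, "activity_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# subject_id=%s", trace$subject_id),
    sprintf("# genotype=%s", trace$genotype),
    sprintf("# bin_seconds=%g", trace$bin_seconds),
    sprintf("# start_s=%g", trace$start_s),
    "bin_index,percent_active"), con)
  writeLines(sprintf("%d,%s", seq_along(trace$values) - 1L,
                     format(trace$values, digits = 15, trim = TRUE,
                            scientific = FALSE)), con)
  invisible(path)
}

#' Read an activity trace from CSV
#'
#' Expects the layout written by [write_activity_csv()]: commented metadata
#' lines, a header row, then `bin_index,percent_active` rows.  The bin grid
#' must be uniform; a missing bin is a hard error under the default gap
#' policy (`"error"`), or is zero-filled with a warning under
#' `gap_policy = "zero_fill"` (sensor-silent bins read as immobile).
#' Out-of-range values fail validation with the offending bin named.
#'
#' @param path input file path.
#' @param gap_policy `"error"` (default) or `"zero_fill"`.
#' @param schedule optional [lighting_schedule()] to attach.
#' @return An [activity_trace()].
#' @export
read_activity_csv <- function(path, gap_policy = c("error", "zero_fill"),
                              schedule = NULL) {
  gap_policy <- match.arg(gap_policy)
  lines <- readLines(path)
  meta_ln <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_ln) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("bin_index", "percent_active") %in% names(df)))
    stop("activity CSV needs columns 'bin_index' and 'percent_active'")
  idx <- as.integer(df$bin_index)
  vals <- as.numeric(df$percent_active)
  if (anyDuplicated(idx)) stop("duplicate bin indices in activity CSV")
  full <- seq.int(min(idx), max(idx))
  if (length(full) != length(idx) || any(sort(idx) != full)) {
    missing_bins <- setdiff(full, idx)
    if (gap_policy == "error")
      stop(sprintf("non-uniform grid: %d missing bin(s), first at index %d",
                   length(missing_bins), missing_bins[1]))
    warning(sprintf("zero-filled %d missing bin(s)", length(missing_bins)))
    filled <- numeric(length(full))
    filled[match(idx, full)] <- vals
    vals <- filled
  } else {
    vals <- vals[order(idx)]
  }
  activity_trace(
    vals,
    bin_seconds = as.numeric(meta$bin_seconds %||% 10),
    subject_id = meta$subject_id %||% "s1",
    genotype = meta$genotype %||% NA_character_,
    start_s = as.numeric(meta$start_s %||% 0),
    schedule = schedule)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an hourly sleep diary to CSV
#'
#' @param diary a `diary_series` from [simulate_sleep_diary()] or
#'   [diary_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_diary_csv <- function(diary, path) {
  stopifnot(inherits(diary, "diary_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id=%s", diary$subject_id),
               "hour_index,asleep"), con)
  writeLines(sprintf("%d,%d", seq_along(diary$asleep) - 1L,
                     as.integer(diary$asleep)), con)
  invisible(path)
}

#' Read an hourly sleep diary from CSV
#'
#' @param path input file path.
#' @return A [diary_series()].
#' @export
read_diary_csv <- function(path) {
  lines <- readLines(path)
  meta_ln <- grep("^#", lines, value = TRUE)
  subject <- "s1"
  for (ln in meta_ln) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2 && kv[1] == "subject_id") subject <- kv[2]
  }
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                     collapse = "\n"))
  diary_series(df$asleep[order(df$hour_index)], subject_id = subject)
}

#' Construct an hourly sleep diary series
#'
#' Hourly binary sleep/wake flags over 27-28 days, the resolution at which
#' long sleep-wake cycles are recorded by caregivers.
#'
#' @param asleep logical/0-1 vector, one flag per hour.
#' @param subject_id subject identifier.
#' @return A `diary_series` object.
#' @export
diary_series <- function(asleep, subject_id = "s1") {
  asleep <- as.integer(asleep)
  if (length(asleep) == 0L) stop("empty diary")
  if (!all(asleep %in% c(0L, 1L))) stop("diary flags must be binary")
  if (length(asleep) %% 24 != 0)
    stop("diary length must be a whole number of days")
  structure(list(subject_id = as.character(subject_id),
                 asleep = asleep,
                 days = length(asleep) / 24),
            class = "diary_series")
}

#' @export
print.diary_series <- function(x, ...) {
  cat(sprintf("Sleep diary '%s': %d days, duty cycle %.2f\n",
              x$subject_id, x$days, mean(x$asleep)))
  invisible(x)
}
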