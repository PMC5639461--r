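#' Construct a lighting schedule
#'
#' A lighting schedule is an ordered, contiguous sequence of experimental
#' blocks, each run under one lighting condition: a 12:12 light:dark cycle
#' (`"LD"`), constant darkness (`"DD"`, < 1 lux) or constant light (`"LL"`
#' at a stated lux level).  Time is kept as integer seconds from the start
#' of the recording; the schedule defines the subjective day structure for
#' every downstream analysis.
#'
#' Blocks of at least 9 uninterrupted days are flagged `analysis_grade`:
#' shorter blocks are kept (e.g. for plotting) but excluded from circadian
#' period estimation.
#'
#' @param condition character vector, one of `"LD"`, `"DD"`, `"LL"` per block.
#' @param lux numeric vector, illuminance of the lit phase (LD) or of the
#'   whole block (LL).  DD blocks conventionally use a value < 1.
#' @param days numeric vector, duration of each block in days.
#' @param lights_on_h hour-of-day at which lights come on in LD blocks
#'   (default 0, i.e. each LD block starts at lights-on).
#' @return A `lighting_schedule`: a data frame with one row per block and
#'   columns `condition`, `lux`, `days`, `start_s`, `end_s`, `analysis_grade`.
#' @examples
#' lighting_schedule(c("LD", "DD"), lux = c(150, 0.5), days = c(7, 10))
#' @export
lighting_schedule <- function(condition, lux, days, lights_on_h = 0) {
  condition <- match.arg(as.character(condition), c("LD", "DD", "LL"),
                         several.ok = TRUE)
  n <- length(condition)
  lux <- rep_len(as.numeric(lux), n)
  days <- rep_len(as.numeric(days), n)
  if (any(!is.finite(days)) || any(days <= 0))
    stop("block durations must be positive")
  if (any(!is.finite(lux)) || any(lux < 0))
    stop("lux must be >= 0")
  end_s <- cumsum(days) * 86400
  sched <- data.frame(
    condition = condition,
    lux = lux,
    days = days,
    start_s = c(0, end_s[-n]),
    end_s = end_s,
    analysis_grade = days >= 9,
    stringsAsFactors = FALSE
  )
  attr(sched, "lights_on_h") <- lights_on_h
  class(sched) <- c("lighting_schedule", "data.frame")
  sched
}

#' Read a lighting schedule from YAML or JSON
#'
#' The file holds a list of blocks, each a mapping with keys `condition`,
#' `lux` and `days` (or `start_h`/`end_h` in hours).  Blocks must be
#' non-overlapping and contiguous; any overlap or gap is an error.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file (JSON is a subset of
#'   YAML, so both go through the same parser).
#' @return A [lighting_schedule()].
#' @export
read_lighting_schedule <- function(path) {
  blocks <- yaml::read_yaml(path)
  if (!is.null(blocks$blocks)) blocks <- blocks$blocks
  if (length(blocks) == 0L) stop("schedule file contains no blocks")
  get <- function(b, k) if (is.null(b[[k]])) NA_real_ else as.numeric(b[[k]])
  cond <- vapply(blocks, function(b) as.character(b$condition), character(1))
  lux <- vapply(blocks, function(b) get(b, "lux"), numeric(1))
  days <- vapply(blocks, function(b) get(b, "days"), numeric(1))
  start_h <- vapply(blocks, function(b) get(b, "start_h"), numeric(1))
  end_h <- vapply(blocks, function(b) get(b, "end_h"), numeric(1))
  if (all(is.na(days))) {
    if (any(is.na(start_h)) || any(is.na(end_h)))
      stop("each block needs either 'days' or both 'start_h' and 'end_h'")
    o <- order(start_h)
    start_h <- start_h[o]; end_h <- end_h[o]
    cond <- cond[o]; lux <- lux[o]
    if (start_h[1] != 0)
      stop("schedule must start at hour 0")
    if (any(end_h <= start_h))
      stop("block end must be after block start")
    if (length(start_h) > 1) {
      gap <- start_h[-1] - end_h[-length(end_h)]
      if (any(gap > 0)) stop("gap between schedule blocks")
      if (any(gap < 0)) stop("overlapping schedule blocks")
    }
    days <- (end_h - start_h) / 24
  } else if (any(is.na(days))) {
    stop("mix of 'days' and 'start_h'/'end_h' blocks is not supported")
  }
  if (any(is.na(lux))) stop("each block needs a 'lux' value")
  lighting_schedule(cond, lux, days)
}

#' Illuminance at given times under a schedule
#'
#' LD blocks alternate `lux` (photophase, first 12 h of each block-relative
#' day by default) with 0 (scotophase); DD and LL blocks are constant.
#' Times at or beyond the schedule end return `NA`.
#'
#' @param schedule a [lighting_schedule()].
#' @param t_s numeric vector of times in seconds from recording start.
#' @return numeric vector of lux values.
#' @export
lux_at <- function(schedule, t_s) {
  stopifnot(inherits(schedule, "lighting_schedule"))
  lights_on_h <- attr(schedule, "lights_on_h")
  if (is.null(lights_on_h)) lights_on_h <- 0
  out <- rep(NA_real_, length(t_s))
  for (i in seq_len(nrow(schedule))) {
    in_blk <- t_s >= schedule$start_s[i] & t_s < schedule$end_s[i]
    if (!any(in_blk)) next
    if (schedule$condition[i] == "LD") {
      rel_h <- ((t_s[in_blk] - schedule$start_s[i]) / 3600 - lights_on_h) %% 24
      out[in_blk] <- ifelse(rel_h < 12, schedule$lux[i], 0)
    } else {
      out[in_blk] <- schedule$lux[i]
    }
  }
  out
}

#' Dark-phase indicator
#'
#' `TRUE` where the schedule puts less than 1 lux on the animal (scotophase
#' of LD blocks and all of DD).
#'
#' @inheritParams lux_at
#' @return logical vector.
#' @export
is_dark_at <- function(schedule, t_s) {
  lx <- lux_at(schedule, t_s)
  lx < 1
}

#' @export
print.lighting_schedule <- function(x, ...) {
  cat("Lighting schedule:", nrow(x), "block(s),",
      sum(x$days), "days total\n")
  print.data.frame(x, ...)
  invisible(x)
}
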