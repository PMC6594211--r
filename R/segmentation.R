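#' Detect bed intervals from actigraphy
#'
#' The time of going to bed and getting out of bed is taken from the
#' actigraphy lying/sleep indications: for each night, the bed interval is
#' the maximal run of consecutive lying minutes that contains the first sleep
#' minute of that night. Runs shorter than \code{min_bed_minutes} (default
#' 180) never count as bed intervals, so afternoon naps are not nights.
#' Nights are delimited noon-to-noon; a night without any qualifying run is
#' simply absent from the result.
#'
#' @param act an [actigraphy_series()].
#' @param cfg an [oxiweek_config()].
#' @return data.frame of class \code{bed_intervals} with columns
#'   \code{bed_start}, \code{bed_end} (half-open \code{[start, end)},
#'   minute-aligned), sorted and non-overlapping.
#' @export
detect_bed_intervals <- function(act, cfg = oxiweek_config()) {
  stopifnot(inherits(act, "actigraphy_series"))
  if (nrow(act) == 0) stop("empty actigraphy series: cannot detect bed intervals")
  t <- tnum(act$time)
  # break runs where the minute grid is interrupted (device off)
  contiguous <- c(TRUE, diff(t) == 60)
  grp <- cumsum(!contiguous)
  run_id <- integer(nrow(act))
  starts <- ends <- integer(0)
  # maximal lying runs within each contiguous stretch
  for (g in unique(grp)) {
    idx <- which(grp == g)
    r <- rle(act$lying[idx] == 1L)
    stop_at <- cumsum(r$lengths)
    start_at <- stop_at - r$lengths + 1L
    keep <- which(r$values)
    starts <- c(starts, idx[start_at[keep]])
    ends <- c(ends, idx[stop_at[keep]])
  }
  if (!length(starts)) {
    return(empty_bed_intervals())
  }
  qual <- logical(length(starts))
  first_sleep <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    span <- starts[i]:ends[i]
    len_min <- length(span)
    has_sleep <- any(act$sleep[span] == 1L)
    qual[i] <- has_sleep && len_min >= cfg$min_bed_minutes
    if (has_sleep) first_sleep[i] <- t[span[which(act$sleep[span] == 1L)[1]]]
  }
  starts <- starts[qual]; ends <- ends[qual]; first_sleep <- first_sleep[qual]
  if (!length(starts)) return(empty_bed_intervals())
  # one interval per noon-to-noon night: the run holding that night's first
  # sleep minute
  night_id <- as.integer(floor((first_sleep - 12 * 3600) / 86400))
  keep <- integer(0)
  for (nid in sort(unique(night_id))) {
    cand <- which(night_id == nid)
    keep <- c(keep, cand[which.min(first_sleep[cand])])
  }
  out <- data.frame(
    bed_start = act$time[starts[keep]],
    bed_end = act$time[ends[keep]] + 60  # half-open: last lying minute + 60 s
  )
  out <- out[order(out$bed_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bed_intervals", "data.frame")
  out
}

empty_bed_intervals <- function() {
  out <- data.frame(bed_start = oxi_time(character()),
                    bed_end = oxi_time(character()))
  class(out) <- c("bed_intervals", "data.frame")
  out
}

new_segment <- function(kind, start, end, spo2, unsegmentable = FALSE) {
  seg <- list(kind = kind, start = start, end = end,
              date = format(start, "%Y-%m-%d", tz = .oxi_tz),
              spo2 = spo2, unsegmentable = unsegmentable)
  class(seg) <- "oxi_segment"
  seg
}

#' @export
print.oxi_segment <- function(x, ...) {
  cat(sprintf("<oxi_segment> %s %s [%s, %s) %d samples%s\n", x$kind, x$date,
              format_iso_time(x$start), format_iso_time(x$end),
              nrow(x$spo2), if (x$unsegmentable) " (unsegmentable)" else ""))
  invisible(x)
}

#' Split an SpO2 stream into night and day segments
#'
#' Night segments coincide with bed intervals; day segments fill the gaps
#' between consecutive bed intervals (and before the first / after the last).
#' Intervals are half-open \code{[start, end)}, so a sample exactly at a bed
#' start belongs to the night and no sample is ever counted twice. With no
#' bed intervals at all, the whole stream becomes a single day segment
#' flagged \code{unsegmentable}, which the retention rules then exclude.
#'
#' @param spo2 an [spo2_series()].
#' @param beds a \code{bed_intervals} data.frame from
#'   [detect_bed_intervals()].
#' @return list of \code{oxi_segment}s in time order; every input sample is
#'   in exactly one segment.
#' @export
split_day_night <- function(spo2, beds) {
  stopifnot(inherits(spo2, "spo2_series"))
  if (nrow(spo2) == 0) stop("empty SpO2 series: nothing to segment")
  if (is.null(beds) || nrow(beds) == 0) {
    seg <- new_segment("day", spo2$time[1], spo2$time[nrow(spo2)] + 1,
                       spo2, unsegmentable = TRUE)
    return(list(seg))
  }
  if (any(tnum(beds$bed_end) <= tnum(beds$bed_start))) {
    stop("bed interval with bed_end <= bed_start")
  }
  if (nrow(beds) > 1 &&
      any(tnum(beds$bed_start[-1]) < tnum(beds$bed_end[-nrow(beds)]))) {
    stop("overlapping bed intervals")
  }
  ts <- tnum(spo2$time)
  first_t <- min(ts[1], tnum(beds$bed_start[1]))
  last_t <- max(ts[length(ts)] + 1, tnum(beds$bed_end[nrow(beds)]))
  # explicit tiling of [first_t, last_t): day gaps interleaved with nights
  starts <- numeric(0); ends <- numeric(0); kinds <- character(0)
  cursor <- first_t
  for (k in seq_len(nrow(beds))) {
    bs <- tnum(beds$bed_start[k]); be <- tnum(beds$bed_end[k])
    if (bs > cursor) {
      starts <- c(starts, cursor); ends <- c(ends, bs); kinds <- c(kinds, "day")
    }
    starts <- c(starts, bs); ends <- c(ends, be); kinds <- c(kinds, "night")
    cursor <- be
  }
  if (last_t > cursor) {
    starts <- c(starts, cursor); ends <- c(ends, last_t)
    kinds <- c(kinds, "day")
  }
  slot <- findInterval(ts, starts, rightmost.closed = FALSE, left.open = FALSE)
  segs <- vector("list", length(starts))
  for (i in seq_along(segs)) {
    sub <- spo2[slot == i, , drop = FALSE]
    class(sub) <- class(spo2)
    rownames(sub) <- NULL
    segs[[i]] <- new_segment(kinds[i], oxi_time(starts[i]), oxi_time(ends[i]),
                             sub)
  }
  segs
}

#' Apply the study's retention rules to segments
#'
#' A day is retained when it holds at least one hour (default 3600 s) of SpO2
#' samples; a night is retained only when the recording covers at least the
#' full-night coverage fraction (default 0.9) of the bed interval.
#' Unsegmentable streams (no day/night distinction possible) are always
#' excluded. Every exclusion is logged with its rule and the measured
#' quantity.
#'
#' @param segments list of \code{oxi_segment}s from [split_day_night()].
#' @param cfg an [oxiweek_config()].
#' @return list with \code{retained} (list of segments) and \code{log}
#'   (data.frame: date, kind, rule, measured).
#' @export
apply_retention_rules <- function(segments, cfg = oxiweek_config()) {
  keep <- logical(length(segments))
  log <- list()
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    n <- nrow(seg$spo2)
    if (isTRUE(seg$unsegmentable)) {
      log[[length(log) + 1]] <- data.frame(
        date = seg$date, kind = seg$kind, rule = "unsegmentable",
        measured = n)
      next
    }
    if (seg$kind == "day") {
      if (n >= cfg$min_day_seconds) keep[i] <- TRUE else {
        log[[length(log) + 1]] <- data.frame(
          date = seg$date, kind = "day", rule = "under one hour",
          measured = n)
      }
    } else {
      dur <- tnum(seg$end) - tnum(seg$start)
      coverage <- n / dur
      if (coverage >= cfg$night_coverage_fraction) keep[i] <- TRUE else {
        log[[length(log) + 1]] <- data.frame(
          date = seg$date, kind = "night", rule = "not full night",
          measured = round(coverage, 6))
      }
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(date = character(), kind = character(), rule = character(),
               measured = numeric())
  list(retained = segments[keep], log = log)
}

#' Label SpO2 samples by activity level
#'
#' Each 1 Hz SpO2 sample inherits the MET value and sleep flag of the
#' actigraphy minute containing it (step alignment, no smoothing). Labels:
#' \code{asleep} when the minute is scored sleep; otherwise \code{rest}
#' (MET <= 1.5), \code{lipa} (1.5 < MET <= 3) or \code{mvpa} (MET > 3);
#' \code{unaligned} when no actigraphy minute covers the sample (excluded
#' from activity-specific features).
#'
#' @param seg an \code{oxi_segment} (typically a day segment), or any
#'   \code{spo2_series}.
#' @param act the patient's [actigraphy_series()].
#' @param cfg an [oxiweek_config()].
#' @return factor of length \code{nrow} with levels
#'   \code{rest, lipa, mvpa, asleep, unaligned}.
#' @export
partition_by_activity <- function(seg, act, cfg = oxiweek_config()) {
  spo2 <- if (inherits(seg, "oxi_segment")) seg$spo2 else seg
  stopifnot(inherits(spo2, "spo2_series"), inherits(act, "actigraphy_series"))
  lv <- c("rest", "lipa", "mvpa", "asleep", "unaligned")
  if (nrow(spo2) == 0) return(factor(character(), levels = lv))
  minute_start <- floor(tnum(spo2$time) / 60) * 60
  idx <- match(minute_start, tnum(act$time))
  lab <- rep("unaligned", nrow(spo2))
  hit <- !is.na(idx)
  met <- act$met[idx[hit]]
  sl <- act$sleep[idx[hit]]
  lab[hit] <- ifelse(sl == 1L, "asleep",
                     ifelse(met <= cfg$rest_met_max, "rest",
                            ifelse(met <= cfg$lipa_met_max, "lipa", "mvpa")))
  factor(lab, levels = lv)
}

#' Afternoon and evening clock windows of a day segment
#'
#' The afternoon window is 13:00--18:00 wall clock of the segment's date; the
#' evening window runs from 18:00 until going to bed (the segment end). A
#' morning window (segment start to 13:00) is computed for completeness but
#' no morning contrast is reported. Each window is eligible for the
#' afternoon--evening contrast only when it holds at least one hour of SpO2
#' samples.
#'
#' @param seg a day \code{oxi_segment}.
#' @param cfg an [oxiweek_config()].
#' @return list of three windows (\code{morning}, \code{afternoon},
#'   \code{evening}), each with \code{start}, \code{end}, \code{n_samples},
#'   \code{eligible}, plus \code{contrast_eligible} (both afternoon and
#'   evening eligible).
#' @export
clock_windows <- function(seg, cfg = oxiweek_config()) {
  stopifnot(inherits(seg, "oxi_segment"))
  if (seg$kind != "day") stop("clock windows are defined for day segments")
  day0 <- oxi_time(paste0(seg$date, " 00:00:00"))
  aft_start <- day0 + 13 * 3600
  aft_end <- day0 + 18 * 3600
  win <- function(start, end) {
    start <- max(start, seg$start); end <- min(end, seg$end)
    n <- if (tnum(end) > tnum(start)) {
      sum(tnum(seg$spo2$time) >= tnum(start) & tnum(seg$spo2$time) < tnum(end))
    } else 0L
    list(start = start, end = end, n_samples = n,
         eligible = n >= cfg$min_window_seconds)
  }
  out <- list(
    morning = win(seg$start, aft_start),
    afternoon = win(aft_start, aft_end),
    evening = win(aft_end, seg$end)
  )
  out$contrast_eligible <- out$afternoon$eligible && out$evening$eligible
  out
}
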