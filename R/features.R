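#' Per-period SpO2 features from a cleaned series
#'
#' Mean SpO2, SpO2 SD and CT90 over the non-missing 20-s bins of one period
#' (interpolated bins count as data). CT90 is the percentage of valid
#' measured time spent with SpO2 strictly below the threshold (default 90).
#' The SD is the sample standard deviation (n-1 denominator).
#'
#' @param cs a \code{clean_series} (see [downsample_median()]), optionally
#'   restricted to an activity class beforehand.
#' @param threshold SpO2 threshold (percent) for CT90. Default 90.
#' @return list of class \code{period_features}: \code{mean_spo2},
#'   \code{spo2_sd}, \code{ct90}, \code{n_valid_bins}, \code{range_spo2}.
#' @export
#' @examples
#' cs <- structure(data.frame(
#'   time = as.POSIXct("2017-01-05 23:00:00", tz = "UTC") + 20 * (0:3),
#'   value = c(92, 89, 91, 88), status = "valid",
#'   n_valid = 20L, n_error = 0L, n_cleaned = 0L),
#'   class = c("clean_series", "data.frame"))
#' period_features(cs)  # mean 90, CT90 50
period_features <- function(cs, threshold = 90) {
  stopifnot(inherits(cs, "clean_series"))
  v <- cs$value[cs$status != "missing"]
  if (!length(v)) stop("no non-missing bins: period features undefined")
  out <- list(
    mean_spo2 = mean(v),
    spo2_sd = if (length(v) > 1) stats::sd(v) else NA_real_,
    ct90 = 100 * sum(v < threshold) / length(v),
    n_valid_bins = length(v),
    range_spo2 = max(v) - min(v))
  class(out) <- "period_features"
  out
}

#' @export
print.period_features <- function(x, ...) {
  cat(sprintf(
    "<period_features> mean %.2f%%, SD %.2f, CT90 %.1f%%, range %.1f (%d bins)\n",
    x$mean_spo2, x$spo2_sd, x$ct90, x$range_spo2, x$n_valid_bins))
  invisible(x)
}

#' Sleep metrics of one night from actigraphy
#'
#' Total night sleeping time (TNST) is the sum of in-bed minutes scored as
#' sleep; wake after sleep onset (WASO) is the sum of in-bed awake minutes
#' strictly after the first sleep minute; sleep efficiency (Seff) is TNST
#' over time in bed, in percent. Sleep-onset latency + TNST + WASO equals
#' time in bed exactly.
#'
#' @param act an [actigraphy_series()].
#' @param bed one bed interval: list or one-row data.frame with
#'   \code{bed_start}, \code{bed_end} (half-open).
#' @return list of class \code{sleep_metrics}: \code{tnst}, \code{waso},
#'   \code{seff}, \code{onset_latency}, \code{time_in_bed} (minutes,
#'   Seff in percent).
#' @export
sleep_metrics <- function(act, bed) {
  stopifnot(inherits(act, "actigraphy_series"))
  t <- tnum(act$time)
  inb <- t >= tnum(bed$bed_start) & t < tnum(bed$bed_end)
  tib <- sum(inb)
  if (tib == 0) stop("no actigraphy minutes inside the bed interval")
  sl <- act$sleep[inb]
  tnst <- sum(sl == 1L)
  if (tnst == 0L) {
    out <- list(tnst = 0L, waso = 0L, seff = 0, onset_latency = tib,
                time_in_bed = tib)
  } else {
    onset <- which(sl == 1L)[1]
    waso <- sum(sl[seq_along(sl) > onset] == 0L)
    out <- list(tnst = tnst, waso = waso, seff = 100 * tnst / tib,
                onset_latency = onset - 1L, time_in_bed = tib)
  }
  class(out) <- "sleep_metrics"
  out
}

#' @export
print.sleep_metrics <- function(x, ...) {
  cat(sprintf(
    "<sleep_metrics> TNST %d min, WASO %d min, Seff %.1f%% (in bed %d min)\n",
    x$tnst, x$waso, x$seff, x$time_in_bed))
  invisible(x)
}

#' Weekly summary of per-period features
#'
#' For one patient and one period kind, the weekly average (unweighted mean
#' over retained periods) and weekly range (max minus min over those
#' periods) of each feature.
#'
#' @param periods data.frame with one row per retained period and one
#'   numeric column per feature (plus any id columns, ignored).
#' @param kind period kind label (\code{"night"}, \code{"day"},
#'   \code{"day_rest"}).
#' @param features character vector of feature column names; defaults to all
#'   numeric columns.
#' @return list of class \code{weekly_summary}: \code{kind},
#'   \code{n_periods}, \code{average} and \code{range} (named numeric
#'   vectors).
#' @export
weekly_summary <- function(periods, kind,
                           features = names(periods)[vapply(periods,
                                                            is.numeric,
                                                            logical(1))]) {
  if (!nrow(periods)) stop("no retained periods: weekly summary undefined")
  avg <- vapply(features, function(f) mean(periods[[f]], na.rm = TRUE),
                numeric(1))
  rng <- vapply(features, function(f) {
    v <- periods[[f]][!is.na(periods[[f]])]
    if (length(v)) max(v) - min(v) else NA_real_
  }, numeric(1))
  out <- list(kind = kind, n_periods = nrow(periods), average = avg,
              range = rng)
  class(out) <- "weekly_summary"
  out
}

#' @export
print.weekly_summary <- function(x, ...) {
  cat(sprintf("<weekly_summary> %s over %d periods\n", x$kind, x$n_periods))
  for (f in names(x$average)) {
    cat(sprintf("  %-12s avg %8.3f  range %8.3f\n", f, x$average[[f]],
                x$range[[f]]))
  }
  invisible(x)
}

#' Classify a patient as nocturnal desaturator over a week of nights
#'
#' A night is a desaturation night when its CT90 exceeds 30\% (strictly:
#' "more than 30\% of the time"). Over the week: all nights above the
#' threshold is a consistent desaturator, all at or below is a consistent
#' nondesaturator, anything mixed is an occasional desaturator.
#'
#' @param nightly_ct90 numeric vector of per-night CT90 values (percent),
#'   at least two nights.
#' @param threshold CT90 threshold in percent, default 30.
#' @return one of \code{"consistent_desaturator"},
#'   \code{"consistent_nondesaturator"}, \code{"occasional_desaturator"}.
#' @export
classify_desaturator <- function(nightly_ct90, threshold = 30) {
  nightly_ct90 <- nightly_ct90[!is.na(nightly_ct90)]
  if (length(nightly_ct90) < 2) {
    stop("desaturator category requires at least 2 nights")
  }
  desat <- nightly_ct90 > threshold
  if (all(desat)) "consistent_desaturator"
  else if (!any(desat)) "consistent_nondesaturator"
  else "occasional_desaturator"
}

#' Does a two-night assessment disagree with the week?
#'
#' Clinical practice categorizes after one or two nights: a patient is a
#' desaturator when desaturation occurs in at least one of the first two
#' nights. The flag is \code{TRUE} when that two-night category differs from
#' the week-level category (with the two-night \code{desaturator} matching
#' \code{consistent_desaturator} and likewise for nondesaturators). The
#' night order matters; the week-level category does not depend on it.
#'
#' @param nightly_ct90 per-night CT90 values in night order (percent), at
#'   least two nights.
#' @param threshold CT90 threshold in percent, default 30.
#' @return list: \code{flag}, \code{two_night_category},
#'   \code{week_category}, \code{first_two_concordant} (were nights 1 and 2
#'   on the same side of the threshold).
#' @export
two_night_vs_week_category <- function(nightly_ct90, threshold = 30) {
  nightly_ct90 <- nightly_ct90[!is.na(nightly_ct90)]
  if (length(nightly_ct90) < 2) {
    stop("two-night comparison requires at least 2 nights")
  }
  two <- nightly_ct90[1:2] > threshold
  two_cat <- if (any(two)) "desaturator" else "nondesaturator"
  week <- classify_desaturator(nightly_ct90, threshold)
  match_cat <- c(desaturator = "consistent_desaturator",
                 nondesaturator = "consistent_nondesaturator")[[two_cat]]
  list(flag = week != match_cat,
       two_night_category = two_cat,
       week_category = week,
       first_two_concordant = two[1] == two[2])
}

#' Afternoon--evening contrast of daytime SpO2 in rest
#'
#' Difference between the mean SpO2 in rest in the afternoon (13:00--18:00)
#' and in the evening (18:00 until going to bed) for one day, in percentage
#' points. Defined only for days with at least one hour of measurements in
#' both windows.
#'
#' @param cs the day's \code{clean_series}.
#' @param bin_labels activity label per bin (factor from
#'   [bin_activity_labels()]).
#' @param windows clock windows from [clock_windows()].
#' @return list: \code{diff} (afternoon minus evening, pp),
#'   \code{afternoon_mean}, \code{evening_mean}, \code{eligible}.
#' @export
afternoon_evening_diff <- function(cs, bin_labels, windows) {
  stopifnot(inherits(cs, "clean_series"), length(bin_labels) == nrow(cs))
  if (!isTRUE(windows$contrast_eligible)) {
    return(list(diff = NA_real_, afternoon_mean = NA_real_,
                evening_mean = NA_real_, eligible = FALSE))
  }
  rest_ok <- cs$status != "missing" & bin_labels == "rest"
  t <- tnum(cs$time)
  in_win <- function(w) t >= tnum(w$start) & t < tnum(w$end)
  am <- cs$value[rest_ok & in_win(windows$afternoon)]
  em <- cs$value[rest_ok & in_win(windows$evening)]
  if (!length(am) || !length(em)) {
    return(list(diff = NA_real_, afternoon_mean = NA_real_,
                evening_mean = NA_real_, eligible = FALSE))
  }
  list(diff = mean(am) - mean(em), afternoon_mean = mean(am),
       evening_mean = mean(em), eligible = TRUE)
}

#' Within-day SpO2 range in rest
#'
#' Max minus min over the valid rest-labelled bins of one day: how much a
#' telemonitoring spot check could differ depending on when it is taken.
#'
#' @param cs the day's \code{clean_series}.
#' @param bin_labels activity label per bin.
#' @return range in percentage points, or \code{NA} when no rest bins.
#' @export
day_rest_range <- function(cs, bin_labels) {
  stopifnot(inherits(cs, "clean_series"), length(bin_labels) == nrow(cs))
  v <- cs$value[cs$status != "missing" & bin_labels == "rest"]
  if (!length(v)) return(NA_real_)
  max(v) - min(v)
}

#' Activity label of each 20-s bin
#'
#' Each bin takes the modal per-second activity label of the raw samples it
#' covers (ties broken in the order rest, lipa, mvpa, asleep, unaligned);
#' bins covering no raw sample are \code{unaligned}.
#'
#' @param spo2 the segment's raw samples (any status).
#' @param mask per-sample activity labels from [partition_by_activity()].
#' @param cs the segment's \code{clean_series} (defines the bin grid).
#' @param start segment start (bin alignment origin).
#' @param cfg an [oxiweek_config()].
#' @return factor of length \code{nrow(cs)} with the activity levels.
#' @export
bin_activity_labels <- function(spo2, mask, cs, start,
                                cfg = oxiweek_config()) {
  stopifnot(length(mask) == nrow(spo2), inherits(cs, "clean_series"))
  lv <- levels(mask)
  nbins <- nrow(cs)
  out <- rep("unaligned", nbins)
  if (nbins && nrow(spo2)) {
    off <- floor((tnum(spo2$time) - tnum(start)) / cfg$bin_seconds)
    inb <- off >= 0 & off < nbins
    if (any(inb)) {
      tab <- table(factor(off[inb], levels = 0:(nbins - 1)),
                   factor(mask[inb], levels = lv))
      has <- rowSums(tab) > 0
      out[has] <- lv[apply(tab[has, , drop = FALSE], 1, which.max)]
    }
  }
  factor(out, levels = lv)
}
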