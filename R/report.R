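#' Cohort-level report from a feature table
#'
#' A pure function of the per-period [feature_table()]: recomputes weekly
#' summaries per patient, cohort means and SDs of weekly averages and
#' ranges per scope (night, day, day in rest), the paired t test between
#' weekly averages of nocturnal and daytime-in-rest SpO2, the SD-vs-mean
#' Pearson correlations per scope, the afternoon--evening contrast,
#' desaturator category counts with the two-night discordance flags, sleep
#' quality averages, and the data-quality table by activity class. Running
#' it again on the written table reproduces it exactly; nothing is
#' hard-coded.
#'
#' @param features a [feature_table()].
#' @param cfg the [oxiweek_config()] in effect (echoed into the report).
#' @return list of class \code{oxiweek_report}.
#' @export
cohort_report <- function(features, cfg = oxiweek_config()) {
  stopifnot(inherits(features, "feature_table"))
  ft <- as.data.frame(features)
  val <- function(sub, feature) sub$value[sub$feature == feature]
  patients <- sort(unique(ft$patient))

  # ---- per-patient weekly summaries per scope ----------------------------
  scope_feats <- c("mean_spo2", "spo2_sd", "ct90")
  weekly <- list()
  for (kind in c("night", "day", "day_rest")) {
    per_pat <- list()
    for (p in patients) {
      sub <- ft[ft$patient == p & ft$kind == kind, , drop = FALSE]
      if (!nrow(sub)) next
      dates <- sort(unique(sub$date))
      wide <- data.frame(date = dates)
      for (f in c(scope_feats, if (kind == "night")
        c("tnst", "waso", "seff") else "range_spo2")) {
        wide[[f]] <- vapply(dates, function(d) {
          v <- sub$value[sub$date == d & sub$feature == f]
          if (length(v)) v[1] else NA_real_
        }, numeric(1))
      }
      if (all(is.na(wide$mean_spo2))) next
      ws <- weekly_summary(wide[!is.na(wide$mean_spo2), , drop = FALSE],
                           kind, features = setdiff(names(wide), "date"))
      per_pat[[p]] <- data.frame(
        patient = p, n_periods = ws$n_periods,
        t(ws$average), t(stats::setNames(ws$range,
                                         paste0("range_", names(ws$range)))))
    }
    weekly[[kind]] <- if (length(per_pat)) do.call(rbind, per_pat) else NULL
  }

  msd <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
    list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
         n = length(v))
  }
  scope_summary <- list()
  for (kind in names(weekly)) {
    w <- weekly[[kind]]
    if (is.null(w)) next
    scope_summary[[kind]] <- list(
      n_patients = nrow(w),
      periods_per_patient = msd(w$n_periods),
      weekly_average = lapply(stats::setNames(scope_feats, scope_feats),
                              function(f) msd(w[[f]])),
      weekly_range = lapply(stats::setNames(scope_feats, scope_feats),
                            function(f) msd(w[[paste0("range_", f)]])))
  }

  # ---- paired test: nocturnal vs daytime-in-rest weekly mean SpO2 --------
  paired <- list(applicable = FALSE, reason = "fewer than 2 complete pairs")
  if (!is.null(weekly$night) && !is.null(weekly$day_rest)) {
    m <- merge(weekly$night[, c("patient", "mean_spo2")],
               weekly$day_rest[, c("patient", "mean_spo2")],
               by = "patient", suffixes = c("_night", "_day_rest"))
    if (nrow(m) >= 2) {
      paired <- tryCatch({
        r <- paired_t_test(m$mean_spo2_night, m$mean_spo2_day_rest)
        c(list(applicable = TRUE), unclass(r))
      }, error = function(e) list(applicable = FALSE,
                                  reason = conditionMessage(e)))
    }
  }

  # ---- SD-vs-mean correlations per scope ---------------------------------
  correlations <- list()
  for (kind in names(weekly)) {
    w <- weekly[[kind]]
    correlations[[kind]] <- if (!is.null(w) && nrow(w) >= 3) {
      tryCatch(unclass(pearson_correlation(w$spo2_sd, w$mean_spo2)),
               error = function(e) list(applicable = FALSE,
                                        reason = conditionMessage(e)))
    } else list(applicable = FALSE, reason = "fewer than 3 patients")
  }

  # ---- afternoon vs evening ----------------------------------------------
  aft <- ft[ft$kind == "afternoon" & ft$feature == "mean_spo2_rest", ]
  eve <- ft[ft$kind == "evening" & ft$feature == "mean_spo2_rest", ]
  m <- merge(aft[, c("patient", "date", "value")],
             eve[, c("patient", "date", "value")],
             by = c("patient", "date"), suffixes = c("_aft", "_eve"))
  ae <- list(n_days = nrow(m), n_patients = length(unique(m$patient)))
  if (nrow(m)) {
    d <- m$value_aft - m$value_eve
    ae$mean_diff <- mean(d)
    ae$sd_diff <- if (length(d) > 1) stats::sd(d) else NA_real_
    ae$test <- if (nrow(m) >= 2) {
      tryCatch(unclass(paired_t_test(m$value_aft, m$value_eve)),
               error = function(e) list(applicable = FALSE,
                                        reason = conditionMessage(e)))
    } else list(applicable = FALSE, reason = "fewer than 2 days")
  }

  # ---- desaturator categories --------------------------------------------
  cats <- list(); flags <- list()
  for (p in patients) {
    sub <- ft[ft$patient == p & ft$kind == "night" & ft$feature == "ct90", ]
    if (!nrow(sub)) next
    ct <- sub$value[order(sub$date)]
    if (sum(!is.na(ct)) >= 2) {
      cats[[p]] <- classify_desaturator(ct, cfg$ct90_threshold)
      flags[[p]] <- two_night_vs_week_category(ct, cfg$ct90_threshold)
    } else {
      cats[[p]] <- NA_character_
    }
  }
  cat_v <- unlist(cats)
  classifiable <- cat_v[!is.na(cat_v)]
  lv <- c("consistent_desaturator", "consistent_nondesaturator",
          "occasional_desaturator")
  counts <- as.list(table(factor(classifiable, levels = lv)))
  occ <- names(cat_v)[!is.na(cat_v) & cat_v == "occasional_desaturator"]
  desat <- list(
    n_classifiable = length(classifiable),
    counts = counts,
    fractions_pct = lapply(counts, function(k)
      if (length(classifiable)) 100 * k / length(classifiable) else NA_real_),
    categories = cats,
    two_night_flags = lapply(flags, function(f) f$flag),
    n_two_night_discordant = sum(vapply(flags, function(f) f$flag,
                                        logical(1))),
    occasional_two_night_concordant_pct = if (length(occ)) {
      100 * mean(vapply(flags[occ], function(f) f$first_two_concordant,
                        logical(1)))
    } else NA_real_)

  # ---- sleep quality ------------------------------------------------------
  sleep <- NULL
  if (!is.null(weekly$night) && "tnst" %in% names(weekly$night)) {
    sleep <- lapply(stats::setNames(c("tnst", "waso", "seff"),
                                    c("tnst", "waso", "seff")),
                    function(f) msd(weekly$night[[f]]))
  }

  # ---- data quality by scope / activity class ----------------------------
  qcount <- function(kinds) {
    sub <- ft[ft$kind %in% kinds & ft$feature %in%
                c("n_error_samples", "n_cleaned_samples", "n_valid_samples"), ]
    e <- sum(sub$value[sub$feature == "n_error_samples"])
    c2 <- sum(sub$value[sub$feature == "n_cleaned_samples"])
    v <- sum(sub$value[sub$feature == "n_valid_samples"])
    n <- e + c2 + v
    if (n == 0) return(list(n_samples = 0))
    list(n_samples = n, valid_pct = 100 * v / n, error_pct = 100 * e / n,
         cleaned_pct = 100 * c2 / n)
  }
  quality <- list(
    overall = qcount(c("night", "day")),
    night = qcount("night"),
    day = qcount("day"),
    day_rest_lipa = qcount(c("day_rest", "day_lipa")),
    day_mvpa = qcount("day_mvpa"))

  out <- list(
    n_patients = length(patients),
    scope_summary = scope_summary,
    sleep = sleep,
    night_vs_day_rest = paired,
    sd_vs_mean_correlation = correlations,
    afternoon_evening = ae,
    desaturation = desat,
    quality = quality,
    weekly = lapply(weekly, function(w) w),
    config = unclass(cfg),
    note = paste("Two-sided p values; significance read at 0.05;",
                 "no multiple-testing correction applied."))
  class(out) <- "oxiweek_report"
  out
}

#' @export
print.oxiweek_report <- function(x, ...) {
  cat("==== oxiweek cohort report ====\n")
  cat(sprintf("Patients: %d\n", x$n_patients))
  fmt_msd <- function(m) {
    if (is.null(m) || !m$n) return("n/a")
    sprintf("%.2f (SD %.2f, n=%d)", m$mean,
            if (is.na(m$sd)) NA else m$sd, m$n)
  }
  for (kind in names(x$scope_summary)) {
    s <- x$scope_summary[[kind]]
    cat(sprintf("\n[%s] %d patients, %.1f periods/patient\n", kind,
                s$n_patients, s$periods_per_patient$mean))
    for (f in names(s$weekly_average)) {
      cat(sprintf("  %-10s weekly avg %s | weekly range %s\n", f,
                  fmt_msd(s$weekly_average[[f]]),
                  fmt_msd(s$weekly_range[[f]])))
    }
  }
  if (!is.null(x$sleep)) {
    cat(sprintf("\nSleep: TNST %s min, WASO %s min, Seff %s%%\n",
                fmt_msd(x$sleep$tnst), fmt_msd(x$sleep$waso),
                fmt_msd(x$sleep$seff)))
  }
  p <- x$night_vs_day_rest
  if (isTRUE(p$applicable)) {
    cat(sprintf(
      "\nNight vs day-in-rest mean SpO2: diff %.2f pp, t=%.3f (df %d), p=%.3g\n",
      p$mean_difference, p$t, p$df, p$p_value))
  } else {
    cat("\nNight vs day-in-rest paired test: not applicable (",
        p$reason, ")\n", sep = "")
  }
  for (kind in names(x$sd_vs_mean_correlation)) {
    r <- x$sd_vs_mean_correlation[[kind]]
    if (!is.null(r$r)) {
      cat(sprintf("SD-vs-mean correlation [%s]: r=%.3f (R2=%.3f), p=%.3g\n",
                  kind, r$r, r$r_squared, r$p_value))
    }
  }
  ae <- x$afternoon_evening
  if (!is.null(ae$mean_diff)) {
    cat(sprintf(
      "Afternoon - evening SpO2 in rest: %.2f pp (SD %.2f) over %d days, %d patients\n",
      ae$mean_diff, ae$sd_diff, ae$n_days, ae$n_patients))
  }
  d <- x$desaturation
  cat(sprintf(
    "\nDesaturator categories (n=%d): %d consistent desaturators, %d consistent nondesaturators, %d occasional\n",
    d$n_classifiable, d$counts$consistent_desaturator,
    d$counts$consistent_nondesaturator, d$counts$occasional_desaturator))
  cat(sprintf("Two-night vs week discordant: %d patients\n",
              d$n_two_night_discordant))
  cat("\nData quality (% of raw samples):\n")
  for (sc in names(x$quality)) {
    q <- x$quality[[sc]]
    if (q$n_samples > 0) {
      cat(sprintf("  %-14s valid %6.2f%%  error %5.2f%%  cleaned %5.2f%%  (n=%d)\n",
                  sc, q$valid_pct, q$error_pct, q$cleaned_pct, q$n_samples))
    }
  }
  cat("\n", x$note, "\n", sep = "")
  invisible(x)
}
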