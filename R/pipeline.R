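#' Analyse one patient-week
#'
#' Full per-patient pipeline: detect bed intervals from actigraphy, split
#' the SpO2 stream into night and day segments, apply the retention rules,
#' clean each retained segment, partition daytime samples by activity level,
#' and extract per-period features (mean SpO2, SpO2 SD, CT90, data-quality
#' counts, sleep metrics, afternoon/evening means).
#'
#' @param spo2 an [spo2_series()].
#' @param act an [actigraphy_series()].
#' @param patient_id identifier used in the feature table.
#' @param cfg an [oxiweek_config()].
#' @return list of class \code{patient_result}: \code{features} (a
#'   [feature_table()]), \code{exclusions}, \code{audit}, \code{beds},
#'   \code{patient_id}.
#' @export
analyze_patient <- function(spo2, act, patient_id = "P01",
                            cfg = oxiweek_config()) {
  stopifnot(inherits(spo2, "spo2_series"), inherits(act, "actigraphy_series"))
  if (nrow(act) == 0) stop("empty actigraphy series for ", patient_id)
  if (nrow(spo2) == 0) stop("empty SpO2 series for ", patient_id)
  beds <- detect_bed_intervals(act, cfg)
  segs <- split_day_night(spo2, beds)
  ret <- apply_retention_rules(segs, cfg)
  rows <- list()
  audits <- list()
  emit <- function(date, kind, feature, value, units) {
    rows[[length(rows) + 1]] <<- data.frame(
      patient = patient_id, date = date, kind = kind, feature = feature,
      value = as.numeric(value), units = units)
  }
  emit_quality <- function(date, kind, sub) {
    emit(date, kind, "n_error_samples", sum(sub$status == "error"), "count")
    emit(date, kind, "n_cleaned_samples", sum(sub$status == "cleaned_out"),
         "count")
    emit(date, kind, "n_valid_samples", sum(sub$status == "raw_valid"),
         "count")
  }
  emit_period <- function(date, kind, cs, threshold) {
    pf <- tryCatch(period_features(cs, threshold), error = function(e) NULL)
    if (is.null(pf)) return(invisible(NULL))
    emit(date, kind, "mean_spo2", pf$mean_spo2, "percent")
    if (!is.na(pf$spo2_sd)) emit(date, kind, "spo2_sd", pf$spo2_sd, "pp")
    emit(date, kind, "ct90", pf$ct90, "percent")
    emit(date, kind, "n_valid_bins", pf$n_valid_bins, "count")
    if (kind == "day_rest") emit(date, kind, "range_spo2", pf$range_spo2, "pp")
  }
  for (seg in ret$retained) {
    cr <- clean_segment(seg, cfg)
    if (nrow(cr$audit)) {
      a <- cr$audit
      a$patient <- patient_id; a$date <- cr$date; a$kind <- cr$kind
      audits[[length(audits) + 1]] <- a
    }
    mask <- partition_by_activity(seg, act, cfg)
    emit_quality(cr$date, cr$kind, cr$spo2)
    if (cr$kind == "night") {
      emit_period(cr$date, "night", cr$bins, cfg$spo2_threshold)
      hit <- which(tnum(beds$bed_start) == tnum(seg$start))
      if (length(hit) == 1) {
        sm <- sleep_metrics(act, beds[hit, , drop = FALSE])
        emit(cr$date, "night", "tnst", sm$tnst, "min")
        emit(cr$date, "night", "waso", sm$waso, "min")
        emit(cr$date, "night", "seff", sm$seff, "percent")
        emit(cr$date, "night", "time_in_bed", sm$time_in_bed, "min")
      }
    } else {
      emit_period(cr$date, "day", cr$bins, cfg$spo2_threshold)
      labs <- bin_activity_labels(cr$spo2, mask, cr$bins, cr$start, cfg)
      for (cls in c("rest", "lipa", "mvpa")) {
        kind_cls <- paste0("day_", cls)
        sel <- labs == cls
        if (any(sel)) {
          sub <- cr$bins[sel, , drop = FALSE]
          class(sub) <- class(cr$bins)
          emit_period(cr$date, kind_cls, sub, cfg$spo2_threshold)
        }
        msel <- mask == cls
        if (any(msel)) {
          emit_quality(cr$date, kind_cls, cr$spo2[msel, , drop = FALSE])
        }
      }
      win <- clock_windows(seg, cfg)
      ae <- afternoon_evening_diff(cr$bins, labs, win)
      if (ae$eligible) {
        emit(cr$date, "afternoon", "mean_spo2_rest", ae$afternoon_mean,
             "percent")
        emit(cr$date, "evening", "mean_spo2_rest", ae$evening_mean, "percent")
        emit(cr$date, "day", "ae_diff", ae$diff, "pp")
      }
    }
  }
  features <- if (length(rows)) {
    df <- do.call(rbind, rows)
    do.call(feature_table, df)
  } else feature_table()
  audit <- if (length(audits)) do.call(rbind, audits) else
    data.frame(step = character(), start = oxi_time(character()),
               n_samples = integer(), block_mean = numeric(),
               deviation = numeric(), patient = character(),
               date = character(), kind = character())
  excl <- ret$log
  if (nrow(excl)) excl$patient <- patient_id else excl$patient <- character(0)
  out <- list(features = features, exclusions = excl, audit = audit,
              beds = beds, patient_id = patient_id)
  class(out) <- "patient_result"
  out
}

#' @export
print.patient_result <- function(x, ...) {
  cat(sprintf("<patient_result> %s: %d feature rows, %d exclusions\n",
              x$patient_id, nrow(x$features), nrow(x$exclusions)))
  invisible(x)
}

#' Run the full pipeline over a cohort of raw files
#'
#' Reads paired SpO2/actigraphy CSV files, analyses every patient, and
#' writes the feature table, exclusion and audit logs, and the cohort
#' report (JSON and text) to \code{out_dir}. Deterministic given inputs and
#' configuration; the report logs every threshold in effect.
#'
#' @param spo2_paths,act_paths equal-length character vectors of file
#'   paths, pairwise per patient.
#' @param patient_ids patient identifiers; default derived from the SpO2
#'   file names (strips a \code{_spo2.csv} suffix).
#' @param cfg an [oxiweek_config()].
#' @param out_dir output directory, created if needed. \code{NULL} skips
#'   writing.
#' @return list of class \code{pipeline_result}: \code{features},
#'   \code{report}, \code{exclusions}, \code{audit}, \code{config}.
#' @export
run_pipeline <- function(spo2_paths, act_paths, patient_ids = NULL,
                         cfg = oxiweek_config(), out_dir = NULL) {
  if (length(spo2_paths) != length(act_paths)) {
    stop("spo2_paths and act_paths must pair up")
  }
  if (!length(spo2_paths)) stop("no input files")
  if (is.null(patient_ids)) {
    patient_ids <- sub("_spo2\\.csv$", "", basename(spo2_paths))
  }
  results <- vector("list", length(spo2_paths))
  for (i in seq_along(spo2_paths)) {
    spo2 <- read_spo2_csv(spo2_paths[i])
    act <- read_actigraphy_csv(act_paths[i])
    results[[i]] <- analyze_patient(spo2, act, patient_ids[i], cfg)
  }
  features <- do.call(rbind, lapply(results, `[[`, "features"))
  class(features) <- c("feature_table", "data.frame")
  exclusions <- do.call(rbind, lapply(results, `[[`, "exclusions"))
  audit <- do.call(rbind, lapply(results, `[[`, "audit"))
  report <- cohort_report(features, cfg)
  out <- list(features = features, report = report,
              exclusions = exclusions, audit = audit, config = cfg)
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_feature_table(features, file.path(out_dir, "features.csv"))
    excl_w <- exclusions
    utils::write.csv(excl_w, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE, quote = FALSE)
    audit_w <- audit
    if (nrow(audit_w)) audit_w$start <- format_iso_time(audit_w$start)
    utils::write.csv(audit_w, file.path(out_dir, "audit.csv"),
                     row.names = FALSE, quote = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
    txt <- utils::capture.output(print(report))
    writeLines(txt, file.path(out_dir, "report.txt"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d feature rows from %d patients\n",
              nrow(x$features), length(unique(x$features$patient))))
  print(x$report)
  invisible(x)
}
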