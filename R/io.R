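#' Construct an SpO2 series
#'
#' A 1 Hz SpO2 stream: one row per recorded second. The oximeter emits the
#' sentinel value 500 when its own algorithms judge a measurement invalid;
#' such rows get status \code{"error"} immediately, everything else starts as
#' \code{"raw_valid"}. Downstream cleaning may mark samples
#' \code{"cleaned_out"}. Time gaps between rows are allowed (device off).
#'
#' @param time POSIXct timestamps, strictly increasing.
#' @param value integer SpO2 percent in \code{[0, 100]}, or 500 (error).
#' @return data.frame of class \code{spo2_series} with columns
#'   \code{time}, \code{value}, \code{status}.
#' @export
spo2_series <- function(time, value) {
  time <- oxi_time(time)
  value <- as.numeric(value)
  if (length(time) != length(value)) stop("time and value lengths differ")
  if (anyNA(time)) stop("unparseable timestamp in SpO2 series")
  if (anyNA(value)) stop("missing SpO2 value")
  if (length(time) > 1 && any(diff(tnum(time)) <= 0)) {
    i <- which(diff(tnum(time)) <= 0)[1]
    stop("SpO2 timestamps not strictly increasing at row ", i + 1L)
  }
  bad <- value != 500 & (value < 0 | value > 100)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("SpO2 value out of range at row ", i, ": ", value[i],
         " (must be in [0,100] or the 500 error sentinel)")
  }
  out <- data.frame(
    time = time,
    value = value,
    status = ifelse(value == 500, "error", "raw_valid"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("spo2_series", "data.frame")
  out
}

#' Construct an actigraphy series
#'
#' One row per minute: energy expenditure in MET plus binary lying-down and
#' sleep indications. A minute scored as sleep must also be scored as lying.
#'
#' @param time POSIXct timestamps at minute resolution, strictly increasing.
#' @param met nonnegative energy expenditure, MET.
#' @param lying,sleep 0/1 indicators.
#' @return data.frame of class \code{actigraphy_series}.
#' @export
actigraphy_series <- function(time, met, lying, sleep) {
  time <- oxi_time(time)
  n <- length(time)
  if (!all(lengths(list(met, lying, sleep)) == n)) {
    stop("actigraphy columns have differing lengths")
  }
  if (anyNA(time)) stop("unparseable timestamp in actigraphy series")
  met <- as.numeric(met); lying <- as.integer(lying); sleep <- as.integer(sleep)
  if (anyNA(met) || any(met < 0)) {
    stop("MET values must be nonnegative at row ",
         which(is.na(met) | met < 0)[1])
  }
  if (!all(lying %in% c(0L, 1L)) || !all(sleep %in% c(0L, 1L))) {
    stop("lying and sleep must be 0/1")
  }
  if (n > 1 && any(diff(tnum(time)) <= 0)) {
    stop("actigraphy timestamps not strictly increasing at row ",
         which(diff(tnum(time)) <= 0)[1] + 1L)
  }
  viol <- sleep == 1L & lying == 0L
  if (any(viol)) {
    stop("sleep=1 requires lying=1; violated at row ", which(viol)[1])
  }
  out <- data.frame(time = time, met = met, lying = lying, sleep = sleep)
  class(out) <- c("actigraphy_series", "data.frame")
  out
}

#' @export
print.spo2_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<spo2_series> %d samples", n))
  if (n) {
    cat(sprintf(", %s .. %s", format_iso_time(x$time[1]),
                format_iso_time(x$time[n])))
    tab <- table(x$status)
    cat("\n  status: ", paste(names(tab), as.integer(tab), sep = "=",
                              collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.actigraphy_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<actigraphy_series> %d minutes", n))
  if (n) {
    cat(sprintf(", %s .. %s, sleep minutes: %d",
                format_iso_time(x$time[1]), format_iso_time(x$time[n]),
                sum(x$sleep)))
  }
  cat("\n")
  invisible(x)
}

# --- CSV dialects ----------------------------------------------------------

#' Read a 1 Hz SpO2 stream from CSV
#'
#' Dialect: header \code{timestamp,spo2}; ISO 8601 local timestamps at 1-s
#' resolution; integer SpO2 percent or the sentinel 500 for device-flagged
#' errors. Values that are neither in \code{[0,100]} nor 500 are rejected
#' with the offending row number.
#'
#' @param path CSV file path.
#' @return an [spo2_series()].
#' @export
read_spo2_csv <- function(path) {
  if (!file.exists(path)) stop("SpO2 file not found: ", path)
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!identical(names(df), c("timestamp", "spo2"))) {
    stop("SpO2 CSV header must be 'timestamp,spo2', got: ",
         paste(names(df), collapse = ","))
  }
  t <- parse_iso_time(df$timestamp)
  if (anyNA(t)) {
    stop("malformed timestamp in ", path, " at data row ", which(is.na(t))[1])
  }
  tryCatch(spo2_series(t, df$spo2),
           error = function(e) stop("in ", path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Read a 1/min actigraphy stream from CSV
#'
#' Dialect: header \code{timestamp,met,lying,sleep}. A minute with
#' \code{sleep=1} but \code{lying=0} violates the series invariant and is
#' rejected. An empty file yields an empty series; downstream stages refuse
#' empty input explicitly.
#'
#' @param path CSV file path.
#' @return an [actigraphy_series()].
#' @export
read_actigraphy_csv <- function(path) {
  if (!file.exists(path)) stop("actigraphy file not found: ", path)
  df <- utils::read.csv(path,
                        colClasses = c("character", "numeric", "integer",
                                       "integer"))
  if (!identical(names(df), c("timestamp", "met", "lying", "sleep"))) {
    stop("actigraphy CSV header must be 'timestamp,met,lying,sleep', got: ",
         paste(names(df), collapse = ","))
  }
  if (nrow(df) == 0) {
    return(actigraphy_series(oxi_time(character()), numeric(), integer(),
                             integer()))
  }
  t <- parse_iso_time(df$timestamp)
  if (anyNA(t)) {
    stop("malformed timestamp in ", path, " at data row ", which(is.na(t))[1])
  }
  tryCatch(actigraphy_series(t, df$met, df$lying, df$sleep),
           error = function(e) stop("in ", path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Write SpO2 / actigraphy streams in the package CSV dialects
#'
#' Deterministic output: fixed column order, ISO timestamps, no quoting, no
#' row names, so identical series produce byte-identical files.
#'
#' @param x series to write.
#' @param path destination CSV.
#' @return \code{path}, invisibly.
#' @export
write_spo2_csv <- function(x, path) {
  stopifnot(inherits(x, "spo2_series"))
  df <- data.frame(timestamp = format_iso_time(x$time),
                   spo2 = format_value_num(x$value))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spo2_csv
#' @export
write_actigraphy_csv <- function(x, path) {
  stopifnot(inherits(x, "actigraphy_series"))
  df <- data.frame(timestamp = format_iso_time(x$time),
                   met = format_value_num(x$met),
                   lying = x$lying, sleep = x$sleep)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# shortest decimal form that round-trips the double exactly (15 significant
# digits when that parses back bit-identically, 17 otherwise)
format_value_num <- function(x) {
  x <- as.numeric(x)
  out <- sprintf("%.15g", x)
  bad <- !is.na(x) & as.numeric(out) != x
  out[bad] <- sprintf("%.17g", x[bad])
  out
}

# --- feature table ---------------------------------------------------------

#' Feature table construction and round-trip IO
#'
#' The pipeline's tidy output: one row per (patient, period, feature). The
#' period id combines the period date and kind (\code{night}, \code{day},
#' \code{day_rest}, \code{day_lipa}, \code{day_mvpa}, \code{afternoon},
#' \code{evening}). Units are fixed per feature. The cohort report is a pure
#' function of this table.
#'
#' @param patient,date,kind,feature,value,units equal-length vectors.
#' @return data.frame of class \code{feature_table} with columns
#'   \code{patient}, \code{date}, \code{kind}, \code{feature}, \code{value},
#'   \code{units}.
#' @export
feature_table <- function(patient = character(), date = character(),
                          kind = character(), feature = character(),
                          value = numeric(), units = character()) {
  out <- data.frame(
    patient = as.character(patient), date = as.character(date),
    kind = as.character(kind), feature = as.character(feature),
    value = as.numeric(value), units = as.character(units),
    stringsAsFactors = FALSE
  )
  key <- paste(out$patient, out$date, out$kind, out$feature)
  if (anyDuplicated(key)) {
    stop("duplicate (patient, period, feature) row: ",
         key[which(duplicated(key))[1]])
  }
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @param x a \code{feature_table}.
#' @param path CSV destination / source.
#' @rdname feature_table
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  ord <- order(x$patient, x$date, x$kind, x$feature, method = "radix")
  df <- as.data.frame(x)[ord, , drop = FALSE]
  df$value <- format_value_num(df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.csv(path, colClasses = c(rep("character", 4), "numeric",
                                             "character"))
  if (!identical(names(df),
                 c("patient", "date", "kind", "feature", "value", "units"))) {
    stop("feature table header mismatch in ", path)
  }
  do.call(feature_table, df)
}

#' Write a cohort report (or any summary list) as JSON
#'
#' @param summary a list (typically an \code{oxiweek_report}).
#' @param path JSON destination.
#' @export
write_report <- function(summary, path) {
  cls <- class(summary)
  class(summary) <- "list"
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  class(summary) <- cls
  invisible(path)
}
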