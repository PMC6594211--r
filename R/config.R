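#' Pipeline configuration
#'
#' Collects every tunable threshold of the preprocessing and analysis pipeline
#' in one validated list. All defaults are the published values of the method:
#' blocks of fewer than 20 samples between error values are dropped, blocks of
#' 20--100 samples are dropped when their mean deviates by more than 6
#' percentage points from the segment mean, the signal is down-sampled to one
#' value per 20 s by the block median, and gaps of up to 3 consecutive missing
#' bins are linearly interpolated.
#'
#' @param small_block_max maximum length (raw samples) of a block between
#'   error values that is excluded unconditionally. Default 19 ("less than 20
#'   samples").
#' @param dev_block_min,dev_block_max length range (raw samples, inclusive) of
#'   blocks between error values that are excluded when deviating. Defaults
#'   20 and 100.
#' @param dev_threshold deviation threshold, SpO2 percentage points. Default 6.
#' @param dev_relative logical; if \code{TRUE} the 6\% threshold is read as
#'   relative to the segment mean instead of absolute percentage points.
#'   Default \code{FALSE} (absolute).
#' @param bin_seconds down-sampling bin width in seconds. Default 20.
#' @param max_interp_gap_bins longest run of missing bins that is filled by
#'   linear interpolation. Default 3.
#' @param acf_threshold autocorrelation level defining the decorrelation lag.
#'   Default \code{exp(-1)}.
#' @param min_bed_minutes shortest lying run (minutes) accepted as a bed
#'   interval. Default 180.
#' @param night_coverage_fraction fraction of the bed interval that must be
#'   covered by SpO2 samples for a night to count as full. Default 0.9.
#' @param min_day_seconds minimum daytime SpO2 coverage (seconds) for a day to
#'   be retained. Default 3600 (one hour).
#' @param min_window_seconds minimum coverage (seconds) of both the afternoon
#'   and the evening window for the afternoon--evening contrast. Default 3600.
#' @param spo2_threshold SpO2 level (percent) below which time counts towards
#'   CT90. Default 90.
#' @param ct90_threshold CT90 level (percent of measured time) above which a
#'   night is a desaturation night. Default 30.
#' @param rest_met_max,lipa_met_max MET cut-points: rest is MET <=
#'   \code{rest_met_max} while awake, LIPA is up to \code{lipa_met_max}, MVPA
#'   above. Defaults 1.5 and 3.
#'
#' @return a list of class \code{oxiweek_config}.
#' @export
#' @examples
#' cfg <- oxiweek_config()
#' cfg$bin_seconds
oxiweek_config <- function(small_block_max = 19L,
                           dev_block_min = 20L,
                           dev_block_max = 100L,
                           dev_threshold = 6,
                           dev_relative = FALSE,
                           bin_seconds = 20L,
                           max_interp_gap_bins = 3L,
                           acf_threshold = exp(-1),
                           min_bed_minutes = 180L,
                           night_coverage_fraction = 0.9,
                           min_day_seconds = 3600L,
                           min_window_seconds = 3600L,
                           spo2_threshold = 90,
                           ct90_threshold = 30,
                           rest_met_max = 1.5,
                           lipa_met_max = 3) {
  cfg <- list(
    small_block_max = as.integer(small_block_max),
    dev_block_min = as.integer(dev_block_min),
    dev_block_max = as.integer(dev_block_max),
    dev_threshold = as.numeric(dev_threshold),
    dev_relative = isTRUE(dev_relative),
    bin_seconds = as.integer(bin_seconds),
    max_interp_gap_bins = as.integer(max_interp_gap_bins),
    acf_threshold = as.numeric(acf_threshold),
    min_bed_minutes = as.integer(min_bed_minutes),
    night_coverage_fraction = as.numeric(night_coverage_fraction),
    min_day_seconds = as.integer(min_day_seconds),
    min_window_seconds = as.integer(min_window_seconds),
    spo2_threshold = as.numeric(spo2_threshold),
    ct90_threshold = as.numeric(ct90_threshold),
    rest_met_max = as.numeric(rest_met_max),
    lipa_met_max = as.numeric(lipa_met_max)
  )
  stopifnot(
    cfg$small_block_max >= 0, cfg$dev_block_min > cfg$small_block_max,
    cfg$dev_block_max >= cfg$dev_block_min, cfg$dev_threshold >= 0,
    cfg$bin_seconds >= 1, cfg$max_interp_gap_bins >= 0,
    cfg$acf_threshold > 0, cfg$acf_threshold < 1,
    cfg$min_bed_minutes >= 1,
    cfg$night_coverage_fraction > 0, cfg$night_coverage_fraction <= 1,
    cfg$min_day_seconds >= 0, cfg$min_window_seconds >= 0,
    cfg$spo2_threshold > 0, cfg$spo2_threshold <= 100,
    cfg$ct90_threshold >= 0, cfg$ct90_threshold <= 100,
    cfg$rest_met_max > 0, cfg$lipa_met_max > cfg$rest_met_max
  )
  class(cfg) <- "oxiweek_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected so that typos in a config file fail loudly.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file whose
#'   top-level keys are arguments of [oxiweek_config()].
#' @return a validated \code{oxiweek_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(oxiweek_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(oxiweek_config, vals)
}

#' @export
print.oxiweek_config <- function(x, ...) {
  cat("oxiweek pipeline configuration\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

# --- internal time helpers -------------------------------------------------

# All timestamps are wall-clock local times held in a fixed UTC representation
# (clock windows such as 13:00-18:00 are wall-clock; no DST arithmetic).
.oxi_tz <- "UTC"

oxi_time <- function(x) {
  as.POSIXct(x, tz = .oxi_tz)
}

parse_iso_time <- function(x) {
  out <- as.POSIXct(x, tz = .oxi_tz,
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  out
}

format_iso_time <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%S", tz = .oxi_tz)
}

# seconds since the epoch as double, for interval arithmetic
tnum <- function(t) as.numeric(t)
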