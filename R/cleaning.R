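#' Four-step SpO2 artifact cleaning of one segment
#'
#' The oximeter flags invalid measurements with the sentinel 500, but
#' spuriously low values surround these error values. Cleaning therefore
#' runs, in order and exactly once:
#' \enumerate{
#'   \item [exclude_small_blocks()]: blocks of fewer than 20 samples between
#'     error values are excluded;
#'   \item [exclude_deviating_blocks()]: blocks of 20--100 samples between
#'     error values are excluded when their mean deviates by more than 6
#'     percentage points from the mean of the whole day or night (computed
#'     before any exclusion);
#'   \item [downsample_median()]: the remaining valid samples are
#'     down-sampled to one value per 20 s by the block median, which
#'     suppresses remaining isolated outliers;
#'   \item [interpolate_gaps()]: runs of at most 3 missing 20-s bins strictly
#'     between valid bins are filled by linear interpolation.
#' }
#' Every removal is recorded in a machine-readable audit log.
#'
#' @param seg an \code{oxi_segment} (from [split_day_night()]) with at least
#'   one raw sample.
#' @param cfg an [oxiweek_config()].
#' @return list of class \code{clean_result}: \code{bins} (a
#'   \code{clean_series} data.frame), \code{quality} (a
#'   \code{quality_fractions} list), \code{audit} (data.frame of removed
#'   blocks), \code{context_mean}, \code{spo2} (the raw samples with final
#'   statuses), and the segment's \code{kind}/\code{date}/\code{start}/
#'   \code{end}.
#' @export
clean_segment <- function(seg, cfg = oxiweek_config()) {
  stopifnot(inherits(seg, "oxi_segment"))
  spo2 <- seg$spo2
  if (nrow(spo2) == 0) stop("refusing to clean an empty segment (", seg$kind,
                            " ", seg$date, ")")
  nonerr <- spo2$status != "error"
  context_mean <- if (any(nonerr)) mean(spo2$value[nonerr]) else NA_real_
  audit1 <- audit2 <- NULL
  if (any(!nonerr) && any(nonerr)) {
    s1 <- exclude_small_blocks(spo2, cfg)
    audit1 <- attr(s1, "audit")
    s2 <- exclude_deviating_blocks(s1, context_mean, cfg)
    audit2 <- attr(s2, "audit")
    spo2 <- s2
  }
  bins <- downsample_median(spo2, start = seg$start, end = seg$end, cfg = cfg)
  bins <- interpolate_gaps(bins, cfg)
  audit <- rbind(audit1, audit2)
  if (is.null(audit)) {
    audit <- data.frame(step = character(), start = oxi_time(character()),
                        n_samples = integer(), block_mean = numeric(),
                        deviation = numeric())
  }
  out <- list(bins = bins, quality = quality_fractions(spo2),
              audit = audit, context_mean = context_mean, spo2 = spo2,
              kind = seg$kind, date = seg$date, start = seg$start,
              end = seg$end)
  class(out) <- "clean_result"
  out
}

#' @export
print.clean_result <- function(x, ...) {
  q <- x$quality
  cat(sprintf(
    "<clean_result> %s %s: %d bins (%d valid, %d interpolated); raw quality: %.2f%% valid, %.2f%% error, %.2f%% cleaned\n",
    x$kind, x$date, nrow(x$bins), sum(x$bins$status == "valid"),
    sum(x$bins$status == "interpolated"), 100 * q$fraction_valid,
    100 * q$fraction_error, 100 * q$fraction_cleaned))
  invisible(x)
}

# Maximal runs of non-error samples, with flags saying whether each run is
# bounded by an error sample on the left/right. A time discontinuity (device
# off) acts like a segment edge: the run is NOT error-bounded across a gap.
spo2_runs <- function(spo2) {
  n <- nrow(spo2)
  t <- tnum(spo2$time)
  stretch <- cumsum(c(TRUE, diff(t) != 1))
  is_err <- spo2$status == "error"
  key <- paste0(stretch, "/", is_err)
  r <- rle(key)
  len <- r$lengths
  ends <- cumsum(len)
  starts <- ends - len + 1L
  run_err <- is_err[starts]
  run_stretch <- stretch[starts]
  k <- length(len)
  left_err <- c(FALSE, run_err[-k]) & c(FALSE, run_stretch[-k] == run_stretch[-1])
  right_err <- c(run_err[-1], FALSE) & c(run_stretch[-1] == run_stretch[-k], FALSE)
  data.frame(start = starts, end = ends, length = len, error = run_err,
             bounded = left_err & right_err)
}

#' Cleaning step 1: exclude small blocks between error values
#'
#' Every maximal run of non-error samples that is adjacent to an error
#' sample on both sides and shorter than 20 samples is marked
#' \code{cleaned_out}. Runs touching a segment edge (or a recording gap) are
#' never removed by this step: removal is tied to lying between error
#' values.
#'
#' @param spo2 an [spo2_series()] (one segment's samples).
#' @param cfg an [oxiweek_config()].
#' @return the series with updated statuses; removed runs in
#'   \code{attr(, "audit")}.
#' @export
exclude_small_blocks <- function(spo2, cfg = oxiweek_config()) {
  runs <- spo2_runs(spo2)
  hit <- !runs$error & runs$bounded & runs$length <= cfg$small_block_max
  audit <- NULL
  for (i in which(hit)) {
    idx <- runs$start[i]:runs$end[i]
    spo2$status[idx] <- "cleaned_out"
    audit <- rbind(audit, data.frame(
      step = "small_block", start = spo2$time[runs$start[i]],
      n_samples = runs$length[i], block_mean = mean(spo2$value[idx]),
      deviation = NA_real_))
  }
  attr(spo2, "audit") <- audit
  spo2
}

#' Cleaning step 2: exclude deviating blocks between error values
#'
#' Runs of 20--100 non-error samples between error values are marked
#' \code{cleaned_out} when their mean SpO2 deviates by more than 6
#' percentage points (absolute, by default) from the mean of the full day or
#' night under consideration, computed over all non-error samples before any
#' exclusion.
#'
#' @param spo2 an [spo2_series()].
#' @param context_mean mean SpO2 of the whole segment's non-error samples.
#' @param cfg an [oxiweek_config()]; with \code{dev_relative = TRUE} the
#'   threshold is read as a percentage of \code{context_mean}.
#' @return the series with updated statuses; removed runs in
#'   \code{attr(, "audit")}.
#' @export
exclude_deviating_blocks <- function(spo2, context_mean,
                                     cfg = oxiweek_config()) {
  if (is.na(context_mean)) stop("context mean is undefined (no non-error samples)")
  runs <- spo2_runs(spo2)
  cand <- which(!runs$error & runs$bounded &
                runs$length >= cfg$dev_block_min &
                runs$length <= cfg$dev_block_max)
  lim <- if (cfg$dev_relative) cfg$dev_threshold / 100 * context_mean else
    cfg$dev_threshold
  audit <- NULL
  for (i in cand) {
    idx <- runs$start[i]:runs$end[i]
    m <- mean(spo2$value[idx])
    dev <- abs(m - context_mean)
    if (dev > lim) {
      spo2$status[idx] <- "cleaned_out"
      audit <- rbind(audit, data.frame(
        step = "deviating_block", start = spo2$time[runs$start[i]],
        n_samples = runs$length[i], block_mean = m, deviation = dev))
    }
  }
  attr(spo2, "audit") <- audit
  spo2
}

#' Cleaning step 3: median down-sampling to 20-s bins
#'
#' Consecutive non-overlapping 20-s windows aligned to the segment start
#' (not to wall-clock :00/:20/:40 -- segments begin at bed transitions). The
#' bin value is the median of the window's \code{raw_valid} samples; taking
#' the median suppresses isolated outliers. A bin with no valid sample is
#' \code{missing}. The median of an even count is the mean of the two
#' central values.
#'
#' @param spo2 an [spo2_series()] (statuses after steps 1--2).
#' @param start,end segment interval; bins cover \code{[start, end)} and a
#'   trailing window shorter than \code{bin_seconds} is dropped.
#' @param cfg an [oxiweek_config()].
#' @return data.frame of class \code{clean_series}: \code{time} (bin start),
#'   \code{value}, \code{status} (\code{valid}/\code{missing}), and
#'   provenance counts \code{n_valid}, \code{n_error}, \code{n_cleaned}.
#' @export
downsample_median <- function(spo2, start, end, cfg = oxiweek_config()) {
  bw <- cfg$bin_seconds
  nbins <- max(0L, as.integer(floor((tnum(end) - tnum(start)) / bw)))
  bin_time <- oxi_time(tnum(start) + bw * (seq_len(nbins) - 1))
  if (nbins == 0L) {
    out <- data.frame(time = bin_time, value = numeric(0),
                      status = character(0), n_valid = integer(0),
                      n_error = integer(0), n_cleaned = integer(0))
    class(out) <- c("clean_series", "data.frame")
    return(out)
  }
  off <- floor((tnum(spo2$time) - tnum(start)) / bw)
  inb <- off >= 0 & off < nbins
  off <- off[inb]
  status <- spo2$status[inb]
  value <- spo2$value[inb]
  f <- factor(off, levels = 0:(nbins - 1))
  n_valid <- as.integer(tapply(status == "raw_valid", f, sum, default = 0L))
  n_error <- as.integer(tapply(status == "error", f, sum, default = 0L))
  n_cleaned <- as.integer(tapply(status == "cleaned_out", f, sum,
                                 default = 0L))
  ok <- status == "raw_valid"
  med <- rep(NA_real_, nbins)
  if (any(ok)) {
    sp <- split(value[ok], factor(off[ok], levels = 0:(nbins - 1)))
    has <- lengths(sp) > 0
    med[has] <- vapply(sp[has], stats::median, numeric(1))
  }
  out <- data.frame(
    time = bin_time, value = med,
    status = ifelse(is.na(med), "missing", "valid"),
    n_valid = n_valid, n_error = n_error, n_cleaned = n_cleaned)
  class(out) <- c("clean_series", "data.frame")
  out
}

#' Cleaning step 4: linear interpolation of short bin gaps
#'
#' Runs of 1--3 consecutive missing 20-s bins strictly between valid bins
#' are replaced by linear interpolation between the flanking bin values and
#' get status \code{interpolated}. Longer runs, and missing runs touching a
#' segment edge, are left missing.
#'
#' @param cs a \code{clean_series} from [downsample_median()].
#' @param cfg an [oxiweek_config()].
#' @return the \code{clean_series} with gaps filled.
#' @export
interpolate_gaps <- function(cs, cfg = oxiweek_config()) {
  stopifnot(inherits(cs, "clean_series"))
  n <- nrow(cs)
  if (n == 0) return(cs)
  miss <- cs$status == "missing"
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    len <- r$lengths[i]
    if (len > cfg$max_interp_gap_bins) next
    if (starts[i] == 1L || ends[i] == n) next  # touches a segment edge
    lv <- cs$value[starts[i] - 1L]
    rv <- cs$value[ends[i] + 1L]
    w <- seq_len(len) / (len + 1)
    cs$value[starts[i]:ends[i]] <- lv + (rv - lv) * w
    cs$status[starts[i]:ends[i]] <- "interpolated"
  }
  cs
}

#' Data-quality fractions of raw SpO2 samples
#'
#' Fractions of device-flagged error samples, algorithm-cleaned samples and
#' valid samples over the raw 1 Hz samples in scope; the three sum to one.
#'
#' @param spo2 an [spo2_series()] with post-cleaning statuses.
#' @param mask optional logical vector (or activity-label factor level
#'   selection, see \code{scope}) restricting the samples considered.
#' @param scope optional label stored in the result.
#' @return list of class \code{quality_fractions}: \code{fraction_error},
#'   \code{fraction_cleaned}, \code{fraction_valid}, \code{n_samples},
#'   \code{scope}.
#' @export
quality_fractions <- function(spo2, mask = NULL, scope = "whole") {
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(spo2))
    spo2 <- spo2[mask, , drop = FALSE]
  }
  n <- nrow(spo2)
  if (n == 0) stop("quality fractions undefined for an empty scope (", scope,
                   ")")
  out <- list(
    fraction_error = sum(spo2$status == "error") / n,
    fraction_cleaned = sum(spo2$status == "cleaned_out") / n,
    fraction_valid = sum(spo2$status == "raw_valid") / n,
    n_samples = n, scope = scope)
  class(out) <- "quality_fractions"
  out
}

#' @export
print.quality_fractions <- function(x, ...) {
  cat(sprintf(
    "<quality_fractions> %s (n=%d): valid %.2f%%, error %.2f%%, cleaned %.2f%%\n",
    x$scope, x$n_samples, 100 * x$fraction_valid, 100 * x$fraction_error,
    100 * x$fraction_cleaned))
  invisible(x)
}

#' Decorrelation lag of a 1 Hz SpO2 signal
#'
#' Gap-aware sample autocorrelation of the valid 1 Hz signal: the series is
#' mean-removed over its valid samples and, for each lag, products are taken
#' only over pairs with both samples valid. The decorrelation lag is the
#' smallest lag at which the autocorrelation falls below the threshold
#' (default \eqn{1/e}); it motivates the choice of the 20-s down-sampling
#' time for a signal whose memory is of that order.
#'
#' @param x an [spo2_series()] (valid = status \code{raw_valid}; the series
#'   is laid out on its full 1-s grid with gaps as missing) or a plain
#'   numeric vector with \code{NA} for invalid samples.
#' @param max_lag largest lag examined, seconds. Default 300.
#' @param threshold autocorrelation threshold; default \code{exp(-1)}.
#' @return list of class \code{oxi_acf}: \code{decorrelation_lag} (seconds),
#'   \code{acf} (data.frame lag/acf for lags \code{0..max_lag}),
#'   \code{threshold}.
#' @export
autocorrelation_sampling_time <- function(x, max_lag = 300L,
                                          threshold = exp(-1)) {
  if (inherits(x, "spo2_series")) {
    t <- tnum(x$time)
    if (!nrow(x)) stop("empty series: autocorrelation undefined")
    grid <- seq(t[1], t[nrow(x)])
    v <- rep(NA_real_, length(grid))
    ok <- x$status == "raw_valid"
    v[t[ok] - t[1] + 1] <- x$value[ok]
    x <- v
  }
  x <- as.numeric(x)
  n <- length(x)
  valid <- !is.na(x)
  if (sum(valid) < 2) stop("too few valid samples for autocorrelation")
  m <- mean(x[valid])
  v <- x - m
  denom <- mean(v[valid]^2)
  if (denom == 0) stop("constant series: autocorrelation undefined (zero variance)")
  max_lag <- min(as.integer(max_lag), n - 1L)
  rho <- numeric(max_lag + 1L)
  rho[1] <- 1
  for (l in seq_len(max_lag)) {
    a <- v[seq_len(n - l)]
    b <- v[seq_len(n - l) + l]
    p <- a * b
    pok <- !is.na(p)
    if (!any(pok)) { rho[l + 1] <- NA_real_; next }
    rho[l + 1] <- mean(p[pok]) / denom
  }
  below <- which(!is.na(rho) & rho < threshold) - 1L
  below <- below[below > 0]
  if (!length(below)) {
    stop("autocorrelation stays above the threshold up to lag ", max_lag,
         " s; increase max_lag")
  }
  out <- list(decorrelation_lag = min(below),
              acf = data.frame(lag = 0:max_lag, acf = rho),
              threshold = threshold)
  class(out) <- "oxi_acf"
  out
}

#' @export
print.oxi_acf <- function(x, ...) {
  cat(sprintf("<oxi_acf> decorrelation lag %d s (threshold %.3f)\n",
              x$decorrelation_lag, x$threshold))
  invisible(x)
}
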