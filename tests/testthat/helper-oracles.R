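# Builders and independent brute-force oracles shared across tests.
# The oracles are deliberately written as plain per-sample scans (no rle, no
# vectorised run bookkeeping, sort-based medians) so that they share no code
# path with the package implementation they check.

T0 <- as.POSIXct("2017-01-05 14:00:00", tz = "UTC")

mk_spo2 <- function(values, start = T0) {
  spo2_series(start + seq_along(values) - 1, values)
}

# a single contiguous segment via the public path (no bed intervals -> one
# all-day segment); interval = [first sample, last sample + 1)
mk_seg <- function(values, start = T0) {
  split_day_night(mk_spo2(values, start), NULL)[[1]]
}

mk_act <- function(met, lying = 0, sleep = 0, start = T0) {
  n <- length(met)
  actigraphy_series(start + 60 * (seq_len(n) - 1), met,
                    rep_len(lying, n), rep_len(sleep, n))
}

# ---- brute-force four-step cleaning oracle (contiguous 1 Hz input) --------

oracle_clean <- function(values, cfg = oxiweek_config()) {
  n <- length(values)
  status <- ifelse(values == 500, "error", "raw_valid")
  nonerr <- values[values != 500]
  ctx <- if (length(nonerr)) mean(nonerr) else NA_real_
  if (any(values == 500) && length(nonerr)) {
    i <- 1
    while (i <= n) {
      if (values[i] != 500) {
        j <- i
        while (j < n && values[j + 1] != 500) j <- j + 1
        bounded <- (i > 1 && values[i - 1] == 500) &&
          (j < n && values[j + 1] == 500)
        len <- j - i + 1
        if (bounded) {
          if (len <= cfg$small_block_max) {
            status[i:j] <- "cleaned_out"
          } else if (len >= cfg$dev_block_min && len <= cfg$dev_block_max) {
            lim <- if (cfg$dev_relative) cfg$dev_threshold / 100 * ctx else
              cfg$dev_threshold
            if (abs(mean(values[i:j]) - ctx) > lim) {
              status[i:j] <- "cleaned_out"
            }
          }
        }
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  nb <- floor(n / cfg$bin_seconds)
  binv <- rep(NA_real_, nb)
  binstat <- rep("missing", nb)
  for (k in seq_len(nb)) {
    idx <- ((k - 1) * cfg$bin_seconds + 1):(k * cfg$bin_seconds)
    vals <- values[idx][status[idx] == "raw_valid"]
    if (length(vals)) {
      s <- sort(vals)
      m <- length(s)
      binv[k] <- if (m %% 2 == 1) s[(m + 1) / 2] else
        (s[m / 2] + s[m / 2 + 1]) / 2
      binstat[k] <- "valid"
    }
  }
  k <- 1
  while (k <= nb) {
    if (binstat[k] == "missing") {
      j <- k
      while (j < nb && binstat[j + 1] == "missing") j <- j + 1
      len <- j - k + 1
      if (len <= cfg$max_interp_gap_bins && k > 1 && j < nb) {
        for (q in k:j) {
          w <- (q - k + 1) / (len + 1)
          binv[q] <- binv[k - 1] + (binv[j + 1] - binv[k - 1]) * w
          binstat[q] <- "interpolated"
        }
      }
      k <- j + 1
    } else {
      k <- k + 1
    }
  }
  list(status = status, bin_value = binv, bin_status = binstat,
       fractions = c(error = mean(values == 500),
                     cleaned = mean(status == "cleaned_out"),
                     valid = mean(status == "raw_valid")))
}

# random artifact-laden segment exercising the rule boundaries: block lengths
# straddling the 19/20 and 100/101 limits, block means straddling the 6.0
# deviation threshold
random_segment_values <- function(base = 93) {
  vals <- numeric(0)
  n_tok <- sample(3:9, 1)
  for (tok in seq_len(n_tok)) {
    type <- sample(c("valid", "error", "block"), 1,
                   prob = c(0.45, 0.3, 0.25))
    if (type == "valid") {
      vals <- c(vals, base + sample(-2:2, sample(10:120, 1), replace = TRUE))
    } else if (type == "error") {
      vals <- c(vals, rep(500, sample(1:5, 1)))
    } else {
      len <- sample(c(1, 5, 18, 19, 20, 21, 50, 99, 100, 101, 120), 1)
      off <- sample(c(0, 3, 5.5, 5.9, 6.0, 6.05, 6.5, 10, 25), 1) *
        sample(c(-1, 1), 1)
      vals <- c(vals, round(base + off) + sample(-1:1, len, replace = TRUE))
    }
  }
  pmin(100, pmax(0, vals))
}

# per-sample activity lookup, scan-based
oracle_activity <- function(spo2, act, cfg = oxiweek_config()) {
  out <- character(nrow(spo2))
  for (i in seq_len(nrow(spo2))) {
    ts <- as.numeric(spo2$time[i])
    hit <- NA
    for (j in seq_len(nrow(act))) {
      ta <- as.numeric(act$time[j])
      if (ts >= ta && ts < ta + 60) { hit <- j; break }
    }
    if (is.na(hit)) { out[i] <- "unaligned"; next }
    if (act$sleep[hit] == 1) out[i] <- "asleep"
    else if (act$met[hit] <= cfg$rest_met_max) out[i] <- "rest"
    else if (act$met[hit] <= cfg$lipa_met_max) out[i] <- "lipa"
    else out[i] <- "mvpa"
  }
  out
}

# expected feature-table value lookup
ft_val <- function(ft, patient, date, kind, feature) {
  ft <- as.data.frame(ft)
  v <- ft$value[ft$patient == patient & ft$date == date & ft$kind == kind &
                  ft$feature == feature]
  if (length(v)) v else NA_real_
}
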