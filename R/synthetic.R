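#' Synthetic patient profile
#'
#' Parameterises one simulated patient-week of raw 1 Hz SpO2 and 1/min
#' actigraphy with known ground truth. The generator emulates the signal
#' structure the pipeline assumes: a circadian SpO2 baseline with a lower
#' nocturnal level and a slight evening dip, Gaussian AR(1) within-period
#' fluctuation (a modelling choice, with memory of the order of 20 s),
#' transient desaturation events, clustered error bursts (sentinel 500)
#' flanked by spuriously low values, isolated single-sample outliers,
#' realistic bed intervals with mid-sleep wake, and daytime MET profiles
#' spanning rest/LIPA/MVPA with wear gaps.
#'
#' @param patient_id identifier used in file names and tables.
#' @param baseline_day_spo2 daytime SpO2 baseline, percent (0, 100].
#' @param nocturnal_drop nocturnal baseline reduction, percentage points
#'   (>= 0).
#' @param intraperiod_sd stationary SD of the AR(1) fluctuation, percentage
#'   points (>= 0).
#' @param desat_event_rate transient desaturation events per hour (>= 0).
#' @param desat_event_depth peak event depth, percentage points.
#' @param desat_event_duration event duration, seconds.
#' @param artifact_burst_rate artifact episodes per hour of daytime wear
#'   (>= 0).
#' @param night_artifact_burst_rate artifact episodes per hour of nocturnal
#'   wear; defaults to one fifth of \code{artifact_burst_rate} (nights are
#'   much cleaner than days).
#' @param lipa_artifact_weight,mvpa_artifact_weight relative propensity of
#'   an artifact episode to start during a LIPA / MVPA minute rather than a
#'   rest minute (motion artifacts concentrate in vigorous movement;
#'   defaults 2 and 8). Episode placement is reweighted, the per-hour rate
#'   is unchanged.
#' @param outlier_rate fraction of samples replaced by isolated outliers
#'   (in [0, 1]).
#' @param bed_time_mean mean time of going to bed, \code{"HH:MM"}.
#' @param time_in_bed_mean mean time in bed, minutes.
#' @param bed_jitter_minutes uniform jitter (plus/minus) of bed start,
#'   minutes.
#' @param tib_jitter_minutes uniform jitter (plus/minus) of time in bed,
#'   minutes.
#' @param n_days number of monitored days (>= 1); one night per day.
#' @param evening_dip baseline reduction after 18:00, percentage points.
#' @param night_baselines optional numeric vector (length \code{n_days}) of
#'   per-night baselines overriding
#'   \code{baseline_day_spo2 - nocturnal_drop}.
#' @param night_desat_fraction optional fraction in [0, 1]: force this
#'   fraction of every night (from bed start, aligned to 20-s blocks) to a
#'   low baseline \code{desat_low_level}, constructing nights of known CT90.
#' @param desat_low_level low level used by \code{night_desat_fraction}.
#' @param ar_phi AR(1) coefficient per 1-s step, in [0, 1).
#' @param start_date first calendar date, \code{"YYYY-MM-DD"}.
#' @param seed integer seed, or \code{NULL} to draw from the current RNG
#'   stream (used by [generate_cohort()], which seeds once globally).
#' @return validated list of class \code{patient_profile}.
#' @export
patient_profile <- function(patient_id = "P01",
                            baseline_day_spo2 = 94,
                            nocturnal_drop = 2,
                            intraperiod_sd = 1.5,
                            desat_event_rate = 1,
                            desat_event_depth = 6,
                            desat_event_duration = 120,
                            artifact_burst_rate = 2,
                            night_artifact_burst_rate = NULL,
                            lipa_artifact_weight = 2,
                            mvpa_artifact_weight = 8,
                            outlier_rate = 0.002,
                            bed_time_mean = "23:00",
                            time_in_bed_mean = 480,
                            bed_jitter_minutes = 30,
                            tib_jitter_minutes = 30,
                            n_days = 7,
                            evening_dip = 0.8,
                            night_baselines = NULL,
                            night_desat_fraction = NULL,
                            desat_low_level = 85,
                            ar_phi = exp(-1 / 20),
                            start_date = "2017-01-02",
                            seed = 1L) {
  p <- as.list(environment())
  chk <- function(field, ok) {
    if (!isTRUE(ok)) stop("invalid profile field '", field, "'")
  }
  chk("baseline_day_spo2", is.numeric(baseline_day_spo2) &&
        baseline_day_spo2 > 0 && baseline_day_spo2 <= 100)
  chk("nocturnal_drop", is.numeric(nocturnal_drop) && nocturnal_drop >= 0)
  chk("intraperiod_sd", is.numeric(intraperiod_sd) && intraperiod_sd >= 0)
  chk("desat_event_rate", is.numeric(desat_event_rate) &&
        desat_event_rate >= 0)
  chk("desat_event_depth", is.numeric(desat_event_depth) &&
        desat_event_depth >= 0)
  chk("desat_event_duration", is.numeric(desat_event_duration) &&
        desat_event_duration >= 1)
  chk("artifact_burst_rate", is.numeric(artifact_burst_rate) &&
        artifact_burst_rate >= 0)
  if (is.null(night_artifact_burst_rate)) {
    p$night_artifact_burst_rate <- 0.2 * artifact_burst_rate
  } else {
    chk("night_artifact_burst_rate", is.numeric(night_artifact_burst_rate) &&
          night_artifact_burst_rate >= 0)
  }
  chk("lipa_artifact_weight", is.numeric(lipa_artifact_weight) &&
        lipa_artifact_weight >= 0)
  chk("mvpa_artifact_weight", is.numeric(mvpa_artifact_weight) &&
        mvpa_artifact_weight >= 0)
  chk("outlier_rate", is.numeric(outlier_rate) && outlier_rate >= 0 &&
        outlier_rate <= 1)
  chk("bed_time_mean", is.character(bed_time_mean) &&
        grepl("^[0-2][0-9]:[0-5][0-9]$", bed_time_mean))
  chk("time_in_bed_mean", is.numeric(time_in_bed_mean) &&
        time_in_bed_mean >= 60)
  chk("bed_jitter_minutes", is.numeric(bed_jitter_minutes) &&
        bed_jitter_minutes >= 0)
  chk("tib_jitter_minutes", is.numeric(tib_jitter_minutes) &&
        tib_jitter_minutes >= 0)
  chk("n_days", is.numeric(n_days) && n_days >= 1 && n_days == round(n_days))
  chk("evening_dip", is.numeric(evening_dip) && evening_dip >= 0)
  if (!is.null(night_baselines)) {
    chk("night_baselines", is.numeric(night_baselines) &&
          length(night_baselines) == n_days &&
          all(night_baselines > 0 & night_baselines <= 100))
  }
  if (!is.null(night_desat_fraction)) {
    chk("night_desat_fraction", is.numeric(night_desat_fraction) &&
          night_desat_fraction >= 0 && night_desat_fraction <= 1)
  }
  chk("desat_low_level", is.numeric(desat_low_level) && desat_low_level > 0 &&
        desat_low_level < 90)
  chk("ar_phi", is.numeric(ar_phi) && ar_phi >= 0 && ar_phi < 1)
  chk("start_date", is.character(start_date) &&
        !is.na(as.Date(start_date, "%Y-%m-%d")))
  if (!is.null(seed)) chk("seed", is.numeric(seed) && seed == round(seed))
  p$n_days <- as.integer(n_days)
  class(p) <- "patient_profile"
  p
}

# stationary Gaussian AR(1) noise, sd = stationary SD
ar1_noise <- function(n, phi, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# one artifact episode: k error runs separated by depressed inter-runs, with
# depressed outer flanks. Returns data.frame(offset, kind, depression)
# relative to the episode onset; kinds are "error" / "artifact".
artifact_episode <- function() {
  k <- 1L + stats::rpois(1, 1.2)
  err_lens <- pmin(1L + stats::rgeom(k, 1 / 10), 60L)
  inter_lens <- if (k > 1) sample(50L, k - 1L, replace = TRUE) else integer(0)
  fl <- sample(60L, 1); fr <- sample(60L, 1)
  kinds <- c(rep("artifact", fl))
  for (j in seq_len(k)) {
    kinds <- c(kinds, rep("error", err_lens[j]))
    if (j < k) kinds <- c(kinds, rep("artifact", inter_lens[j]))
  }
  kinds <- c(kinds, rep("artifact", fr))
  depr <- ifelse(kinds == "artifact", stats::runif(length(kinds), 10, 30), 0)
  data.frame(offset = seq_along(kinds) - 1L, kind = kinds, depression = depr)
}

#' Generate one synthetic patient-week
#'
#' Produces the raw streams a real deployment would yield -- a 1 Hz SpO2
#' series over the wear periods (full nights in bed plus afternoon and
#' evening daytime blocks, with the device off in between) and a continuous
#' 1/min actigraphy series -- together with ground truth. Per-night truth
#' (mean SpO2, CT90) is computed from the artifact-free signal passed
#' through the same ideal 20-s median binning aligned to the true bed start,
#' so that comparing pipeline estimates against truth isolates
#' artifact-handling error. Output is fully reproducible for a fixed seed.
#'
#' @param profile a [patient_profile()].
#' @return list of class \code{oxi_synthetic}: \code{spo2}
#'   ([spo2_series()]), \code{act} ([actigraphy_series()]), \code{truth}
#'   (list: \code{bed_intervals}, \code{nights} with per-night
#'   \code{true_mean}/\code{true_ct90}, \code{days} with per-day
#'   \code{true_mean}, per-sample \code{labels} in
#'   \code{clean|artifact|outlier|error}, \code{designed_category},
#'   \code{two_night} flag list), and \code{profile}.
#' @export
generate_patient_week <- function(profile) {
  stopifnot(inherits(profile, "patient_profile"))
  p <- profile
  if (!is.null(p$seed)) set.seed(as.integer(p$seed))
  day0 <- tnum(oxi_time(paste(p$start_date, "00:00:00")))
  bed_secs <- {
    hm <- as.integer(strsplit(p$bed_time_mean, ":")[[1]])
    hm[1] * 3600 + hm[2] * 60
  }
  nd <- p$n_days
  jit_min <- function(w) if (w > 0) round(stats::runif(1, -w, w)) else 0
  bed_start <- bed_end <- numeric(nd)
  for (d in seq_len(nd)) {
    bs <- day0 + (d - 1) * 86400 + bed_secs + 60 * jit_min(p$bed_jitter_minutes)
    tib <- round(p$time_in_bed_mean) + jit_min(p$tib_jitter_minutes)
    bed_start[d] <- bs
    bed_end[d] <- bs + 60 * tib
  }

  ## ---- actigraphy: continuous 1/min from day0 to the last bed end --------
  act_t <- seq(day0, bed_end[nd] - 60, by = 60)
  n_min <- length(act_t)
  met <- pmax(0.6, stats::rnorm(n_min, 1.2, 0.1))
  lying <- integer(n_min)
  sleep <- integer(n_min)
  for (d in seq_len(nd)) {
    inb <- which(act_t >= bed_start[d] & act_t < bed_end[d])
    lying[inb] <- 1L
    met[inb] <- pmax(0.6, stats::rnorm(length(inb), 0.95, 0.05))
    sl <- rep(1L, length(inb))
    latency <- sample(5:20, 1)
    sl[seq_len(min(latency, length(inb)))] <- 0L
    n_wake <- 1L + stats::rpois(1, 2)
    for (w in seq_len(n_wake)) {
      len <- sample(5:25, 1)
      if (length(inb) > latency + len + 10) {
        at <- sample((latency + 2):(length(inb) - len), 1)
        sl[at:(at + len - 1)] <- 0L
      }
    }
    sleep[inb] <- sl
    # daytime activity bouts between getting up and going to bed
    awake_lo <- if (d == 1) day0 + 7 * 3600 else bed_end[d - 1]
    day_idx <- which(act_t >= awake_lo & act_t < bed_start[d])
    if (length(day_idx) > 60) {
      for (b in seq_len(4)) {
        len <- sample(10:30, 1)
        at <- sample(seq_len(length(day_idx) - len), 1)
        met[day_idx[at:(at + len - 1)]] <- stats::runif(len, 1.8, 2.8)
      }
      for (b in seq_len(2)) {
        len <- sample(4:10, 1)
        at <- sample(seq_len(length(day_idx) - len), 1)
        met[day_idx[at:(at + len - 1)]] <- stats::runif(len, 3.2, 4.8)
      }
    }
  }
  act <- actigraphy_series(oxi_time(act_t), met, lying, sleep)

  ## ---- SpO2 wear blocks --------------------------------------------------
  blocks <- list()
  for (d in seq_len(nd)) {
    day_d <- day0 + (d - 1) * 86400
    aft_start <- day_d + 12.5 * 3600 + round(stats::runif(1, 0, 3600))
    aft_end <- min(aft_start + round(stats::runif(1, 3.5, 4.5) * 3600),
                   day_d + 18 * 3600 - 60)
    eve_start <- day_d + 18 * 3600 + 60 * sample(0:20, 1)
    eve_end <- bed_start[d] - 60 * sample(0:10, 1)
    if (aft_end > aft_start) {
      blocks[[length(blocks) + 1]] <-
        list(start = aft_start, end = aft_end, kind = "day", day = d)
    }
    if (eve_end > eve_start) {
      blocks[[length(blocks) + 1]] <-
        list(start = eve_start, end = eve_end, kind = "day", day = d)
    }
    blocks[[length(blocks) + 1]] <-
      list(start = bed_start[d], end = bed_end[d], kind = "night", day = d)
  }

  night_base <- if (!is.null(p$night_baselines)) p$night_baselines else
    rep(p$baseline_day_spo2 - p$nocturnal_drop, nd)

  all_t <- vector("list", length(blocks))
  all_v <- vector("list", length(blocks))
  all_clean <- vector("list", length(blocks))
  all_lab <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    bl <- blocks[[bi]]
    t <- seq(bl$start, bl$end - 1)
    n <- length(t)
    day_d <- day0 + (bl$day - 1) * 86400
    if (bl$kind == "night") {
      mu <- rep(night_base[bl$day], n)
      if (!is.null(p$night_desat_fraction)) {
        nbins <- floor(n / 20)
        low_bins <- round(p$night_desat_fraction * nbins)
        low_n <- min(n, low_bins * 20)
        if (low_n > 0) mu[seq_len(low_n)] <- p$desat_low_level
      }
    } else {
      mu <- rep(p$baseline_day_spo2, n)
      mu[t >= day_d + 18 * 3600] <- p$baseline_day_spo2 - p$evening_dip
    }
    # transient desaturation events
    hrs <- n / 3600
    n_ev <- stats::rpois(1, p$desat_event_rate * hrs)
    for (e in seq_len(n_ev)) {
      dur <- max(20L, round(p$desat_event_duration *
                              stats::runif(1, 0.8, 1.2)))
      at <- sample.int(n, 1)
      span <- at:min(n, at + dur - 1)
      depth <- p$desat_event_depth * stats::runif(1, 0.8, 1.2)
      mu[span] <- mu[span] -
        depth * sin(pi * (seq_along(span) - 0.5) / length(span))
    }
    clean <- round(pmin(100, pmax(50, mu + ar1_noise(n, p$ar_phi,
                                                     p$intraperiod_sd))))
    v <- clean
    lab <- rep("clean", n)
    # isolated outliers
    if (p$outlier_rate > 0) {
      oi <- which(stats::runif(n) < p$outlier_rate)
      if (length(oi)) {
        v[oi] <- pmax(0, v[oi] - round(stats::runif(length(oi), 10, 40)))
        lab[oi] <- "outlier"
      }
    }
    # clustered artifact episodes; daytime placement follows activity level
    # (motion artifacts concentrate in LIPA/MVPA minutes)
    rate <- if (bl$kind == "night") p$night_artifact_burst_rate else
      p$artifact_burst_rate
    n_ep <- stats::rpois(1, rate * hrs)
    ep_w <- NULL
    if (bl$kind == "day" && n_ep > 0) {
      midx <- floor((t - day0) / 60) + 1
      midx[midx < 1 | midx > length(met)] <- NA
      m_here <- ifelse(is.na(midx), 1.2, met[midx])
      ep_w <- 1 + (p$lipa_artifact_weight - 1) *
        (m_here > 1.5 & m_here <= 3) +
        (p$mvpa_artifact_weight - 1) * (m_here > 3)
    }
    for (e in seq_len(n_ep)) {
      at <- if (is.null(ep_w)) sample.int(n, 1) else
        sample.int(n, 1, prob = ep_w)
      ep <- artifact_episode()
      idx <- at + ep$offset
      keep <- idx <= n
      idx <- idx[keep]; ep <- ep[keep, , drop = FALSE]
      err <- ep$kind == "error"
      v[idx[err]] <- 500
      lab[idx[err]] <- "error"
      art <- !err
      v[idx[art]] <- pmax(0, round(clean[idx[art]] - ep$depression[art]))
      lab[idx[art]] <- "artifact"
    }
    all_t[[bi]] <- t
    all_v[[bi]] <- v
    all_clean[[bi]] <- clean
    all_lab[[bi]] <- lab
  }

  t_all <- unlist(all_t)
  ord <- order(t_all)
  spo2 <- spo2_series(oxi_time(t_all[ord]), unlist(all_v)[ord])
  labels <- unlist(all_lab)[ord]
  clean_all <- unlist(all_clean)[ord]

  ## ---- ground truth ------------------------------------------------------
  nights <- data.frame(night = seq_len(nd),
                       date = format(oxi_time(bed_start), "%Y-%m-%d",
                                     tz = .oxi_tz),
                       true_mean = NA_real_, true_ct90 = NA_real_)
  t_sorted <- t_all[ord]
  for (d in seq_len(nd)) {
    inb <- t_sorted >= bed_start[d] & t_sorted < bed_end[d]
    cv <- clean_all[inb]
    nbins <- floor(length(cv) / 20)
    bm <- vapply(seq_len(nbins), function(k) {
      stats::median(cv[((k - 1) * 20 + 1):(k * 20)])
    }, numeric(1))
    nights$true_mean[d] <- mean(bm)
    nights$true_ct90[d] <- 100 * sum(bm < 90) / nbins
  }
  days <- data.frame(day = seq_len(nd),
                     date = format(oxi_time(day0 + (seq_len(nd) - 1) * 86400),
                                   "%Y-%m-%d", tz = .oxi_tz),
                     true_mean = NA_real_)
  for (d in seq_len(nd)) {
    lo <- if (d == 1) day0 else bed_end[d - 1]
    ind <- t_sorted >= lo & t_sorted < bed_start[d]
    if (any(ind)) days$true_mean[d] <- mean(clean_all[ind])
  }
  designed <- if (nd >= 2) classify_desaturator(nights$true_ct90) else NA
  two_night <- if (nd >= 2) two_night_vs_week_category(nights$true_ct90) else
    NULL
  truth <- list(
    bed_intervals = data.frame(night = seq_len(nd),
                               bed_start = oxi_time(bed_start),
                               bed_end = oxi_time(bed_end)),
    nights = nights, days = days, labels = labels,
    designed_category = designed, two_night = two_night)
  out <- list(spo2 = spo2, act = act, truth = truth, profile = p)
  class(out) <- "oxi_synthetic"
  out
}

#' @export
print.oxi_synthetic <- function(x, ...) {
  cat(sprintf(
    "<oxi_synthetic> %s: %d SpO2 samples over %d nights, category %s\n",
    x$profile$patient_id, nrow(x$spo2), x$profile$n_days,
    as.character(x$truth$designed_category)))
  invisible(x)
}

#' Write a synthetic patient to disk
#'
#' Writes \code{<id>_spo2.csv} and \code{<id>_act.csv} in the package CSV
#' dialects plus a \code{<id>_truth.json} sidecar (per-night truth, designed
#' category, label counts; not the full per-sample label vector).
#'
#' @param x an \code{oxi_synthetic}.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_patient <- function(x, dir) {
  stopifnot(inherits(x, "oxi_synthetic"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- x$profile$patient_id
  paths <- c(
    spo2 = file.path(dir, paste0(id, "_spo2.csv")),
    act = file.path(dir, paste0(id, "_act.csv")),
    truth = file.path(dir, paste0(id, "_truth.json")))
  write_spo2_csv(x$spo2, paths[["spo2"]])
  write_actigraphy_csv(x$act, paths[["act"]])
  truth <- x$truth
  truth$bed_intervals <- data.frame(
    night = truth$bed_intervals$night,
    bed_start = format_iso_time(truth$bed_intervals$bed_start),
    bed_end = format_iso_time(truth$bed_intervals$bed_end))
  truth$label_counts <- as.list(table(truth$labels))
  truth$labels <- NULL
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(paths)
}

#' Generate a designed cohort of synthetic patient-weeks
#'
#' Builds patients whose per-night true CT90 sequences are all above 30\%
#' (consistent desaturators), all at or below (consistent nondesaturators),
#' or mixed (occasional desaturators). Occasional patients have nightly mean
#' SpO2 near 90\% -- nights alternate between a low baseline (clear
#' desaturation) and a high one (clear non-desaturation) -- and 60\% of them
#' are concordant over their first two nights (both on the same side of the
#' threshold), so the two-night assessment looks consistent but the week
#' reveals the switching. All randomness flows from one global seed.
#'
#' @param n_consistent_desat,n_consistent_nondesat,n_occasional patient
#'   counts (>= 0).
#' @param seed integer seed for the whole cohort.
#' @param n_days monitored days per patient, default 7.
#' @param out_dir optional directory: each patient is written via
#'   [write_patient()] plus a \code{cohort_manifest.json}.
#' @param profile_overrides named list of [patient_profile()] arguments
#'   applied to every patient (e.g. lower artifact rates).
#' @return list of class \code{oxi_cohort}: \code{patients} (list of
#'   \code{oxi_synthetic}), \code{design} (data.frame: patient, group,
#'   designed_category, designed_two_night_flag), \code{seed}.
#' @export
generate_cohort <- function(n_consistent_desat, n_consistent_nondesat,
                            n_occasional, seed, n_days = 7, out_dir = NULL,
                            profile_overrides = list()) {
  stopifnot(n_consistent_desat >= 0, n_consistent_nondesat >= 0,
            n_occasional >= 0)
  n_tot <- n_consistent_desat + n_consistent_nondesat + n_occasional
  if (n_tot == 0) stop("empty cohort requested")
  set.seed(as.integer(seed))
  groups <- c(rep("consistent_desat", n_consistent_desat),
              rep("consistent_nondesat", n_consistent_nondesat),
              rep("occasional", n_occasional))
  n_conc <- round(0.6 * n_occasional)  # two-night-concordant occasionals
  occ_seen <- 0L
  patients <- vector("list", n_tot)
  design <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    id <- sprintf("P%02d", i)
    g <- groups[i]
    if (g == "consistent_desat") {
      base_day <- stats::runif(1, 90.5, 92.5)
      nb <- stats::runif(1, 85.5, 88) + stats::runif(n_days, -0.3, 0.3)
    } else if (g == "consistent_nondesat") {
      base_day <- stats::runif(1, 94, 96)
      nb <- stats::runif(1, 92, 94) + stats::runif(n_days, -0.3, 0.3)
    } else {
      occ_seen <- occ_seen + 1L
      base_day <- stats::runif(1, 92, 93)
      low <- stats::runif(1, 88.2, 88.8)
      high <- stats::runif(1, 91.2, 92)
      is_low <- rep(NA, n_days)
      if (occ_seen <= n_conc) {
        s <- occ_seen %% 2 == 0
        is_low[1:2] <- s
      } else {
        is_low[1:2] <- c(occ_seen %% 2 == 0, occ_seen %% 2 != 0)
      }
      if (n_days > 2) {
        is_low[3:n_days] <- stats::runif(n_days - 2) < 0.5
      }
      # an occasional patient must see both sides of the threshold
      if (all(is_low)) is_low[n_days] <- FALSE
      if (!any(is_low)) is_low[n_days] <- TRUE
      nb <- ifelse(is_low, low, high) + stats::runif(n_days, -0.2, 0.2)
    }
    args <- c(list(patient_id = id, baseline_day_spo2 = base_day,
                   night_baselines = nb, n_days = n_days, seed = NULL),
              profile_overrides)
    prof <- do.call(patient_profile, args[!duplicated(names(args))])
    patients[[i]] <- generate_patient_week(prof)
    design[[i]] <- data.frame(
      patient = id, group = g,
      designed_category = patients[[i]]$truth$designed_category,
      designed_two_night_flag = patients[[i]]$truth$two_night$flag,
      designed_two_night_concordant =
        patients[[i]]$truth$two_night$first_two_concordant)
  }
  design <- do.call(rbind, design)
  out <- list(patients = patients, design = design, seed = as.integer(seed))
  class(out) <- "oxi_cohort"
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (pt in patients) write_patient(pt, out_dir)
    manifest <- list(seed = as.integer(seed), n_days = n_days,
                     design = design)
    jsonlite::write_json(manifest, file.path(out_dir,
                                             "cohort_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  out
}

#' @export
print.oxi_cohort <- function(x, ...) {
  cat(sprintf("<oxi_cohort> %d patients (seed %d)\n", nrow(x$design), x$seed))
  print(table(x$design$group, x$design$designed_category))
  invisible(x)
}
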