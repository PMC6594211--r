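test_that("profile validation rejects bad fields by name", {
  expect_error(patient_profile(baseline_day_spo2 = 104),
               "baseline_day_spo2")
  expect_error(patient_profile(nocturnal_drop = -1), "nocturnal_drop")
  expect_error(patient_profile(outlier_rate = 2), "outlier_rate")
  expect_error(patient_profile(n_days = 0), "n_days")
  expect_error(patient_profile(bed_time_mean = "25h"), "bed_time_mean")
  expect_error(patient_profile(night_baselines = c(90, 91), n_days = 3),
               "night_baselines")
})

test_that("a noise-free profile yields a constant daytime signal", {
  p <- patient_profile(n_days = 1, seed = 2, baseline_day_spo2 = 95,
                       intraperiod_sd = 0, desat_event_rate = 0,
                       artifact_burst_rate = 0, outlier_rate = 0,
                       evening_dip = 0, nocturnal_drop = 0)
  x <- generate_patient_week(p)
  expect_true(all(x$spo2$value == 95))
  expect_true(all(x$truth$labels == "clean"))
})

test_that("a constructed night forces its designed CT90 exactly", {
  p <- patient_profile(n_days = 2, seed = 3, intraperiod_sd = 0,
                       desat_event_rate = 0, artifact_burst_rate = 0,
                       outlier_rate = 0, bed_jitter_minutes = 0,
                       tib_jitter_minutes = 0, time_in_bed_mean = 480,
                       night_desat_fraction = 0.4, nocturnal_drop = 0,
                       baseline_day_spo2 = 95)
  x <- generate_patient_week(p)
  expect_equal(x$truth$nights$true_ct90, c(40, 40))
  # 40% of in-bed seconds are below 90 by construction
  bs <- x$truth$bed_intervals$bed_start[1]
  be <- x$truth$bed_intervals$bed_end[1]
  inb <- x$spo2$time >= bs & x$spo2$time < be
  expect_equal(mean(x$spo2$value[inb] < 90), 0.4)
})

test_that("the same seed reproduces byte-identical output files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_patient(generate_patient_week(patient_profile(n_days = 2,
                                                      seed = 123)), d1)
  write_patient(generate_patient_week(patient_profile(n_days = 2,
                                                      seed = 123)), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
  # and a different seed does not
  d3 <- withr::local_tempdir()
  write_patient(generate_patient_week(patient_profile(n_days = 2,
                                                      seed = 124)), d3)
  expect_false(identical(
    readBin(file.path(d1, "P01_spo2.csv"), "raw", 1e7),
    readBin(file.path(d3, "P01_spo2.csv"), "raw", 1e7)))
})

test_that("clean-sample moments converge to the profile values", {
  p <- patient_profile(n_days = 4, seed = 6, baseline_day_spo2 = 94,
                       nocturnal_drop = 2, intraperiod_sd = 1.5,
                       desat_event_rate = 0, artifact_burst_rate = 0,
                       outlier_rate = 0, evening_dip = 0)
  x <- generate_patient_week(p)
  beds <- x$truth$bed_intervals
  in_bed <- rep(FALSE, nrow(x$spo2))
  for (i in seq_len(nrow(beds))) {
    in_bed <- in_bed | (x$spo2$time >= beds$bed_start[i] &
                          x$spo2$time < beds$bed_end[i])
  }
  day_v <- x$spo2$value[!in_bed]
  night_v <- x$spo2$value[in_bed]
  # effective sample size under AR(1) memory ~ 2/(1 - phi) seconds per
  # independent draw; allow 3 standard errors
  ness <- function(v) length(v) * (1 - p$ar_phi) / (1 + p$ar_phi)
  se_day <- p$intraperiod_sd / sqrt(ness(day_v))
  se_night <- p$intraperiod_sd / sqrt(ness(night_v))
  expect_lt(abs(mean(day_v) - 94), 3 * se_day + 0.3)  # + rounding margin
  expect_lt(abs(mean(night_v) - 92), 3 * se_night + 0.3)
  expect_lt(abs(sd(day_v) - 1.5), 0.3)
})

test_that("the error-coded fraction converges to rate times mean episode error length", {
  p <- patient_profile(n_days = 7, seed = 44, artifact_burst_rate = 4,
                       night_artifact_burst_rate = 4, outlier_rate = 0,
                       desat_event_rate = 0)
  x <- generate_patient_week(p)
  frac <- mean(x$spo2$value == 500)
  # episodes have (1 + Pois(1.2)) error runs of mean length 10 (truncated
  # geometric): about 22 error seconds per episode
  expected <- 4 * 22 / 3600
  expect_lt(abs(frac - expected) / expected, 0.35)
  # labels and the sentinel agree exactly
  expect_identical(x$spo2$value == 500, x$truth$labels == "error")
})

test_that("every sample carries exactly one ground-truth label", {
  x <- generate_patient_week(patient_profile(n_days = 2, seed = 10))
  expect_equal(length(x$truth$labels), nrow(x$spo2))
  expect_true(all(x$truth$labels %in% c("clean", "artifact", "outlier",
                                        "error")))
})

test_that("designed single-category cohorts come out as designed", {
  # one consistent nondesaturator: every night at or below the threshold
  coh0 <- generate_cohort(0, 1, 0, seed = 5, n_days = 4)
  expect_true(all(coh0$patients[[1]]$truth$nights$true_ct90 <= 30))
  expect_equal(coh0$design$designed_category, "consistent_nondesaturator")

  # one consistent desaturator, recovered end to end by the pipeline
  coh1 <- generate_cohort(1, 0, 0, seed = 5, n_days = 4)
  pt <- coh1$patients[[1]]
  expect_true(all(pt$truth$nights$true_ct90 > 30))
  res <- analyze_patient(pt$spo2, pt$act, "P01")
  ft <- as.data.frame(res$features)
  ct <- ft$value[ft$kind == "night" & ft$feature == "ct90"]
  expect_equal(classify_desaturator(ct), "consistent_desaturator")
})

test_that("cohort writing produces the dialect files plus truth sidecars", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(1, 1, 1, seed = 9, n_days = 2, out_dir = dir)
  expect_equal(nrow(coh$design), 3)
  files <- list.files(dir)
  expect_true(all(c("P01_spo2.csv", "P01_act.csv", "P01_truth.json",
                    "cohort_manifest.json") %in% files))
  # files re-read into the same series the generator returned
  expect_equal(read_spo2_csv(file.path(dir, "P01_spo2.csv")),
               coh$patients[[1]]$spo2)
  tr <- jsonlite::read_json(file.path(dir, "P01_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$designed_category, coh$design$designed_category[1])
})
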