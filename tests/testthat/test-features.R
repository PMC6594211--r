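mk_cs_vals <- function(vals, start = T0) {
  v <- rep(vals, each = 20)
  downsample_median(spo2_series(start + seq_along(v) - 1, v), start = start,
                    end = start + length(v))
}

test_that("period features compute mean, sample SD and CT90 over non-missing bins", {
  pf <- period_features(mk_cs_vals(rep(95, 10)))
  expect_equal(pf$mean_spo2, 95)
  expect_equal(pf$spo2_sd, 0)
  expect_equal(pf$ct90, 0)

  expect_equal(period_features(mk_cs_vals(rep(85, 10)))$ct90, 100)

  # hand-computable case: bins 92, 89, 91, 88
  v <- c(92, 89, 91, 88)
  pf <- period_features(mk_cs_vals(v))
  expect_equal(pf$ct90, 50)
  expect_equal(pf$mean_spo2, 90)
  expect_equal(pf$spo2_sd, sqrt(sum((v - mean(v))^2) / 3))
  expect_equal(pf$n_valid_bins, 4)
  expect_equal(pf$range_spo2, 4)

  # interpolated bins count as data; missing bins never do
  cs <- interpolate_gaps(local({
    v <- rep(c(94, NA, 96), each = 20)
    keep <- !is.na(v)
    downsample_median(spo2_series(T0 + which(keep) - 1, v[keep]), start = T0,
                      end = T0 + 60)
  }))
  expect_equal(period_features(cs)$n_valid_bins, 3)
  expect_equal(period_features(cs)$mean_spo2, 95)

  empty <- mk_cs_vals(95)[0, ]
  class(empty) <- c("clean_series", "data.frame")
  expect_error(period_features(empty), "undefined")
})

test_that("CT90 never decreases when the whole series is shifted down", {
  set.seed(8)
  for (rep in 1:30) {
    vals <- round(runif(sample(5:40, 1), 85, 99))
    shift <- runif(1, 0.5, 6)
    ct_a <- period_features(mk_cs_vals(vals))$ct90
    ct_b <- period_features(mk_cs_vals(vals - shift))$ct90
    expect_gte(ct_b, ct_a)
  }
})

test_that("sleep metrics count in-bed minutes as the study defines them", {
  mk_bed_act <- function(sleep_flags, start = T0) {
    n <- length(sleep_flags)
    list(act = actigraphy_series(start + 60 * (0:(n - 1)), rep(0.9, n),
                                 rep(1L, n), sleep_flags),
         bed = data.frame(bed_start = start, bed_end = start + 60 * n))
  }
  # 480 minutes all asleep
  a <- mk_bed_act(rep(1L, 480))
  sm <- sleep_metrics(a$act, a$bed)
  expect_equal(sm$tnst, 480)
  expect_equal(sm$waso, 0)
  expect_equal(sm$seff, 100)

  # 30 awake, then 400 asleep with 50 awake interleaved after onset
  flags <- c(rep(0L, 30), rep(1L, 200), rep(0L, 50), rep(1L, 200))
  a <- mk_bed_act(flags)
  sm <- sleep_metrics(a$act, a$bed)
  expect_equal(sm$tnst, 400)
  expect_equal(sm$waso, 50)
  expect_equal(sm$seff, 100 * 400 / 480, tolerance = 1e-12)
  expect_equal(sm$onset_latency, 30)

  # no sleep at all: zero TNST and WASO (no onset), Seff 0
  a <- mk_bed_act(rep(0L, 120))
  sm <- sleep_metrics(a$act, a$bed)
  expect_equal(c(sm$tnst, sm$waso, sm$seff), c(0, 0, 0))

  # identity: latency + TNST + WASO = time in bed, on random nights
  set.seed(12)
  for (rep in 1:40) {
    flags <- as.integer(runif(sample(200:500, 1)) < 0.8)
    a <- mk_bed_act(flags)
    sm <- sleep_metrics(a$act, a$bed)
    expect_identical(sm$onset_latency + sm$tnst + sm$waso, sm$time_in_bed)
  }
})

test_that("weekly summaries average and range per-period features", {
  d <- data.frame(mean_spo2 = c(88, 90, 86, 90, 89, 88, 90))
  ws <- weekly_summary(d, "night")
  expect_equal(unname(ws$range["mean_spo2"]), 4)
  expect_equal(unname(ws$average["mean_spo2"]), mean(d$mean_spo2))
  expect_equal(ws$n_periods, 7)

  ws1 <- weekly_summary(data.frame(mean_spo2 = 91.5), "day")
  expect_equal(unname(ws1$range["mean_spo2"]), 0)
  expect_error(weekly_summary(data.frame(mean_spo2 = numeric()), "day"),
               "undefined")
})

test_that("desaturator classification uses strict thresholds and ignores night order", {
  expect_equal(classify_desaturator(c(45, 60, 35, 50)),
               "consistent_desaturator")
  expect_equal(classify_desaturator(c(10, 31)), "occasional_desaturator")
  expect_equal(classify_desaturator(c(10, 30)), "consistent_nondesaturator")
  expect_equal(classify_desaturator(c(30, 30.0001)), "occasional_desaturator")
  expect_error(classify_desaturator(50), "at least 2")

  set.seed(4)
  for (rep in 1:20) {
    ct <- runif(7, 0, 60)
    expect_equal(classify_desaturator(sample(ct)), classify_desaturator(ct))
  }
})

test_that("two-night assessment flags disagreement with the week category", {
  # nondesaturator over two nights, occasional over the week
  r <- two_night_vs_week_category(c(10, 12, 40, 5, 8))
  expect_true(r$flag)
  expect_equal(r$two_night_category, "nondesaturator")
  expect_true(r$first_two_concordant)

  # all nights above threshold: two-night desaturator, week consistent
  expect_false(two_night_vs_week_category(c(45, 50, 60, 40))$flag)
  # all nights below: consistent nondesaturator
  expect_false(two_night_vs_week_category(c(5, 10, 15))$flag)

  # ordering matters for the two-night view, unlike the week category
  a <- two_night_vs_week_category(c(40, 45, 10))
  b <- two_night_vs_week_category(c(10, 40, 45))
  expect_equal(a$week_category, b$week_category)
  expect_true(a$first_two_concordant)
  expect_false(b$first_two_concordant)
})

test_that("afternoon-evening contrast and day-in-rest range work on labelled bins", {
  day0 <- as.POSIXct("2017-01-05 00:00:00", tz = "UTC")
  bs <- day0 + 23 * 3600
  beds <- data.frame(bed_start = bs, bed_end = bs + 8 * 3600)
  t <- c(day0 + (13 * 3600):(15 * 3600 - 1),
         day0 + (19 * 3600):(21 * 3600 - 1))
  v <- c(rep(93, 7200), rep(92, 7200))  # afternoon 93, evening 92
  x <- spo2_series(t, v)
  seg <- split_day_night(x, beds)[[1]]
  cr <- clean_segment(seg)
  act <- actigraphy_series(day0 + 60 * (0:(24 * 60 - 1)), rep(1.0, 24 * 60),
                           rep(0L, 24 * 60), rep(0L, 24 * 60))
  mask <- partition_by_activity(seg, act)
  labs <- bin_activity_labels(cr$spo2, mask, cr$bins, cr$start)
  win <- clock_windows(seg)
  ae <- afternoon_evening_diff(cr$bins, labs, win)
  expect_true(ae$eligible)
  expect_equal(ae$diff, 1)
  expect_equal(ae$afternoon_mean, 93)

  expect_equal(day_rest_range(cr$bins, labs), 1)

  # identical windows give a zero contrast
  v0 <- rep(94, length(t))
  seg0 <- split_day_night(spo2_series(t, v0), beds)[[1]]
  cr0 <- clean_segment(seg0)
  labs0 <- bin_activity_labels(cr0$spo2, partition_by_activity(seg0, act),
                               cr0$bins, cr0$start)
  expect_equal(afternoon_evening_diff(cr0$bins, labs0,
                                      clock_windows(seg0))$diff, 0)

  # ineligible day: NA and flagged
  short_t <- day0 + (13 * 3600):(14 * 3600 - 1)
  segs <- split_day_night(spo2_series(short_t, rep(94, 3600)), beds)[[1]]
  crs <- clean_segment(segs)
  labss <- bin_activity_labels(crs$spo2, partition_by_activity(segs, act),
                               crs$bins, crs$start)
  aes <- afternoon_evening_diff(crs$bins, labss, clock_windows(segs))
  expect_false(aes$eligible)
  expect_true(is.na(aes$diff))
})
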