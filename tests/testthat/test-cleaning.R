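test_that("small-block exclusion follows the between-errors rule", {
  v <- c(rep(93, 30), 500, rep(88, 5), 500, rep(93, 30))
  out <- exclude_small_blocks(mk_spo2(v))
  expect_equal(sum(out$status == "cleaned_out"), 5)
  expect_equal(which(out$status == "cleaned_out"), 32:36)

  # exactly 20 samples between errors: retained (rule is "less than 20")
  v20 <- c(rep(93, 30), 500, rep(88, 20), 500, rep(93, 30))
  expect_equal(sum(exclude_small_blocks(mk_spo2(v20))$status == "cleaned_out"),
               0)

  # a segment-leading run followed by an error is not "between errors"
  vlead <- c(rep(88, 5), 500, rep(93, 30))
  expect_equal(sum(exclude_small_blocks(mk_spo2(vlead))$status ==
                     "cleaned_out"), 0)

  # a recording gap acts like a segment edge, not an error bound
  t <- c(T0 + 0:4, T0 + 100, T0 + 101:130)
  vg <- spo2_series(t, c(rep(88, 5), 500, rep(93, 30)))
  expect_equal(sum(exclude_small_blocks(vg)$status == "cleaned_out"), 0)
})

test_that("deviating-block exclusion uses the pre-exclusion segment mean and the 6-point rule", {
  ctx <- 93
  mk <- function(block) c(rep(ctx, 200), 500, block, 500, rep(ctx, 200))
  # 50 samples at 85: deviation 8 > 6 -> excluded
  out <- exclude_deviating_blocks(mk_spo2(mk(rep(85, 50))), 93)
  expect_equal(sum(out$status == "cleaned_out"), 50)
  # 50 samples at 90: deviation 3 -> retained
  out <- exclude_deviating_blocks(mk_spo2(mk(rep(90, 50))), 93)
  expect_equal(sum(out$status == "cleaned_out"), 0)
  # deviation exactly 6.0 is not "more than 6": retained
  out <- exclude_deviating_blocks(mk_spo2(mk(rep(87, 50))), 93)
  expect_equal(sum(out$status == "cleaned_out"), 0)
  # 101 samples: beyond the 20..100 window -> retained however deviating
  out <- exclude_deviating_blocks(mk_spo2(mk(rep(80, 101))), 93)
  expect_equal(sum(out$status == "cleaned_out"), 0)
  # 19 samples deviating: not this step's job (length < 20)
  out <- exclude_deviating_blocks(mk_spo2(mk(rep(80, 19))), 93)
  expect_equal(sum(out$status == "cleaned_out"), 0)
  # relative reading of the threshold via config
  cfg_rel <- oxiweek_config(dev_relative = TRUE)
  out <- exclude_deviating_blocks(mk_spo2(mk(rep(87, 50))), 93, cfg_rel)
  expect_equal(sum(out$status == "cleaned_out"), 50)  # 6% of 93 = 5.58 < 6
})

test_that("median down-sampling aligns bins to the segment start and resists outliers", {
  seg <- mk_seg(rep(95, 3600))
  cr <- clean_segment(seg)
  expect_equal(nrow(cr$bins), 180)
  expect_true(all(cr$bins$value == 95))
  expect_true(all(cr$bins$status == "valid"))
  expect_equal(cr$quality$fraction_valid, 1)
  expect_equal(cr$quality$fraction_error, 0)

  # 19 samples at 95 plus one outlier at 70 -> median 95
  cs <- downsample_median(mk_spo2(c(rep(95, 19), 70)), start = T0,
                          end = T0 + 20)
  expect_equal(cs$value, 95)

  # even-count median = mean of the two central values
  cs <- downsample_median(mk_spo2(c(90, 92, 94, 96)), start = T0,
                          end = T0 + 20)
  expect_equal(cs$value, 93)

  # random windows equal a sort-based median oracle
  set.seed(42)
  for (rep in 1:25) {
    v <- sample(80:100, 20, replace = TRUE)
    cs <- downsample_median(mk_spo2(v), start = T0, end = T0 + 20)
    s <- sort(v)
    expect_equal(cs$value, (s[10] + s[11]) / 2)
  }
})

test_that("gap interpolation fills only 1-3 missing bins strictly between valid bins", {
  mk_cs <- function(vals) {
    n <- length(vals)
    v <- rep(NA_real_, n * 20)
    for (i in seq_len(n)) if (!is.na(vals[i])) {
      v[((i - 1) * 20 + 1):(i * 20)] <- vals[i]
    }
    present <- !is.na(v)
    sp <- spo2_series(T0 + which(present) - 1, v[present])
    downsample_median(sp, start = T0, end = T0 + 20 * n)
  }
  # linear midpoint exactness
  cs <- interpolate_gaps(mk_cs(c(94, NA, 96)))
  expect_equal(cs$value[2], 95)
  expect_equal(cs$status[2], "interpolated")
  # three missing bins: filled linearly
  cs <- interpolate_gaps(mk_cs(c(92, NA, NA, NA, 96)))
  expect_equal(cs$value[2:4], c(93, 94, 95))
  # four missing bins: untouched
  cs <- interpolate_gaps(mk_cs(c(92, NA, NA, NA, NA, 96)))
  expect_true(all(cs$status[2:5] == "missing"))
  # a gap touching the segment edge is never filled
  cs <- interpolate_gaps(mk_cs(c(NA, 94, NA)))
  expect_equal(cs$status[c(1, 3)], c("missing", "missing"))
})

test_that("full cleaning equals the brute-force oracle on randomized segments", {
  set.seed(2024)
  for (rep in 1:250) {
    v <- random_segment_values(base = sample(88:96, 1))
    if (all(v == 500)) next
    seg <- mk_seg(v)
    cr <- clean_segment(seg)
    or <- oracle_clean(v)
    expect_identical(cr$spo2$status, or$status)
    expect_equal(cr$bins$value[cr$bins$status != "missing"],
                 or$bin_value[or$bin_status != "missing"])
    expect_identical(cr$bins$status, or$bin_status)
    expect_equal(cr$quality$fraction_error, unname(or$fractions["error"]))
    expect_equal(cr$quality$fraction_cleaned,
                 unname(or$fractions["cleaned"]))
  }
})

test_that("cleaning is conservative, conservative-per-segment and idempotent on clean input", {
  # conservation: every raw sample is exactly one of valid/error/cleaned_out
  set.seed(7)
  v <- random_segment_values()
  cr <- clean_segment(mk_seg(v))
  q <- cr$quality
  expect_equal(q$fraction_error + q$fraction_cleaned + q$fraction_valid, 1,
               tolerance = 1e-12)
  expect_true(all(cr$spo2$status %in% c("raw_valid", "error", "cleaned_out")))

  # an error-free segment is only down-sampled: nothing removed
  v2 <- sample(88:96, 600, replace = TRUE)
  cr2 <- clean_segment(mk_seg(v2))
  expect_equal(cr2$quality$fraction_valid, 1)
  expect_equal(nrow(cr2$audit), 0)

  # per-segment locality: another segment's data never changes this output
  cr_again <- clean_segment(mk_seg(v))
  expect_identical(cr_again$bins$value, cr$bins$value)
})

test_that("quality fractions are plain sample arithmetic and refuse empty scopes", {
  v <- c(rep(95, 85), rep(500, 10), rep(90, 5))
  x <- mk_spo2(v)
  x$status[96:100] <- "cleaned_out"
  q <- quality_fractions(x)
  expect_equal(q$fraction_error, 0.10)
  expect_equal(q$fraction_cleaned, 0.05)
  expect_equal(q$fraction_valid, 0.85)
  expect_error(quality_fractions(x, mask = rep(FALSE, 100)), "empty scope")
})

test_that("decorrelation lag: white noise has none, AR(1) matches theory, constants refuse", {
  set.seed(11)
  wn <- rnorm(20000, 94, 1.5)
  expect_equal(autocorrelation_sampling_time(wn,
                                             max_lag = 50)$decorrelation_lag,
               1)
  phi <- 0.95
  x <- as.numeric(stats::filter(rnorm(50000, 0, sqrt(1 - phi^2)), phi,
                                method = "recursive"))
  lag <- autocorrelation_sampling_time(x, max_lag = 100)$decorrelation_lag
  expect_lt(abs(lag - (-1 / log(phi))) / (-1 / log(phi)), 0.2)
  expect_error(autocorrelation_sampling_time(rep(95, 1000)), "zero variance")

  # gap-aware: works straight off an spo2_series with sentinel errors
  v <- c(rnorm(500, 94, 1.5), rep(500, 20), rnorm(500, 94, 1.5))
  v[v != 500] <- round(pmin(100, pmax(0, v[v != 500])))
  out <- autocorrelation_sampling_time(mk_spo2(v), max_lag = 60)
  expect_true(out$decorrelation_lag >= 1)
})
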