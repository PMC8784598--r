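make_flat_night <- function(activity_fun, night = 1) {
  offset <- 0:959  # 60-s epochs spanning 18:00-10:00
  data.frame(night_date = night, offset = offset,
             activity = activity_fun(offset / 60 + 18))
}

test_that("the optimal window finds a unique activity minimum", {
  # zero activity 23:00-07:00, 1.0 elsewhere: unique 8-h minimum at 23:00
  n <- make_flat_night(function(h) ifelse(h %% 24 >= 23 | h %% 24 < 7, 0, 1))
  w <- optimal_sleep_window(n)
  expect_equal(w$start_clock_h, 23)
  expect_equal(w$pooled_mean, 0)
  # constant activity: every candidate ties, earliest start wins
  flat <- make_flat_night(function(h) rep(1, length(h)))
  expect_equal(optimal_sleep_window(flat)$start_clock_h, 18)
})

test_that("window search equals exhaustive enumeration on noisy nights", {
  nights <- make_synthetic_nights(20, sleep_start_h = 24, sleep_dur_h = 8,
                                  seed = 301)
  w <- optimal_sleep_window(nights)
  o <- oracle_window_scan(nights)
  expect_equal(w$start_offset_min, o$start_offset_min)
  expect_equal(w$pooled_mean, o$pooled_mean, tolerance = 1e-12)
  expect_equal(w$start_clock_h, 24 %% 24)  # 00:00
  # optimality invariant: no candidate beats the selected window
  expect_true(all(w$candidate_means >= w$pooled_mean - 1e-12))
})

test_that("insufficient coverage is rejected or yields missing nights", {
  thin <- make_flat_night(function(h) rep(1, length(h)))[1:300, ]  # 31% coverage
  expect_error(optimal_sleep_window(thin), "insufficient accelerometer data")
  expect_true(is.na(nightly_sleep_duration(thin, 0)))
})

test_that("nightly duration respects the degenerate threshold conventions", {
  # in-window zeros, out-of-window ones: saturated 8-h sleep
  sat <- make_flat_night(function(h) ifelse(h %% 24 >= 23 | h %% 24 < 7, 0, 1))
  base <- optimal_sleep_window(sat)$start_offset_min
  expect_equal(nightly_sleep_duration(sat, base), 8)
  # constant positive activity: nothing strictly below the threshold
  flat <- make_flat_night(function(h) rep(1.7, length(h)))
  expect_equal(nightly_sleep_duration(flat, 0), 0)
})

test_that("nightly durations recover known sleep lengths within half an hour", {
  for (dur in c(5, 6.5, 7.5)) {
    nights <- make_synthetic_nights(10, sleep_start_h = 23.5, sleep_dur_h = dur,
                                    seed = 310 + dur * 10)
    base <- optimal_sleep_window(nights)$start_offset_min
    per <- split(nights, nights$night_date)
    est <- vapply(per, nightly_sleep_duration, numeric(1),
                  base_start_offset_min = base)
    expect_lt(abs(mean(est) - dur), 0.5)
    expect_true(all(est >= 0 & est <= 8))
  }
})

test_that("epoch aggregation averages raw records and splits nights by date", {
  d0 <- as.numeric(as.Date("2021-02-03")) * 86400000
  raw <- data.frame(ts = d0 + c(0, 20000, 40000, 60000, 80000),
                    activity = c(1, 2, 3, 10, 20))
  ep <- accel_epochs(raw)
  expect_equal(ep$activity, c(2, 15))  # two 60-s epochs
  # overnight epochs attribute evening to the next date, morning to its own
  cfg <- sleep_config()
  ev <- data.frame(epoch_local_ms = d0 + c(19, 23, 9, 11) * 3.6e6,
                   activity = 1)
  nt <- phenocap:::night_epochs(ev, cfg)
  expect_equal(nt$night_date, as.numeric(as.Date("2021-02-03")) + c(1, 1, 0))
})

test_that("cohort-level sleep estimates track the generated truth", {
  cfg <- small_cohort_config(seed = 33, n = 3)
  cohort <- generate_cohort(cfg)
  for (i in 1:3) {
    p <- cohort$roster[i, ]
    st <- generate_participant_streams(p, cfg)
    ep <- accel_epochs(st$accel, tz_offset_min = p$tz_offset_min)
    sl <- sleep_durations(ep)
    truth <- (st$truth$sleep$end_ts - st$truth$sleep$start_ts) / 3.6e6
    expect_equal(nrow(sl), length(truth))
    expect_lt(abs(mean(sl$sleep_duration_h) - mean(truth)), 0.5)
  }
})
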