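test_that("stream generation is deterministic under a fixed seed", {
  cfg <- small_cohort_config(seed = 21, n = 2)
  cohort <- generate_cohort(cfg)
  a <- generate_participant_streams(cohort$roster[1, ], cfg)
  b <- generate_participant_streams(cohort$roster[1, ], cfg)
  expect_identical(a, b)
  # a one-day slice equals the corresponding slice of the full run
  day <- cfg$cohort$start_date + 4
  slice <- generate_sensor_streams(cohort$roster[1, ], cfg, day)
  tz <- cohort$roster$tz_offset_min[1]
  full_day <- a$gps[floor((a$gps$ts + tz * 60000) / 86400000) ==
                      as.numeric(day), ]
  expect_equal(slice$gps$ts, full_day$ts)
  expect_equal(slice$truth$sleep, a$truth$sleep[a$truth$sleep$date == day, ],
               ignore_attr = TRUE)
})

test_that("degenerate mobility and screen settings produce degenerate streams", {
  cfg <- small_cohort_config(seed = 22, n = 2)
  cohort <- generate_cohort(cfg)
  p <- cohort$roster[1, ]
  p$true_home_fraction <- 1
  p$true_daily_screen_h <- 0
  st <- generate_participant_streams(p, cfg, dates = cfg$cohort$start_date + 0:2)
  d <- haversine_m(st$gps$lat, st$gps$lon, p$home_lat, p$home_lon)
  expect_lt(max(d), 6 * cfg$sensors$gps_noise_m)  # all fixes near home
  expect_equal(nrow(st$screen), 0)                # no screen events
  expect_equal(nrow(st$truth$screen_bouts), 0)
})

test_that("accelerometer activity is lower inside the true sleep interval", {
  cfg <- small_cohort_config(seed = 23, n = 2)
  cohort <- generate_cohort(cfg)
  p <- cohort$roster[1, ]
  p$true_sleep_onset_h <- 24  # 00:00
  p$true_sleep_duration_h <- 7
  st <- generate_participant_streams(p, cfg)
  sl <- st$truth$sleep
  inside <- rep(FALSE, nrow(st$accel))
  for (i in seq_len(nrow(sl))) {
    inside <- inside | (st$accel$ts >= sl$start_ts[i] &
                          st$accel$ts < sl$end_ts[i])
  }
  expect_lt(mean(st$accel$activity[inside]),
            mean(st$accel$activity[!inside]))
  expect_true(all(st$accel$activity >= 0))
})

test_that("true screen bouts realize the configured daily screen hours", {
  cfg <- small_cohort_config(seed = 24, n = 3)
  cohort <- generate_cohort(cfg)
  for (i in 1:3) {
    p <- cohort$roster[i, ]
    st <- generate_participant_streams(p, cfg,
                                       dates = cfg$cohort$start_date + 0:6)
    per_day <- tapply((st$truth$screen_bouts$end_ts -
                         st$truth$screen_bouts$start_ts) / 3.6e6,
                      as.character(st$truth$screen_bouts$date), sum)
    expect_equal(as.numeric(per_day), rep(p$true_daily_screen_h, 7),
                 tolerance = 1e-4)  # ms rounding of event times
    # bouts are non-overlapping and ordered
    b <- st$truth$screen_bouts[st$truth$screen_bouts$date ==
                                 cfg$cohort$start_date, ]
    expect_true(all(b$end_ts[-nrow(b)] <= b$start_ts[-1]))
  }
})

test_that("ground-truth intervals stay within the study period", {
  cfg <- small_cohort_config(seed = 25, n = 2)
  cohort <- generate_cohort(cfg)
  st <- generate_participant_streams(cohort$roster[1, ], cfg)
  expect_true(all(st$truth$sleep$end_ts > st$truth$sleep$start_ts))
  expect_true(all(st$truth$home$end_ts > st$truth$home$start_ts))
  # nightly sleep lies in the overnight interval attributed to its date
  tz <- cohort$roster$tz_offset_min[1]
  d <- as.numeric(st$truth$sleep$date)
  start_loc <- st$truth$sleep$start_ts + tz * 60000
  end_loc <- st$truth$sleep$end_ts + tz * 60000
  expect_true(all(start_loc >= (d - 1) * 86400000 + 18 * 3.6e6))
  expect_true(all(end_loc <= d * 86400000 + 10 * 3.6e6))
})

test_that("sensor JSON-lines round-trip preserves the streams", {
  cfg <- small_cohort_config(seed = 26, n = 2)
  cohort <- generate_cohort(cfg)
  st <- generate_participant_streams(cohort$roster[1, ], cfg,
                                     dates = cfg$cohort$start_date + 0:1)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_sensor_jsonl(st, path)
  back <- read_sensor_jsonl(path)
  expect_equal(back$gps$ts, st$gps$ts)
  expect_equal(back$gps$lat, st$gps$lat, tolerance = 1e-7)
  expect_equal(back$accel$activity, st$accel$activity, tolerance = 1e-5)
  expect_equal(back$screen$state, st$screen$state)
  line1 <- readLines(path, n = 1)
  expect_true(jsonlite::validate(line1))
})

test_that("item sampler hits its configured mean exactly and in simulation", {
  s <- item_sampler(0.5, 0.99, 0, 3)
  expect_equal(sum(s$values * s$probs), 0.5, tolerance = 1e-9)
  set.seed(1)
  draws <- sample_item(s, 10000)
  se <- s$sd_analytic / sqrt(10000)
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
  expect_lt(abs(sd(draws) - s$sd_analytic), 4 * se)
  # zero dispersion gives a point mass
  expect_equal(unique(sample_item(item_sampler(0, 0, 0, 3), 100)), 0)
  expect_equal(unique(sample_item(item_sampler(2, 0, 0, 3), 100)), 2)
})

test_that("survey responses are on-scale, scheduled, and group-calibrated", {
  cfg <- small_cohort_config(seed = 27, n = 60, p_exposed = 0.5)
  cohort <- generate_cohort(cfg)
  sv <- generate_cohort_surveys(cohort)
  expect_identical(sv, {set.seed(0); generate_cohort_surveys(cohort)})
  expect_equal(length(unique(sv$ts)), 3)  # enrollment + 2 biweekly
  for (id in unique(sv$instrument_id)) {
    spec <- instrument_registry(id)
    r <- sv$response[sv$instrument_id == id]
    expect_true(all(r >= spec$scale_min & r <= spec$scale_max))
  }
  # an exposure-elevated item separates the groups in the right direction
  ex <- split_groups(cohort$roster)
  reality <- sv[sv$instrument_id == "PQ16" & sv$item_index == 5, ]
  m_ex <- mean(reality$response[reality$participant_id %in% ex$exposed])
  m_un <- mean(reality$response[reality$participant_id %in% ex$unexposed])
  expect_gt(m_ex, m_un)
})
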