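test_that("significant locations handle empty and degenerate inputs", {
  empty <- significant_locations(data.frame(ts = numeric(0),
                                            lat = numeric(0),
                                            lon = numeric(0)))
  expect_equal(nrow(empty), 0)
  same <- data.frame(ts = 1:100 * 1000, lat = rep(42.3, 100),
                     lon = rep(-71.1, 100))
  cl <- significant_locations(same, eps_m = 100)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$weight, 1.0)
  expect_equal(cl$lat, 42.3)
  expect_equal(cl$lon, -71.1)
})

test_that("two separated fix clouds yield weighted clusters at their centroids", {
  a <- make_fix_cloud(80, 42.30, -71.10, 30, t0 = 0)
  b <- make_fix_cloud(20, 42.309, -71.10, 30, t0 = 80 * 60000)  # ~1 km north
  fixes <- rbind(a, b)
  cl <- significant_locations(fixes, eps_m = 100)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$weight, c(0.80, 0.20))
  expect_equal(sum(cl$weight), 1)
  # centroids equal the assigned-fix means, cross-checked with geosphere
  expect_equal(cl$lat[1], mean(a$lat), tolerance = 1e-9)
  expect_equal(cl$lon[2], mean(b$lon), tolerance = 1e-9)
  skip_if_not_installed("geosphere")
  d <- geosphere::distHaversine(c(cl$lon[1], cl$lat[1]),
                                c(cl$lon[2], cl$lat[2]), r = 6371008.8)
  expect_gt(d, 900); expect_lt(d, 1100)
  # the package's haversine agrees with geosphere's (same mean radius)
  expect_equal(haversine_m(cl$lat[1], cl$lon[1], cl$lat[2], cl$lon[2]),
               d, tolerance = 1e-4)
})

test_that("light clusters are dropped but keep their mass in the weights", {
  a <- make_fix_cloud(95, 42.30, -71.10, 20, t0 = 0)
  b <- make_fix_cloud(5, 42.35, -71.10, 20, t0 = 95 * 60000)
  cl <- significant_locations(rbind(a, b), eps_m = 100, min_weight = 0.10)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$weight, 0.95)   # not renormalized to 1
  expect_equal(length(attr(cl, "assignment")), 100)
})

test_that("home is the cluster holding the overnight fixes", {
  # cluster A: few overnight fixes; cluster B: many daytime fixes
  night_t0 <- as.numeric(as.Date("2021-02-01")) * 86400000 + 1 * 3.6e6
  day_t0 <- as.numeric(as.Date("2021-02-01")) * 86400000 + 12 * 3.6e6
  a <- make_fix_cloud(10, 42.30, -71.10, 20, t0 = night_t0)
  b <- make_fix_cloud(50, 42.35, -71.10, 20, t0 = day_t0)
  fixes <- rbind(a, b)
  cl <- label_home(significant_locations(fixes, eps_m = 100), fixes)
  expect_equal(sum(cl$is_home), 1)
  expect_true(cl$is_home[cl$n_fixes == 10])
  # single cluster is home
  cl1 <- label_home(significant_locations(a, eps_m = 100), a)
  expect_true(cl1$is_home)
  # no overnight fixes: highest-weight fallback, flagged
  cl2 <- label_home(significant_locations(b, eps_m = 100), b)
  expect_true(cl2$is_home[which.max(cl2$weight)])
  expect_equal(attr(cl2, "quality"), "no_overnight_fixes")
  # overnight tie goes to the earlier-formed cluster
  c1 <- make_fix_cloud(5, 42.30, -71.10, 10, t0 = night_t0)
  c2 <- make_fix_cloud(5, 42.35, -71.10, 10, t0 = night_t0 + 5 * 60000)
  tie <- rbind(c1, c2)
  clt <- label_home(significant_locations(tie, eps_m = 100), tie)
  expect_equal(which(clt$is_home), 1L)
})

test_that("home time integrates covered home intervals per day", {
  d0 <- as.numeric(as.Date("2021-02-01")) * 86400000
  # full-day 1-min cadence at one location
  home <- make_fix_cloud(1440, 42.30, -71.10, 10, t0 = d0, cadence_s = 60)
  cl <- label_home(significant_locations(home, eps_m = 100), home)
  ht <- home_time(home, cl)
  expect_equal(ht$home_time_h, 24 - 1 / 60, tolerance = 1e-9)
  # away fixes contribute zero home time
  away <- make_fix_cloud(600, 42.40, -71.10, 10, t0 = d0 + 8 * 3.6e6,
                         cadence_s = 60)
  both <- rbind(home[1:400, ], away)
  cl2 <- label_home(significant_locations(both, eps_m = 100), both)
  ht2 <- home_time(both, cl2)
  expect_equal(ht2$home_time_h, 399 / 60, tolerance = 1e-9)
  # gaps larger than gap_max do not accrue
  sparse <- home[seq(1, 1440, by = 20), ]  # 20-min gaps
  cl3 <- label_home(significant_locations(sparse, eps_m = 100), sparse)
  expect_equal(home_time(sparse, cl3, gap_max_s = 600)$home_time_h, 0)
})

test_that("synthetic-day home time recovers the generator's truth", {
  cfg <- small_cohort_config(seed = 31, n = 2)
  cohort <- generate_cohort(cfg)
  p <- cohort$roster[1, ]
  p$true_home_fraction <- 16 / 24
  st <- generate_participant_streams(p, cfg, dates = cfg$cohort$start_date)
  tz <- p$tz_offset_min
  cl <- label_home(significant_locations(st$gps, eps_m = 100), st$gps,
                   tz_offset_min = tz)
  ht <- home_time(st$gps, cl, tz_offset_min = tz)
  gap_h <- 2 * cfg$features$gap_max_s / 3600
  expect_lt(abs(ht$home_time_h - 16), gap_h + 2 * cfg$sensors$gps_cadence_s / 3600)
})

test_that("cluster weights conserve mass and features are label-invariant", {
  set.seed(7)
  cfg <- small_cohort_config(seed = 32, n = 2)
  cohort <- generate_cohort(cfg)
  st <- generate_participant_streams(cohort$roster[1, ], cfg,
                                     dates = cfg$cohort$start_date + 0:3)
  cl <- significant_locations(st$gps, eps_m = 100, min_weight = 0)
  expect_equal(sum(cl$weight), 1, tolerance = 1e-9)
  tz <- cohort$roster$tz_offset_min[1]
  cl <- label_home(cl, st$gps, tz_offset_min = tz)
  ht <- home_time(st$gps, cl, tz_offset_min = tz)
  # shifting every timestamp by whole days shifts dates, not values
  shifted <- st$gps
  shifted$ts <- shifted$ts + 7 * 86400000
  cls <- label_home(significant_locations(shifted, eps_m = 100), shifted,
                    tz_offset_min = tz)
  hts <- home_time(shifted, cls, tz_offset_min = tz)
  expect_equal(hts$home_time_h, ht$home_time_h)
  expect_equal(as.numeric(hts$date - ht$date), rep(7, nrow(ht)))
})
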