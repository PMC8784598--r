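test_that("exposure answers split into the published grouping", {
  roster <- data.frame(participant_id = c("p1", "p2", "p3", "p4"),
                       exposure_answer = c("Yes", "No",
                                           "Unsure, but I think so", NA))
  g <- split_groups(roster)
  expect_equal(g$exposed, c("p1", "p3"))
  expect_equal(g$unexposed, "p2")
  expect_equal(g$excluded, "p4")
  roster$exposure_answer[1] <- "maybe"
  expect_error(split_groups(roster), "unknown exposure answer")
  # an empty group makes comparison impossible
  allno <- data.frame(participant_id = c("a", "b"),
                      exposure_answer = c("No", "No"))
  expect_error(compare_all(NULL, NULL, NULL, split_groups(allno)),
               "non-empty")
})

test_that("one-sided p follows the upper-tail convention of the published table", {
  expect_equal(one_sided_p(0, 10), 0.5)
  expect_equal(round(one_sided_p(1.17, 380), 2), 0.12)
  expect_equal(round(one_sided_p(-0.77, 380), 2), 0.78)
  expect_lt(one_sided_p(2.34, 380), 0.05)
  # monotone decreasing in t
  ts <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(one_sided_p(ts, 50)) < 0))
  expect_error(one_sided_p(1, 0), "df")
})

test_that("pooled t from summaries equals the from-scratch sample computation", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(5:60, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:60, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got <- pooled_t(group_summary(x), group_summary(y))
    want <- oracle_two_pass_t(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$ci_lower, want$ci_lower, tolerance = 1e-12)
    expect_equal(got$df, want$df)
    # and agrees with the standard library's equal-variance test
    tt <- t.test(x, y, var.equal = TRUE, alternative = "greater")
    expect_equal(got$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(got$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("pooled t has the textbook symmetries and edge cases", {
  s1 <- list(n = 20, mean = 1.2, sd = 0.8)
  s2 <- list(n = 30, mean = 0.9, sd = 1.1)
  a <- pooled_t(s1, s2)
  b <- pooled_t(s2, s1)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, 1 - b$p, tolerance = 1e-12)
  # scale equivariance: multiplying scores by c > 0 leaves t, df, p unchanged
  s1c <- list(n = 20, mean = 1.2 * 5, sd = 0.8 * 5)
  s2c <- list(n = 30, mean = 0.9 * 5, sd = 1.1 * 5)
  ac <- pooled_t(s1c, s2c)
  expect_equal(ac$t, a$t, tolerance = 1e-12)
  expect_equal(ac$p, a$p, tolerance = 1e-12)
  # identical summaries: t = 0, p = 0.5
  same <- pooled_t(s1, s1)
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  # zero pooled variance with nonzero difference: signed infinity
  z1 <- list(n = 5, mean = 2, sd = 0)
  z2 <- list(n = 5, mean = 1, sd = 0)
  expect_warning(inf <- pooled_t(z1, z2), "zero pooled variance")
  expect_equal(inf$t, Inf)
  expect_equal(inf$p, 0)
})

test_that("published rows reconstruct from printed means and t statistics", {
  ref <- reference_item_table()
  q <- qt(0.95, 380)
  for (code in c("Sounds", "Meaning")) {
    row <- ref[ref$item_code == code, ]
    diff <- row$mean_exposed - row$mean_unexposed
    se <- diff / row$t
    expect_equal(round(diff - q * se, 2), row$ci_lower)
    expect_equal(round(diff + q * se, 2), row$ci_upper)
  }
  # the implied group split reproduces the printed Meaning t from its SDs
  row <- ref[ref$item_code == "Meaning", ]
  tt <- pooled_t(list(n = 54, mean = row$mean_exposed, sd = row$sd_exposed),
                 list(n = 328, mean = row$mean_unexposed, sd = row$sd_unexposed))
  expect_equal(round(tt$t, 1), round(row$t, 1))
  expect_equal(tt$df, 380)
})

test_that("gender summaries round to integer percentages", {
  r <- data.frame(gender = rep(c("female", "male", "other"), c(237, 133, 11)))
  cs <- cohort_summary(r)
  expect_equal(cs$pct[match(c("female", "male", "other"), cs$gender)],
               c(62L, 35L, 3L))
  expect_equal(cohort_summary(data.frame(gender = "female"))$pct, 100L)
  thirds <- data.frame(gender = rep(c("female", "male", "other"), each = 100))
  expect_equal(cohort_summary(thirds)$pct, rep(33L, 3))
})

test_that("comparison rows star the published effect sizes with high power", {
  hits_reality <- 0; hits_seeing <- 0
  n_reps <- 100
  for (r in seq_len(n_reps)) {
    cmp <- simulate_comparison_replicate(54, 328, seed = 6000 + r)
    hits_reality <- hits_reality +
      (cmp$marker[cmp$variable == "PQ16: Reality"] != "")
    hits_seeing <- hits_seeing +
      (cmp$marker[cmp$variable == "PQ16: Seeing things"] != "")
  }
  expect_gte(hits_reality / n_reps, 0.8)
  expect_gte(hits_seeing / n_reps, 0.8)
})

test_that("null cohorts star at close to the nominal rate", {
  # smaller companion to the full calibration run: 60 replicates
  res <- null_star_rate(n_reps = 60, n_exposed = 100, n_unexposed = 100,
                        seed = 17)
  expect_lt(abs(res$star_rate - 0.05), 0.03)
})

test_that("null intervals exclude zero at the rate of a 90%-width interval", {
  set.seed(55)
  excl <- 0
  for (r in 1:400) {
    x <- rnorm(20); y <- rnorm(20)
    tt <- pooled_t(group_summary(x), group_summary(y))
    excl <- excl + (tt$ci_lower > 0 || tt$ci_upper < 0)
  }
  expect_lt(abs(excl / 400 - 0.10), 0.05)
})

test_that("sparse groups yield missing statistics, and BH stars never exceed raw", {
  pm <- data.frame(participant_id = c("a", "b", "c"),
                   instrument_id = "PHQ9",
                   mean_normalized = c(0.1, 0.2, 0.3))
  groups <- list(exposed = c("a"), unexposed = c("b", "c"))
  expect_warning(cmp <- compare_all(pm, NULL, NULL, groups),
                 "fewer than 2")
  expect_true(is.na(cmp$t))
  expect_equal(cmp$n_exposed, 1)

  cmp2 <- simulate_comparison_replicate(40, 40, seed = 9,
                                        config = pipeline_config(
                                          seed = 9,
                                          inference = inference_config(fdr = TRUE)))
  cmp3 <- simulate_comparison_replicate(40, 40, seed = 9)
  expect_lte(sum(cmp2$marker != ""), sum(cmp3$marker != ""))
})
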