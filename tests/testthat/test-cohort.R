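test_that("exact attrition reproduces the recruitment funnel counts", {
  cfg <- pipeline_config(seed = 1)
  cohort <- generate_cohort(cfg)
  expect_equal(unname(cohort$funnel),
               c(695L, 612L, 507L, 382L))
  expect_equal(names(cohort$funnel),
               c("recruited", "used_app", "completed_surveys",
                 "answered_exposure"))
})

test_that("no attrition keeps every recruited participant in the analysis set", {
  cfg <- small_cohort_config(seed = 3, n = 25)
  cohort <- generate_cohort(cfg)
  expect_true(all(cohort$roster$in_analysis))
  expect_equal(unname(cohort$funnel), rep(25L, 4))
})

test_that("rosters are identical under a fixed seed and config", {
  cfg <- pipeline_config(seed = 99, cohort = cohort_config(n_recruited = 80))
  expect_identical(generate_cohort(cfg)$roster, generate_cohort(cfg)$roster)
  # and differ under another seed
  cfg2 <- pipeline_config(seed = 100, cohort = cohort_config(n_recruited = 80))
  expect_false(identical(generate_cohort(cfg)$roster,
                         generate_cohort(cfg2)$roster))
})

test_that("funnel stage counts are non-increasing under bernoulli thinning", {
  for (s in 1:5) {
    cfg <- pipeline_config(seed = s,
                           cohort = cohort_config(n_recruited = 200,
                                                  attrition = "bernoulli"))
    f <- generate_cohort(cfg)$funnel
    expect_true(all(diff(f) <= 0))
  }
})

test_that("eligibility gate keeps PSS >= threshold, preserving order", {
  roster <- data.frame(participant_id = c("a", "b", "c", "d"),
                       enrollment_pss = c(14, 13, 40, 20))
  kept <- apply_eligibility(roster, 14)
  expect_equal(kept$participant_id, c("a", "c", "d"))
  expect_equal(apply_eligibility(roster, 0)$participant_id,
               roster$participant_id)
  roster$enrollment_pss[2] <- NA
  expect_error(apply_eligibility(roster, 14), "missing enrollment PSS.*b")
})

test_that("screened cohorts satisfy the stress gate by construction", {
  cfg <- pipeline_config(seed = 4, cohort = cohort_config(n_recruited = 300))
  cohort <- generate_cohort(cfg)
  expect_true(all(cohort$roster$enrollment_pss >= 14))
  expect_true(all(cohort$roster$enrollment_pss <= 40))
  # unscreened draws can fall below the gate
  cfg2 <- pipeline_config(seed = 4,
                          cohort = cohort_config(n_recruited = 300,
                                                 pss_screened = FALSE))
  expect_true(any(generate_cohort(cfg2)$roster$enrollment_pss < 14))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(p_app_usage = 1.2), "probabilities")
  expect_error(cohort_config(p_exposed_or_unsure = -0.1), "probabilities")
  expect_error(cohort_config(gender_probs = c(0.5, 0.5, 0.5)), "gender_probs")
  expect_error(cohort_config(n_recruited = 0), "n_recruited")
  expect_error(pipeline_config(), "seed")
})

test_that("exposure answers map onto latent groups and stay auditable", {
  cfg <- small_cohort_config(seed = 10, n = 400, p_exposed = 0.3)
  r <- generate_cohort(cfg)$roster
  expect_true(all(r$exposure_answer %in%
                    c("Yes", "No", "Unsure, but I think so")))
  expect_equal(r$exposure_group == "exposed",
               r$exposure_answer != "No")
  expect_equal(r$exposure_group == "exposed", r$latent_exposed)
  # behavioral ground truth reflects the configured sleep deficit
  gap <- mean(r$true_sleep_duration_h[!r$latent_exposed]) -
    mean(r$true_sleep_duration_h[r$latent_exposed])
  expect_gt(gap, 0.2)
  expect_true(all(r$true_sleep_duration_h >= 3 &
                    r$true_sleep_duration_h <= 7.9))
})
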