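#' Generate a synthetic cohort with ground-truth behavior
#'
#' Draws a seeded roster of recruited students through the attrition funnel
#' (recruitment, app usage, biweekly-survey completion, exposure-question
#' response), assigns exposure answers, gender and enrollment PSS, and
#' draws each participant's true behavioral parameters (sleep onset and
#' duration, daily screen time, home fraction, home/away coordinates) from
#' the configured group distributions. Participants who never answered the
#' exposure question still receive a latent exposure group so their sensor
#' behavior is drawn from the same mixture.
#'
#' @param config a [pipeline_config()].
#' @return object of class `phenocap_cohort`: list with `roster`
#'   (data.frame, one row per recruited participant), `config`, and
#'   `funnel` (named stage counts).
#' @export
#' @examples
#' cohort <- generate_cohort(pipeline_config(seed = 1))
#' cohort$funnel
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phenocap_config"))
  cc <- config$cohort
  bb <- config$behavior
  set.seed(config$seed)

  n <- cc$n_recruited
  ids <- sprintf("P%05d", seq_len(n))

  used_app <- draw_stage(rep(TRUE, n), cc$p_app_usage, cc$attrition)
  completed_surveys <- draw_stage(used_app, cc$p_survey_completion, cc$attrition)
  answered_exposure <- draw_stage(completed_surveys, cc$p_exposure_answered,
                                  cc$attrition)

  latent_exposed <- runif(n) < cc$p_exposed_or_unsure
  unsure <- runif(n) < cc$p_unsure_given_exposed
  exposure_answer <- rep(NA_character_, n)
  exposure_answer[answered_exposure & !latent_exposed] <- "No"
  exposure_answer[answered_exposure & latent_exposed] <-
    ifelse(unsure[answered_exposure & latent_exposed],
           "Unsure, but I think so", "Yes")
  exposure_group <- rep(NA_character_, n)
  exposure_group[answered_exposure] <-
    ifelse(latent_exposed[answered_exposure], "exposed", "unexposed")

  gender <- sample(names(cc$gender_probs), n, replace = TRUE,
                   prob = cc$gender_probs)

  if (cc$pss_screened) {
    plo <- pnorm(cc$pss_threshold - 0.5, cc$pss_mean, cc$pss_sd)
    pss <- round(qnorm(runif(n, plo, 1), cc$pss_mean, cc$pss_sd))
    pss <- as.integer(clip(pss, cc$pss_threshold, 40))
  } else {
    pss <- as.integer(clip(round(rnorm(n, cc$pss_mean, cc$pss_sd)), 0, 40))
  }

  sleep_mean <- ifelse(latent_exposed,
                       bb$sleep_mean_h - bb$sleep_deficit_h, bb$sleep_mean_h)
  true_sleep_duration_h <- rtruncnorm(n, sleep_mean, bb$sleep_sd_h,
                                      bb$sleep_range_h[1], bb$sleep_range_h[2])
  true_sleep_onset_h <- clip(rnorm(n, bb$sleep_onset_mean_h,
                                   bb$sleep_onset_sd_h), 21, 26)
  true_daily_screen_h <- rtruncnorm(n, bb$screen_mean_h, bb$screen_sd_h,
                                    bb$screen_range_h[1], bb$screen_range_h[2])
  true_home_fraction <- rtruncnorm(n, bb$home_fraction_mean,
                                   bb$home_fraction_sd,
                                   bb$home_fraction_range[1],
                                   bb$home_fraction_range[2])

  scatter <- function(n, center, radius_km) {
    ang <- runif(n, 0, 2 * pi)
    r <- radius_km * sqrt(runif(n))
    data.frame(lat = center[["lat"]] + r * sin(ang) / 111.32,
               lon = center[["lon"]] + r * cos(ang) /
                 (111.32 * cos(center[["lat"]] * pi / 180)))
  }
  home <- scatter(n, bb$campus, bb$home_scatter_km)
  away1 <- scatter(n, bb$campus, bb$away_scatter_km)
  away2 <- scatter(n, bb$campus, bb$away_scatter_km)

  roster <- data.frame(
    participant_id = ids,
    used_app = used_app,
    completed_surveys = completed_surveys,
    answered_exposure = answered_exposure,
    exposure_answer = exposure_answer,
    exposure_group = exposure_group,
    latent_exposed = latent_exposed,
    gender = gender,
    enrollment_pss = pss,
    tz_offset_min = cc$tz_offset_min,
    home_lat = home$lat, home_lon = home$lon,
    away1_lat = away1$lat, away1_lon = away1$lon,
    away2_lat = away2$lat, away2_lon = away2$lon,
    true_sleep_onset_h = true_sleep_onset_h,
    true_sleep_duration_h = true_sleep_duration_h,
    true_daily_screen_h = true_daily_screen_h,
    true_home_fraction = true_home_fraction,
    stringsAsFactors = FALSE
  )
  roster$in_analysis <- roster$used_app & roster$completed_surveys &
    roster$answered_exposure

  structure(list(roster = roster, config = config,
                 funnel = funnel_counts(roster)),
            class = "phenocap_cohort")
}

# Thin the survivors of the previous stage. "exact" keeps round(n_prev * p)
# participants (a seeded random subset); "bernoulli" flips one coin each.
draw_stage <- function(prev, p, mode) {
  out <- rep(FALSE, length(prev))
  idx <- which(prev)
  if (!length(idx)) return(out)
  if (mode == "exact") {
    k <- round(length(idx) * p)
    out[sample(idx, k)] <- TRUE
  } else {
    out[idx] <- runif(length(idx)) < p
  }
  out
}

#' Recruitment-funnel stage counts
#'
#' @param roster roster data.frame from [generate_cohort()].
#' @return named integer vector: recruited, used_app, completed_surveys,
#'   answered_exposure.
#' @export
funnel_counts <- function(roster) {
  c(recruited = nrow(roster),
    used_app = sum(roster$used_app),
    completed_surveys = sum(roster$used_app & roster$completed_surveys),
    answered_exposure = sum(roster$used_app & roster$completed_surveys &
                              roster$answered_exposure))
}

#' Apply the perceived-stress eligibility gate
#'
#' Retains exactly the participants whose enrollment PSS meets the
#' threshold, preserving roster order.
#'
#' @param roster roster data.frame with an `enrollment_pss` column.
#' @param threshold eligibility threshold (default 14, at least moderate
#'   stress).
#' @return filtered roster.
#' @export
apply_eligibility <- function(roster, threshold = 14) {
  if (!"enrollment_pss" %in% names(roster)) {
    stop("apply_eligibility: roster lacks enrollment_pss")
  }
  missing_pss <- is.na(roster$enrollment_pss)
  if (any(missing_pss)) {
    stop("apply_eligibility: missing enrollment PSS for participant(s) ",
         paste(roster$participant_id[missing_pss], collapse = ", "))
  }
  roster[roster$enrollment_pss >= threshold, , drop = FALSE]
}

#' @export
print.phenocap_cohort <- function(x, ...) {
  cat("<phenocap_cohort>\n")
  cat("  funnel:", paste(names(x$funnel), x$funnel, sep = "=",
                         collapse = " -> "), "\n")
  grp <- table(x$roster$exposure_group[x$roster$in_analysis])
  cat("  analysis set:", sum(x$roster$in_analysis),
      sprintf("(exposed %d, unexposed %d)",
              grp["exposed"], grp["unexposed"]), "\n")
  invisible(x)
}

#' Analysis-set roster
#'
#' Participants who used the app, completed the biweekly surveys, and
#' answered the exposure question.
#'
#' @param cohort a `phenocap_cohort` or roster data.frame.
#' @return roster subset.
#' @export
analysis_roster <- function(cohort) {
  roster <- if (inherits(cohort, "phenocap_cohort")) cohort$roster else cohort
  roster[roster$in_analysis, , drop = FALSE]
}
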