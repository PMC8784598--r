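#' Generate survey responses for a whole cohort
#'
#' Draws item-level responses for every participant who completed the
#' biweekly surveys, at each scheduled administration, from the configured
#' item effect table: each item uses a discretized truncated-normal sampler
#' calibrated so its expectation equals the participant's group mean for
#' that item (see [item_sampler()]). Participants whose exposure answer is
#' missing draw from their latent exposure group, so cohort-level behavior
#' is one mixture.
#'
#' @param cohort a `phenocap_cohort`.
#' @param schedule_days administration days relative to the study start;
#'   defaults to the configured schedule (enrollment + two biweekly).
#' @return long data.frame: `participant_id`, `instrument_id`, `ts`,
#'   `item_index`, `response`.
#' @export
generate_cohort_surveys <- function(cohort, schedule_days = NULL) {
  config <- cohort$config
  schedule_days <- schedule_days %||% config$survey_schedule_days
  roster <- cohort$roster
  takers <- roster[roster$used_app & roster$completed_surveys, , drop = FALSE]
  set.seed(sub_seed(config$seed, 0L, 2L))
  draw_survey_block(takers, config, schedule_days)
}

#' Generate survey responses for one participant
#'
#' @param profile one roster row.
#' @param config the cohort's `phenocap_config`.
#' @param schedule_days administration days relative to the study start.
#' @param seed RNG seed; defaults to a participant-specific lane.
#' @return long data.frame as in [generate_cohort_surveys()].
#' @export
generate_survey_responses <- function(profile, config, schedule_days = NULL,
                                      seed = NULL) {
  stopifnot(nrow(profile) == 1)
  schedule_days <- schedule_days %||% config$survey_schedule_days
  set.seed(seed %||% sub_seed(config$seed,
                              participant_index(profile$participant_id), 3L))
  draw_survey_block(profile, config, schedule_days)
}

draw_survey_block <- function(takers, config, schedule_days) {
  effects <- config$item_effects
  for (id in unique(effects$instrument_id)) instrument_registry(id)
  n_p <- nrow(takers)
  n_adm <- length(schedule_days)
  if (!n_p || !n_adm) {
    return(data.frame(participant_id = character(0),
                      instrument_id = character(0), ts = numeric(0),
                      item_index = integer(0), response = integer(0)))
  }
  start_dn <- daynum(config$cohort$start_date)
  ts_adm <- utc_ms_of_local(start_dn + schedule_days, 12, config$cohort$tz_offset_min)
  exposed <- takers$latent_exposed

  blocks <- vector("list", nrow(effects))
  for (r in seq_len(nrow(effects))) {
    row <- effects[r, ]
    spec <- instrument_registry(row$instrument_id)
    resp <- integer(n_p * n_adm)
    for (g in c(TRUE, FALSE)) {
      idx <- which(rep(exposed, times = n_adm) == g)
      if (!length(idx)) next
      sm <- item_sampler(if (g) row$mean_exposed else row$mean_unexposed,
                         if (g) row$sd_exposed else row$sd_unexposed,
                         spec$scale_min, spec$scale_max)
      resp[idx] <- sample_item(sm, length(idx))
    }
    blocks[[r]] <- data.frame(
      participant_id = rep(takers$participant_id, times = n_adm),
      instrument_id = row$instrument_id,
      ts = rep(ts_adm, each = n_p),
      item_index = row$item_index,
      response = resp,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$participant_id, out$instrument_id, out$ts,
                   out$item_index), ]
  rownames(out) <- NULL
  out
}
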