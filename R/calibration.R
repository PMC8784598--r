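#' Simulate one cohort replicate for comparison calibration
#'
#' Fast-path replicate generator for Monte-Carlo calibration of
#' [compare_all()]: draws each participant's survey responses from the
#' item-level samplers (the same calibrated samplers the full stream
#' generator uses) and each participant's daily passive features from the
#' behavioral ground-truth distributions plus day-level noise, skipping raw
#' sensor-stream emission. Under `null_effects = TRUE` both groups share
#' the unexposed means everywhere, so every comparison row tests a true
#' null.
#'
#' @param n_exposed,n_unexposed group sizes.
#' @param seed RNG seed for the replicate.
#' @param null_effects if TRUE, remove all group effects.
#' @param config a `phenocap_config` supplying item effects, behavior and
#'   schedule.
#' @param study_days days of passive data per participant.
#' @return the [compare_all()] comparison table for the replicate.
#' @export
simulate_comparison_replicate <- function(n_exposed, n_unexposed, seed,
                                          null_effects = FALSE,
                                          config = pipeline_config(seed = seed),
                                          study_days = 28) {
  set.seed(seed)
  n <- n_exposed + n_unexposed
  ids <- sprintf("S%05d", seq_len(n))
  exposed <- c(rep(TRUE, n_exposed), rep(FALSE, n_unexposed))
  groups <- list(exposed = ids[exposed], unexposed = ids[!exposed])
  n_adm <- length(config$survey_schedule_days)
  effects <- config$item_effects
  if (null_effects) {
    effects$mean_exposed <- effects$mean_unexposed
    effects$sd_exposed <- effects$sd_unexposed
  }

  pm <- list(); im <- list()
  for (ins in unique(effects$instrument_id)) {
    spec <- instrument_registry(ins)
    rows <- effects[effects$instrument_id == ins, ]
    # responses[participant, item, administration]
    resp <- array(0L, dim = c(n, spec$n_items, n_adm))
    for (j in seq_len(nrow(rows))) {
      for (g in c(TRUE, FALSE)) {
        idx <- which(exposed == g)
        if (!length(idx)) next
        sm <- item_sampler(if (g) rows$mean_exposed[j] else rows$mean_unexposed[j],
                           if (g) rows$sd_exposed[j] else rows$sd_unexposed[j],
                           spec$scale_min, spec$scale_max)
        resp[idx, rows$item_index[j], ] <- sample_item(sm, length(idx) * n_adm)
      }
    }
    raw <- apply(resp, c(1, 3), sum)
    if (length(spec$reverse_items)) {
      rev_part <- apply(resp[, spec$reverse_items, , drop = FALSE], c(1, 3), sum)
      raw <- raw - rev_part +
        length(spec$reverse_items) * (spec$scale_max + spec$scale_min) - rev_part
    }
    pm[[ins]] <- data.frame(participant_id = ids, instrument_id = ins,
                            mean_normalized = rowMeans(raw) / spec$max_score,
                            stringsAsFactors = FALSE)
    if (ins %in% c("PQ16", "PSQI9")) {
      item_mean <- apply(resp, c(1, 2), mean)
      im[[ins]] <- data.frame(
        participant_id = rep(ids, times = spec$n_items),
        item_index = rep(seq_len(spec$n_items), each = n),
        item_code = rep(spec$item_codes, each = n),
        mean_response = as.vector(item_mean),
        stringsAsFactors = FALSE)
    }
  }
  participant_means <- do.call(rbind, pm)

  bb <- config$behavior
  sleep_mu <- if (null_effects) rep(bb$sleep_mean_h, n) else
    ifelse(exposed, bb$sleep_mean_h - bb$sleep_deficit_h, bb$sleep_mean_h)
  true_sleep <- rtruncnorm(n, sleep_mu, bb$sleep_sd_h,
                           bb$sleep_range_h[1], bb$sleep_range_h[2])
  true_home <- 24 * rtruncnorm(n, bb$home_fraction_mean, bb$home_fraction_sd,
                               bb$home_fraction_range[1], bb$home_fraction_range[2])
  true_screen <- rtruncnorm(n, bb$screen_mean_h, bb$screen_sd_h,
                            bb$screen_range_h[1], bb$screen_range_h[2])
  day_noise <- function(truth, sd_day) {
    matrix(truth, n, study_days) + matrix(rnorm(n * study_days, 0, sd_day),
                                          n, study_days)
  }
  daily <- data.frame(
    participant_id = rep(ids, times = study_days),
    date = rep(as.Date("2021-02-01") + seq_len(study_days) - 1, each = n),
    home_time_h = as.vector(day_noise(true_home, 1.0)),
    sleep_duration_h = as.vector(pmax(day_noise(true_sleep, 0.3), 0)),
    screen_duration_h = as.vector(pmax(day_noise(true_screen, 0.8), 0)),
    gps_missing = FALSE, accel_missing = FALSE, screen_missing = FALSE,
    stringsAsFactors = FALSE)
  feature_means <- participant_feature_means(daily)

  compare_all(participant_means, im, feature_means, groups,
              config$inference)
}

#' Starred-row rate over replicated null cohorts
#'
#' Type-I calibration experiment: with all group effects removed, the
#' long-run fraction of comparison rows starred at level alpha should be
#' close to alpha under the one-sided convention.
#'
#' @param n_reps number of replicates.
#' @param n_exposed,n_unexposed group sizes per replicate.
#' @param seed base seed; replicate r uses seed + r.
#' @param config a `phenocap_config`.
#' @return list `star_rate`, `n_rows`, `alpha`.
#' @export
null_star_rate <- function(n_reps = 400, n_exposed = 100, n_unexposed = 100,
                           seed = 1, config = pipeline_config(seed = seed)) {
  starred <- 0L; total <- 0L
  for (r in seq_len(n_reps)) {
    cmp <- simulate_comparison_replicate(n_exposed, n_unexposed,
                                         seed = sub_seed(seed, r, 4L),
                                         null_effects = TRUE, config = config)
    ok <- !is.na(cmp$p)
    starred <- starred + sum(cmp$p[ok] < config$inference$alpha)
    total <- total + sum(ok)
  }
  list(star_rate = starred / total, n_rows = total,
       alpha = config$inference$alpha)
}
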