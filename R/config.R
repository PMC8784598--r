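#' Cohort generation configuration
#'
#' Parameters of the synthetic recruitment funnel and the enrollment survey.
#' Defaults reproduce the study conditions the generator emulates: 695
#' recruited students, stage retention ratios 612/695 (app usage), 507/612
#' (biweekly survey completion) and 382/507 (exposure question answered), a
#' perceived-stress eligibility screen at PSS >= 14, a 4-week observation
#' window, and a gender mix of 62/35/3 percent female/male/other. The
#' exposed-or-unsure proportion defaults to 54/382, the split consistent
#' with the published item-level t statistics (group sizes were not printed).
#'
#' @param n_recruited number of recruited students.
#' @param p_app_usage,p_survey_completion,p_exposure_answered stage
#'   retention probabilities of the attrition funnel.
#' @param p_exposed_or_unsure probability a participant's exposure answer is
#'   "Yes" or "Unsure, but I think so".
#' @param p_unsure_given_exposed within the exposed group, probability the
#'   raw answer is "Unsure, but I think so" rather than "Yes".
#' @param gender_probs named 3-vector of probabilities (female, male,
#'   other); must sum to 1.
#' @param study_days length of the observation window in days.
#' @param start_date first study date.
#' @param attrition `"exact"` reproduces the stage counts deterministically
#'   (round(n * p) survivors per stage); `"bernoulli"` thins each stage with
#'   independent coin flips.
#' @param pss_threshold eligibility threshold on the enrollment PSS.
#' @param pss_mean,pss_sd latent mean/SD of the enrollment PSS draw.
#' @param pss_screened if TRUE (default) recruits are drawn conditional on
#'   meeting the eligibility threshold, mirroring screening before
#'   enrollment; if FALSE the PSS is unconditional.
#' @param tz_offset_min fixed UTC offset of local clock time, minutes.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_recruited = 695,
                          p_app_usage = 612 / 695,
                          p_survey_completion = 507 / 612,
                          p_exposure_answered = 382 / 507,
                          p_exposed_or_unsure = 54 / 382,
                          p_unsure_given_exposed = 0.5,
                          gender_probs = c(female = 0.62, male = 0.35, other = 0.03),
                          study_days = 28,
                          start_date = as.Date("2021-02-01"),
                          attrition = c("exact", "bernoulli"),
                          pss_threshold = 14,
                          pss_mean = 20, pss_sd = 5,
                          pss_screened = TRUE,
                          tz_offset_min = -300) {
  attrition <- match.arg(attrition)
  probs <- c(p_app_usage, p_survey_completion, p_exposure_answered,
             p_exposed_or_unsure, p_unsure_given_exposed)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("cohort_config: probabilities must lie in [0, 1]")
  }
  if (length(gender_probs) != 3 || abs(sum(gender_probs) - 1) > 1e-8 ||
      any(gender_probs < 0)) {
    stop("cohort_config: gender_probs must be a non-negative 3-vector summing to 1")
  }
  if (is.null(names(gender_probs))) {
    names(gender_probs) <- c("female", "male", "other")
  }
  if (!is.numeric(n_recruited) || n_recruited < 1) {
    stop("cohort_config: n_recruited must be >= 1")
  }
  stopifnot(study_days >= 1, pss_threshold >= 0, pss_sd >= 0)
  structure(list(
    n_recruited = as.integer(n_recruited),
    p_app_usage = p_app_usage,
    p_survey_completion = p_survey_completion,
    p_exposure_answered = p_exposure_answered,
    p_exposed_or_unsure = p_exposed_or_unsure,
    p_unsure_given_exposed = p_unsure_given_exposed,
    gender_probs = gender_probs,
    study_days = as.integer(study_days),
    start_date = as.Date(start_date),
    attrition = attrition,
    pss_threshold = pss_threshold,
    pss_mean = pss_mean, pss_sd = pss_sd,
    pss_screened = isTRUE(pss_screened),
    tz_offset_min = tz_offset_min
  ), class = "cohort_config")
}

#' Ground-truth behavioral parameter configuration
#'
#' Population distributions the generator draws each participant's true
#' behavior from. Sleep is parameterized as the non-exposed group mean and
#' an exposed-group deficit (default 0.48 h, the published ~30-minute
#' shortfall); true durations are kept inside the measurable 8-h sleep
#' window (upper bound 7.9 h) so the window estimator can observe them.
#' Home fraction and screen time carry no group effect, matching the null
#' findings they emulate.
#'
#' @param sleep_mean_h non-exposed mean nightly sleep, hours.
#' @param sleep_deficit_h exposed-group mean sleep deficit, hours.
#' @param sleep_sd_h between-participant SD of true sleep duration.
#' @param sleep_range_h truncation bounds on true sleep duration.
#' @param sleep_onset_mean_h,sleep_onset_sd_h clock time of sleep onset
#'   (hours; 23.5 = 23:30), truncated to [21, 26] (21:00-02:00).
#' @param screen_mean_h,screen_sd_h,screen_range_h daily screen-on time.
#' @param home_fraction_mean,home_fraction_sd,home_fraction_range fraction
#'   of the day spent at home.
#' @param campus reference (lat, lon) around which homes are scattered.
#' @param home_scatter_km,away_scatter_km scatter radii for home and
#'   away-location coordinates.
#' @return list of class `behavior_config`.
#' @export
behavior_config <- function(sleep_mean_h = 7.0,
                            sleep_deficit_h = 0.48,
                            sleep_sd_h = 0.45,
                            sleep_range_h = c(3, 7.9),
                            sleep_onset_mean_h = 23.5,
                            sleep_onset_sd_h = 0.5,
                            screen_mean_h = 5.0,
                            screen_sd_h = 1.5,
                            screen_range_h = c(0.5, 12),
                            home_fraction_mean = 0.7,
                            home_fraction_sd = 0.1,
                            home_fraction_range = c(0.3, 0.95),
                            campus = c(lat = 42.34, lon = -71.10),
                            home_scatter_km = 4,
                            away_scatter_km = 2) {
  stopifnot(sleep_range_h[1] >= 0, sleep_range_h[2] <= 8,
            sleep_range_h[1] < sleep_range_h[2],
            sleep_sd_h >= 0, screen_sd_h >= 0, home_fraction_sd >= 0,
            home_fraction_range[1] >= 0, home_fraction_range[2] <= 1)
  structure(as.list(environment()), class = "behavior_config")
}

#' Sensor stream emission configuration
#'
#' Cadence, noise and activity-distribution parameters of the synthetic raw
#' streams. Accelerometer activity is an abstract non-negative score per
#' 60-s epoch; asleep and awake epochs draw from two normals (truncated at
#' zero) whose separation makes the activity contrast detectable.
#'
#' @param gps_cadence_s seconds between GPS fixes.
#' @param gps_noise_m positional Gaussian noise SD, meters.
#' @param gps_accuracy_m reported accuracy field, meters.
#' @param accel_epoch_s accelerometer epoch length, seconds.
#' @param activity_sleep_mean,activity_sleep_sd activity score during sleep.
#' @param activity_wake_mean,activity_wake_sd activity score while awake.
#' @param sleep_onset_jitter_h,sleep_duration_jitter_h night-to-night SD of
#'   onset clock time and duration around the participant's true values.
#' @param screen_bouts mean number of screen-use bouts per day.
#' @param screen_window_h local clock interval within which bouts occur.
#' @param p_day_missing probability a participant-day's streams are dropped
#'   entirely (uniform day-level dropout).
#' @return list of class `sensor_config`.
#' @export
sensor_config <- function(gps_cadence_s = 300,
                          gps_noise_m = 20,
                          gps_accuracy_m = 10,
                          accel_epoch_s = 60,
                          activity_sleep_mean = 0.05,
                          activity_sleep_sd = 0.015,
                          activity_wake_mean = 1.2,
                          activity_wake_sd = 0.35,
                          sleep_onset_jitter_h = 0.15,
                          sleep_duration_jitter_h = 0.15,
                          screen_bouts = 15,
                          screen_window_h = c(10, 23),
                          p_day_missing = 0) {
  stopifnot(gps_cadence_s > 0, accel_epoch_s > 0,
            p_day_missing >= 0, p_day_missing <= 1,
            screen_window_h[1] < screen_window_h[2])
  structure(as.list(environment()), class = "sensor_config")
}

#' Sleep-window estimation configuration
#'
#' The sleep feature searches the overnight interval (default 18:00 to
#' 10:00 the next day) for the fixed-length window (default 8 h) with
#' minimal pooled accelerometer activity, stepping candidate starts by
#' `step_min`. Each night the window may shift by up to `adjust_shift_h`
#' before the asleep threshold is applied.
#'
#' @param overnight_start,overnight_end clock hours bounding the overnight
#'   interval; `overnight_end` is on the following day.
#' @param window_h sleep-window length, hours.
#' @param step_min candidate start step, minutes; must divide the window
#'   evenly.
#' @param adjust_shift_h maximal nightly shift of the window, hours.
#' @param epoch_s activity epoch length used by the feature, seconds.
#' @param min_coverage minimal fraction of overnight epochs a night must
#'   have to be used.
#' @param asleep_threshold_rule named rule for the asleep threshold;
#'   `"halves_midpoint"` sets it to the midpoint of the means of the lower
#'   and upper halves of the night's sorted in-window activities.
#' @return list of class `sleep_config`.
#' @export
sleep_config <- function(overnight_start = 18,
                         overnight_end = 10,
                         window_h = 8,
                         step_min = 10,
                         adjust_shift_h = 2,
                         epoch_s = 60,
                         min_coverage = 0.5,
                         asleep_threshold_rule = "halves_midpoint") {
  interval_h <- (24 - overnight_start) + overnight_end
  if (window_h > interval_h) {
    stop("sleep_config: window_h exceeds the overnight interval length")
  }
  if ((window_h * 60) %% step_min != 0) {
    stop("sleep_config: step_min must divide the window evenly")
  }
  stopifnot(min_coverage > 0, min_coverage <= 1,
            identical(asleep_threshold_rule, "halves_midpoint"))
  structure(list(overnight_start = overnight_start,
                 overnight_end = overnight_end, window_h = window_h,
                 step_min = step_min, adjust_shift_h = adjust_shift_h,
                 epoch_s = epoch_s, min_coverage = min_coverage,
                 asleep_threshold_rule = asleep_threshold_rule),
            class = "sleep_config")
}

#' Feature extraction configuration (GPS clustering, home time, screen)
#'
#' @param eps_m significant-location clustering radius, meters.
#' @param min_weight minimal weight for a cluster to be reported.
#' @param home_night_start,home_night_end clock hours of the overnight span
#'   whose fixes define the home cluster.
#' @param gap_max_s maximal gap between consecutive home-assigned fixes for
#'   the interval between them to count as time at home, seconds.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(eps_m = 100,
                           min_weight = 0,
                           home_night_start = 0,
                           home_night_end = 6,
                           gap_max_s = 600) {
  stopifnot(eps_m > 0, min_weight >= 0, min_weight <= 1, gap_max_s > 0)
  structure(as.list(environment()), class = "feature_config")
}

#' Group-inference configuration
#'
#' @param alpha significance level for single stars.
#' @param alpha_strong level for double stars.
#' @param sided `"greater"` (upper-tail, exposed > non-exposed; the
#'   published convention) or `"two.sided"`.
#' @param ci_quantile Student-t quantile used for the reconstructed
#'   interval; 0.95 reproduces the published bounds.
#' @param fdr apply Benjamini-Hochberg adjustment before starring.
#' @return list of class `inference_config`.
#' @export
inference_config <- function(alpha = 0.05,
                             alpha_strong = 0.001,
                             sided = c("greater", "two.sided"),
                             ci_quantile = 0.95,
                             fdr = FALSE) {
  sided <- match.arg(sided)
  stopifnot(alpha > 0, alpha < 1, alpha_strong > 0, alpha_strong <= alpha,
            ci_quantile > 0.5, ci_quantile < 1)
  structure(list(alpha = alpha, alpha_strong = alpha_strong, sided = sided,
                 ci_quantile = ci_quantile, fdr = isTRUE(fdr)),
            class = "inference_config")
}

#' Full pipeline configuration
#'
#' Assembles the per-stage configurations with a mandatory seed. Any
#' section can be overridden by passing a corresponding `*_config()` object
#' or a named list of overrides.
#'
#' @param seed integer seed; every source of randomness derives from it.
#' @param cohort,behavior,sensors,sleep,features,inference section configs.
#' @param survey_schedule_days administration days relative to the study
#'   start (default enrollment plus two biweekly administrations).
#' @param item_effects item-level effect table (see
#'   [default_item_effects()]).
#' @param out_dir output directory for [run_pipeline()].
#' @return nested list of class `phenocap_config`.
#' @export
pipeline_config <- function(seed,
                            cohort = cohort_config(),
                            behavior = behavior_config(),
                            sensors = sensor_config(),
                            sleep = sleep_config(),
                            features = feature_config(),
                            inference = inference_config(),
                            survey_schedule_days = c(0, 14, 28),
                            item_effects = default_item_effects(),
                            out_dir = NULL) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed)) {
    stop("pipeline_config: an integer seed is required")
  }
  coerce <- function(x, ctor) {
    if (inherits(x, class(ctor()))) return(x)
    do.call(ctor, as.list(x))
  }
  structure(list(
    seed = as.integer(seed),
    cohort = coerce(cohort, cohort_config),
    behavior = coerce(behavior, behavior_config),
    sensors = coerce(sensors, sensor_config),
    sleep = coerce(sleep, sleep_config),
    features = coerce(features, feature_config),
    inference = coerce(inference, inference_config),
    survey_schedule_days = survey_schedule_days,
    item_effects = item_effects,
    out_dir = out_dir
  ), class = "phenocap_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds any subset of the [pipeline_config()] sections
#' (`seed`, `cohort`, `behavior`, `sensors`, `sleep`, `features`,
#' `inference`, `survey_schedule_days`, `out_dir`); unspecified values fall
#' back to defaults. The seed is mandatory in the file unless supplied via
#' `seed`.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file.
#' @return a `phenocap_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  seed <- seed %||% raw$seed
  if (is.null(seed)) stop("read_run_config: config must provide a seed")
  args <- list(seed = seed)
  for (sec in c("cohort", "behavior", "sensors", "sleep", "features",
                "inference")) {
    if (!is.null(raw[[sec]])) args[[sec]] <- raw[[sec]]
  }
  if (!is.null(raw$cohort$start_date)) {
    args$cohort$start_date <- as.Date(raw$cohort$start_date)
  }
  if (!is.null(raw$survey_schedule_days)) {
    args$survey_schedule_days <- raw$survey_schedule_days
  }
  if (!is.null(raw$out_dir)) args$out_dir <- raw$out_dir
  do.call(pipeline_config, args)
}

#' Default item-level effect table
#'
#' One row per instrument item with the target mean response per exposure
#' group and the latent dispersion. PQ-16 and PSQI rows carry the published
#' item-level group means and SDs; the remaining instruments (for which no
#' group difference was reported) use one common mean for both groups.
#'
#' @return data.frame `instrument_id`, `item_index`, `item_code`,
#'   `mean_exposed`, `mean_unexposed`, `sd_exposed`, `sd_unexposed`.
#' @export
default_item_effects <- function() {
  ref <- reference_item_table()
  tab1 <- data.frame(
    instrument_id = ref$instrument_id,
    item_index = ref$item_index,
    item_code = ref$item_code,
    mean_exposed = ref$mean_exposed,
    mean_unexposed = ref$mean_unexposed,
    sd_exposed = ref$sd_exposed,
    sd_unexposed = ref$sd_unexposed,
    stringsAsFactors = FALSE
  )
  flat <- function(id, mean, sd) {
    spec <- instrument_registry(id)
    data.frame(instrument_id = id,
               item_index = seq_len(spec$n_items),
               item_code = spec$item_codes,
               mean_exposed = mean, mean_unexposed = mean,
               sd_exposed = sd, sd_unexposed = sd,
               stringsAsFactors = FALSE)
  }
  rbind(tab1,
        flat("PHQ9", 1.0, 0.9),
        flat("GAD7", 1.0, 0.9),
        flat("PSS", 2.0, 1.0),
        flat("UCLA", 2.2, 0.9),
        flat("DWAI", 4.8, 1.4))
}
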