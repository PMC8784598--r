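#' Build the per-participant-day passive feature table
#'
#' Runs the three passive-feature extractors over a cohort's raw streams:
#' significant-location clustering and home labeling feed daily home time;
#' accelerometer epochs feed the optimal-sleep-window estimator; screen
#' events feed daily screen duration. One row is produced per participant
#' and study date. A missing or unusable sensor yields missing feature
#' values with a quality flag, never zeros. Duplicate sensor timestamps
#' are dropped (first record kept).
#'
#' @param streams list of long data.frames `gps`, `accel`, `screen` (each
#'   with `participant_id`), e.g. from [generate_cohort_streams()] or
#'   [read_sensor_jsonl()].
#' @param roster roster rows for the participants to process (supplies
#'   `tz_offset_min`).
#' @param config a `phenocap_config` (feature and sleep sections used).
#' @param dates study dates; defaults to the configured study window.
#' @return data.frame `participant_id`, `date`, `home_time_h`,
#'   `sleep_duration_h`, `screen_duration_h`, `gps_missing`,
#'   `accel_missing`, `screen_missing`.
#' @export
build_daily_features <- function(streams, roster, config, dates = NULL) {
  cc <- config$cohort
  fc <- config$features
  sc <- config$sleep
  dates <- dates %||% (cc$start_date + seq_len(cc$study_days) - 1)
  out <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    pid <- roster$participant_id[i]
    tz <- roster$tz_offset_min[i]
    row <- data.frame(participant_id = pid, date = dates,
                      home_time_h = NA_real_, sleep_duration_h = NA_real_,
                      screen_duration_h = NA_real_,
                      gps_missing = FALSE, accel_missing = FALSE,
                      screen_missing = FALSE, stringsAsFactors = FALSE)

    gps <- dedupe_ts(streams$gps[streams$gps$participant_id == pid, , drop = FALSE])
    if (nrow(gps) >= 2) {
      cl <- significant_locations(gps, eps_m = fc$eps_m,
                                  min_weight = fc$min_weight)
      cl <- label_home(cl, gps, fc$home_night_start, fc$home_night_end, tz)
      ht <- home_time(gps, cl, fc$gap_max_s, tz)
      m <- match(as.Date(dates), ht$date)
      row$home_time_h <- ht$home_time_h[m]
    } else {
      row$gps_missing <- TRUE
    }

    accel <- dedupe_ts(streams$accel[streams$accel$participant_id == pid, , drop = FALSE])
    if (nrow(accel)) {
      ep <- accel_epochs(accel, sc$epoch_s, tz)
      sl <- tryCatch(sleep_durations(ep, sc), error = function(e) NULL)
      if (is.null(sl)) {
        row$accel_missing <- TRUE
      } else {
        m <- match(as.Date(dates), sl$date)
        row$sleep_duration_h <- sl$sleep_duration_h[m]
      }
    } else {
      row$accel_missing <- TRUE
    }

    scr <- dedupe_ts(streams$screen[streams$screen$participant_id == pid, , drop = FALSE])
    if (nrow(scr)) {
      sd_ <- screen_daily(scr, dates, tz)
      row$screen_duration_h <- sd_$screen_duration_h
    } else {
      row$screen_missing <- TRUE
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

dedupe_ts <- function(df) {
  if (is.null(df) || !nrow(df)) {
    return(df %||% data.frame(participant_id = character(0), ts = numeric(0)))
  }
  df <- df[order(df$ts), , drop = FALSE]
  df[!duplicated(df$ts), , drop = FALSE]
}

#' Per-participant means of daily passive features
#'
#' The unit of analysis for group comparison: each participant's mean over
#' their available days (missing days excluded, not imputed).
#'
#' @param daily output of [build_daily_features()].
#' @return data.frame `participant_id`, `home_time_h`, `sleep_duration_h`,
#'   `screen_duration_h` (NA when a participant has no usable day).
#' @export
participant_feature_means <- function(daily) {
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  ids <- unique(daily$participant_id)
  do.call(rbind, lapply(ids, function(pid) {
    d <- daily[daily$participant_id == pid, ]
    data.frame(participant_id = pid,
               home_time_h = mean_or_na(d$home_time_h),
               sleep_duration_h = mean_or_na(d$sleep_duration_h),
               screen_duration_h = mean_or_na(d$screen_duration_h),
               stringsAsFactors = FALSE)
  }))
}
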