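#' Generate raw sensor streams for one participant over the study
#'
#' Emits the three raw streams the feature layer consumes, together with
#' the ground truth that produced them:
#' \itemize{
#'   \item GPS fixes at a fixed cadence over each day, positioned at the
#'     participant's home coordinate during true home intervals and at the
#'     away coordinates otherwise, with Gaussian positional noise;
#'   \item accelerometer activity epochs covering each night's overnight
#'     interval (18:00 to 10:00 next day), low activity inside the night's
#'     true sleep interval and higher activity outside;
#'   \item screen-state events as alternating on/off pairs whose bouts sum
#'     to the participant's true daily screen hours.
#' }
#' Time away from home is one contiguous block per day centered on 13:00
#' local; sleep for date d occupies the night ending on the morning of d,
#' so each study date owns one sleep interval.
#'
#' @param profile one roster row from [generate_cohort()].
#' @param config the `phenocap_config` used to generate the cohort.
#' @param dates Date vector; defaults to the configured study window.
#' @param seed RNG seed; defaults to a lane derived from the config seed
#'   and the participant id, so streams are reproducible regardless of the
#'   order participants are generated in.
#' @return list with `gps` (ts, lat, lon, accuracy_m), `accel`
#'   (ts, activity), `screen` (ts, state) and `truth` (data.frames `sleep`,
#'   `home`, `screen_bouts`, each with date and UTC-ms interval bounds).
#'   All `ts` are UTC epoch milliseconds.
#' @export
generate_participant_streams <- function(profile, config, dates = NULL,
                                         seed = NULL) {
  stopifnot(nrow(profile) == 1)
  cc <- config$cohort; ss <- config$sensors
  dates <- dates %||% (cc$start_date + seq_len(cc$study_days) - 1)
  set.seed(seed %||% sub_seed(config$seed, participant_index(profile$participant_id), 1L))

  tz <- profile$tz_offset_min
  dn <- daynum(dates)
  nd <- length(dn)

  # --- nightly sleep truth -------------------------------------------------
  onset <- clip(profile$true_sleep_onset_h + rnorm(nd, 0, ss$sleep_onset_jitter_h),
                21, 26)
  dur <- clip(profile$true_sleep_duration_h +
                rnorm(nd, 0, ss$sleep_duration_jitter_h),
              0, pmin(8, 34 - onset - 0.05))
  sl_start_loc <- dn * MS_PER_DAY + (onset - 24) * MS_PER_HOUR
  sl_end_loc <- sl_start_loc + dur * MS_PER_HOUR

  # --- daily home truth ----------------------------------------------------
  away_h <- (1 - profile$true_home_fraction) * 24
  a_start <- clip(13 - away_h / 2, 0, 24)
  a_end <- clip(13 + away_h / 2, 0, 24)

  keep <- runif(nd) >= ss$p_day_missing

  # --- accelerometer: overnight interval of each night ---------------------
  n_ep <- as.integer(16 * 3600 / ss$accel_epoch_s)
  ep_ms <- ss$accel_epoch_s * 1000
  night_start_loc <- (dn - 1) * MS_PER_DAY + 18 * MS_PER_HOUR
  lts <- rep(night_start_loc, each = n_ep) + rep.int(seq_len(n_ep) - 1, nd) * ep_ms
  act <- rnorm(nd * n_ep, ss$activity_wake_mean, ss$activity_wake_sd)
  asleep <- lts >= rep(sl_start_loc, each = n_ep) &
    lts < rep(sl_end_loc, each = n_ep)
  act[asleep] <- rnorm(sum(asleep), ss$activity_sleep_mean, ss$activity_sleep_sd)
  act <- pmax(act, 0)
  keep_ep <- rep(keep, each = n_ep)
  accel <- data.frame(ts = lts[keep_ep] - tz * 60000,
                      activity = act[keep_ep])

  # --- GPS -----------------------------------------------------------------
  cad_ms <- ss$gps_cadence_s * 1000
  n_fix <- as.integer(MS_PER_DAY / cad_ms)
  flts <- rep(dn * MS_PER_DAY, each = n_fix) +
    rep.int(seq_len(n_fix) - 1, nd) * cad_ms
  hr <- (flts %% MS_PER_DAY) / MS_PER_HOUR
  away <- hr >= a_start & hr < a_end
  second_leg <- hr >= (a_start + a_end) / 2
  base_lat <- ifelse(away, ifelse(second_leg, profile$away2_lat, profile$away1_lat),
                     profile$home_lat)
  base_lon <- ifelse(away, ifelse(second_leg, profile$away2_lon, profile$away1_lon),
                     profile$home_lon)
  ncoord <- length(flts)
  noise_deg <- ss$gps_noise_m / 111320
  lat <- base_lat + rnorm(ncoord, 0, noise_deg)
  lon <- base_lon + rnorm(ncoord, 0, noise_deg / cos(profile$home_lat * pi / 180))
  keep_fix <- rep(keep, each = n_fix)
  gps <- data.frame(ts = flts[keep_fix] - tz * 60000,
                    lat = lat[keep_fix], lon = lon[keep_fix],
                    accuracy_m = ss$gps_accuracy_m)

  # --- screen events -------------------------------------------------------
  win <- ss$screen_window_h
  win_len <- win[2] - win[1]
  s_h <- min(profile$true_daily_screen_h, win_len - 0.5)
  sb <- vector("list", nd)
  if (s_h > 0) {
    k <- max(1L, as.integer(round(ss$screen_bouts)))
    for (i in seq_len(nd)) {
      w <- rexp(k); g <- rexp(k + 1)
      bout_h <- s_h * w / sum(w)
      gap_h <- (win_len - s_h) * g / sum(g)
      starts <- win[1] + cumsum(gap_h)[seq_len(k)] +
        c(0, cumsum(bout_h))[seq_len(k)]
      ends <- starts + bout_h
      sb[[i]] <- data.frame(
        date = dates[i],
        start_ts = round(dn[i] * MS_PER_DAY + starts * MS_PER_HOUR - tz * 60000),
        end_ts = round(dn[i] * MS_PER_DAY + ends * MS_PER_HOUR - tz * 60000))
    }
  }
  screen_bouts <- if (s_h > 0) do.call(rbind, sb) else
    data.frame(date = as.Date(character(0)), start_ts = numeric(0),
               end_ts = numeric(0))
  emitted <- screen_bouts[rep(keep, vapply(sb, NROW, 1L))
                          [seq_len(nrow(screen_bouts))], , drop = FALSE]
  screen <- data.frame(
    ts = as.vector(rbind(emitted$start_ts, emitted$end_ts)),
    state = rep(c("on", "off"), length.out = 2 * nrow(emitted)),
    stringsAsFactors = FALSE)
  screen <- screen[order(screen$ts), , drop = FALSE]
  rownames(screen) <- NULL

  # --- ground truth --------------------------------------------------------
  home_rows <- list()
  for (i in seq_len(nd)) {
    segs <- rbind(if (a_start > 0) c(0, a_start),
                  if (a_end < 24) c(a_end, 24))
    if (profile$true_home_fraction >= 1 - 1e-12) segs <- rbind(c(0, 24))
    if (!is.null(segs) && nrow(segs)) {
      home_rows[[i]] <- data.frame(
        date = dates[i],
        start_ts = dn[i] * MS_PER_DAY + segs[, 1] * MS_PER_HOUR - tz * 60000,
        end_ts = dn[i] * MS_PER_DAY + segs[, 2] * MS_PER_HOUR - tz * 60000)
    }
  }
  truth <- list(
    sleep = data.frame(date = dates,
                       start_ts = sl_start_loc - tz * 60000,
                       end_ts = sl_end_loc - tz * 60000),
    home = if (length(home_rows)) do.call(rbind, home_rows) else
      data.frame(date = as.Date(character(0)), start_ts = numeric(0),
                 end_ts = numeric(0)),
    screen_bouts = screen_bouts
  )
  list(gps = gps, accel = accel, screen = screen, truth = truth)
}

participant_index <- function(id) {
  idx <- suppressWarnings(as.integer(gsub("\\D", "", id)))
  if (is.na(idx)) idx <- sum(utf8ToInt(id)) %% 100000L
  idx
}

#' Generate one day's sensor streams for a participant
#'
#' Single-day view of [generate_participant_streams()]: GPS and screen
#' events of the local date, the accelerometer epochs of the night ending
#' on its morning, and that day's ground truth. Values are identical to the
#' corresponding slice of the full-study streams.
#'
#' @inheritParams generate_participant_streams
#' @param date one study date.
#' @export
generate_sensor_streams <- function(profile, config, date, seed = NULL) {
  date <- as.Date(date)
  cc <- config$cohort
  study <- cc$start_date + seq_len(cc$study_days) - 1
  if (!date %in% study) stop("generate_sensor_streams: date outside study period")
  full <- generate_participant_streams(profile, config, dates = study,
                                       seed = seed)
  tz <- profile$tz_offset_min
  d <- daynum(date)
  gd <- local_daynum(full$gps$ts, tz) == d
  night <- local_ms(full$accel$ts, tz) >= (d - 1) * MS_PER_DAY + 18 * MS_PER_HOUR &
    local_ms(full$accel$ts, tz) < d * MS_PER_DAY + 10 * MS_PER_HOUR
  sd_ <- local_daynum(full$screen$ts, tz) == d
  list(gps = full$gps[gd, , drop = FALSE],
       accel = full$accel[night, , drop = FALSE],
       screen = full$screen[sd_, , drop = FALSE],
       truth = lapply(full$truth, function(t) t[t$date == date, , drop = FALSE]))
}

#' Generate sensor streams and ground truth for a whole cohort
#'
#' @param cohort a `phenocap_cohort`.
#' @param participants optional participant ids; defaults to all app users.
#' @return list of long data.frames `gps`, `accel`, `screen` (each with a
#'   `participant_id` column) and `truth` (list of long `sleep`, `home`,
#'   `screen_bouts` tables).
#' @export
generate_cohort_streams <- function(cohort, participants = NULL) {
  roster <- cohort$roster
  participants <- participants %||% roster$participant_id[roster$used_app]
  rows <- roster[match(participants, roster$participant_id), , drop = FALSE]
  if (anyNA(rows$participant_id)) stop("unknown participant id(s)")
  per <- lapply(seq_len(nrow(rows)), function(i) {
    st <- generate_participant_streams(rows[i, ], cohort$config)
    for (nm in c("gps", "accel", "screen")) {
      if (nrow(st[[nm]])) st[[nm]]$participant_id <- rows$participant_id[i]
    }
    for (nm in names(st$truth)) {
      if (nrow(st$truth[[nm]])) st$truth[[nm]]$participant_id <- rows$participant_id[i]
    }
    st
  })
  bind <- function(get) do.call(rbind, lapply(per, get))
  list(gps = bind(function(x) x$gps),
       accel = bind(function(x) x$accel),
       screen = bind(function(x) x$screen),
       truth = list(
         sleep = bind(function(x) x$truth$sleep),
         home = bind(function(x) x$truth$home),
         screen_bouts = bind(function(x) x$truth$screen_bouts)))
}
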