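#' Aggregate raw accelerometer records to fixed activity epochs
#'
#' Pre-aggregation step of the sleep feature: raw activity scores are
#' averaged within consecutive epochs (default 60 s) of the local clock,
#' making the feature robust to the raw sampling cadence and unit-agnostic.
#'
#' @param accel data.frame `ts` (UTC ms), `activity`.
#' @param epoch_s epoch length, seconds.
#' @param tz_offset_min participant's UTC offset in minutes.
#' @return data.frame `epoch_local_ms` (epoch start, local ms), `activity`.
#' @export
accel_epochs <- function(accel, epoch_s = 60, tz_offset_min = 0) {
  if (!nrow(accel)) {
    return(data.frame(epoch_local_ms = numeric(0), activity = numeric(0)))
  }
  ep <- floor(local_ms(accel$ts, tz_offset_min) / (epoch_s * 1000))
  m <- rowsum(accel$activity, ep) / as.vector(table(ep))
  data.frame(epoch_local_ms = as.numeric(rownames(m)) * epoch_s * 1000,
             activity = as.numeric(m))
}

# Assign epochs to nights. A night runs from `overnight_start` on date d-1
# to `overnight_end` on date d and is attributed to date d; epochs outside
# the overnight interval are dropped. Returns night_date (day number),
# offset (epoch index from the interval start) and activity.
night_epochs <- function(epochs, cfg) {
  lms <- epochs$epoch_local_ms
  hr <- (lms %% MS_PER_DAY) / MS_PER_HOUR
  day <- floor(lms / MS_PER_DAY)
  evening <- hr >= cfg$overnight_start
  morning <- hr < cfg$overnight_end
  keep <- evening | morning
  night_date <- ifelse(evening, day + 1, day)[keep]
  start_ms <- (night_date - 1) * MS_PER_DAY + cfg$overnight_start * MS_PER_HOUR
  offset <- (lms[keep] - start_ms) / (cfg$epoch_s * 1000)
  data.frame(night_date = night_date, offset = as.integer(offset),
             activity = epochs$activity[keep])
}

night_slots <- function(cfg) {
  as.integer(((24 - cfg$overnight_start) + cfg$overnight_end) * 3600 / cfg$epoch_s)
}

window_slots <- function(cfg) as.integer(cfg$window_h * 3600 / cfg$epoch_s)

# windowed means over slot vectors via cumulative sums; candidates are slot
# offsets. Missing slots contribute nothing (excluded from the mean).
window_means <- function(sums, counts, candidates, w) {
  cs <- c(0, cumsum(sums))
  cc <- c(0, cumsum(counts))
  s <- cs[candidates + w + 1] - cs[candidates + 1]
  n <- cc[candidates + w + 1] - cc[candidates + 1]
  ifelse(n > 0, s / n, Inf)
}

#' Optimal sleep window across nights
#'
#' Finds the fixed-length window (default 8 h) within the overnight
#' interval (default 18:00-10:00) whose mean accelerometer activity,
#' pooled over all usable nights, is minimal. Candidate starts step by
#' `step_min` from the interval start to the last start whose window still
#' ends inside the interval; missing epochs are excluded from the means;
#' ties go to the earliest start. Nights with epoch coverage below
#' `min_coverage` are ignored.
#'
#' @param nights data.frame from [night_epochs()] (columns `night_date`,
#'   `offset`, `activity`), one participant.
#' @param cfg a [sleep_config()].
#' @return list: `start_offset_min` (minutes after the interval start),
#'   `start_clock_h` (clock hour of the window start), `pooled_mean`,
#'   `candidate_offsets_min`, `candidate_means`, `nights_used`.
#' @export
optimal_sleep_window <- function(nights, cfg = sleep_config()) {
  slots <- night_slots(cfg)
  w <- window_slots(cfg)
  cov <- table(nights$night_date)
  good <- as.numeric(names(cov))[cov >= cfg$min_coverage * slots]
  if (!length(good)) stop("insufficient accelerometer data")
  nn <- nights[nights$night_date %in% good, ]
  sums <- counts <- numeric(slots)
  agg <- rowsum(cbind(nn$activity, 1), nn$offset)
  idx <- as.numeric(rownames(agg)) + 1
  sums[idx] <- agg[, 1]; counts[idx] <- agg[, 2]
  step_slots <- as.integer(cfg$step_min * 60 / cfg$epoch_s)
  candidates <- seq.int(0L, slots - w, by = step_slots)
  means <- window_means(sums, counts, candidates, w)
  best <- which.min(means)   # first minimum = earliest start
  off_min <- candidates[best] * cfg$epoch_s / 60
  list(start_offset_min = off_min,
       start_clock_h = (cfg$overnight_start + off_min / 60) %% 24,
       pooled_mean = means[best],
       candidate_offsets_min = candidates * cfg$epoch_s / 60,
       candidate_means = means,
       nights_used = good)
}

#' Nightly sleep duration from an adjusted window
#'
#' Estimates one night's sleep duration in three steps: (i) shift the base
#' window within +/- `adjust_shift_h` (clipped to the overnight interval)
#' to the candidate start minimizing that night's mean activity; (ii) set
#' the asleep threshold to the midpoint of the means of the lower and upper
#' halves of the night's sorted in-window activities; (iii) count in-window
#' epochs that are asleep: activity strictly below the threshold, or
#' exactly zero (perfect stillness is asleep regardless of the threshold).
#' A night of constant positive activity therefore yields 0 h, and a
#' window of identical zeros yields the full window.
#'
#' @param night data.frame (`offset`, `activity`) of one night.
#' @param base_start_offset_min base window start from
#'   [optimal_sleep_window()], minutes after the interval start.
#' @param cfg a [sleep_config()].
#' @return estimated hours asleep, or `NA` if the night's coverage is below
#'   `min_coverage`.
#' @export
nightly_sleep_duration <- function(night, base_start_offset_min,
                                   cfg = sleep_config()) {
  slots <- night_slots(cfg)
  w <- window_slots(cfg)
  if (nrow(night) < cfg$min_coverage * slots) return(NA_real_)
  step_slots <- as.integer(cfg$step_min * 60 / cfg$epoch_s)
  base <- as.integer(base_start_offset_min * 60 / cfg$epoch_s)
  shift <- as.integer(cfg$adjust_shift_h * 3600 / cfg$epoch_s)
  candidates <- seq.int(max(0L, base - shift),
                        min(slots - w, base + shift), by = step_slots)
  sums <- counts <- numeric(slots)
  agg <- rowsum(cbind(night$activity, 1), night$offset)
  idx <- as.numeric(rownames(agg)) + 1
  sums[idx] <- agg[, 1]; counts[idx] <- agg[, 2]
  means <- window_means(sums, counts, candidates, w)
  if (all(!is.finite(means))) return(NA_real_)
  best <- candidates[which.min(means)]
  acts <- night$activity[night$offset >= best & night$offset < best + w]
  if (!length(acts)) return(NA_real_)
  theta <- halves_midpoint(acts)
  sum(acts < theta | acts == 0) * cfg$epoch_s / 3600
}

# asleep threshold: midpoint of the means of the lower and upper halves of
# the sorted activities (median value goes to the upper half for odd n).
halves_midpoint <- function(acts) {
  a <- sort(acts)
  n <- length(a)
  if (n == 1) return(a)
  h <- n %/% 2
  (mean(a[seq_len(h)]) + mean(a[(h + 1):n])) / 2
}

#' Per-night sleep durations for one participant
#'
#' Convenience wrapper: derives the base optimal window from all usable
#' nights, then estimates each night's duration.
#'
#' @param epochs output of [accel_epochs()].
#' @param cfg a [sleep_config()].
#' @return data.frame `date`, `sleep_duration_h` (NA for nights below the
#'   coverage requirement).
#' @export
sleep_durations <- function(epochs, cfg = sleep_config()) {
  nights <- night_epochs(epochs, cfg)
  base <- optimal_sleep_window(nights, cfg)
  per <- split(nights, nights$night_date)
  dur <- vapply(per, nightly_sleep_duration, numeric(1),
                base_start_offset_min = base$start_offset_min, cfg = cfg)
  data.frame(date = daynum_to_date(as.numeric(names(per))),
             sleep_duration_h = as.numeric(dur))
}
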