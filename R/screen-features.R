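#' Pair screen-state events into usage bouts
#'
#' Each "on" opens a bout closed by the next "off". Repeated "on" events
#' keep the first (the screen was already on); "off" events with no open
#' bout are ignored; a trailing unmatched "on" is dropped. Malformed events
#' are counted in `attr(, "n_malformed")`.
#'
#' @param events data.frame `ts` (UTC ms), `state` ("on"/"off"),
#'   time-sorted.
#' @return data.frame `start_ts`, `end_ts`.
#' @export
screen_bouts <- function(events) {
  out <- data.frame(start_ts = numeric(0), end_ts = numeric(0))
  if (!nrow(events)) {
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  if (is.unsorted(events$ts)) stop("screen_bouts: events must be time-sorted")
  stopifnot(all(events$state %in% c("on", "off")))
  starts <- ends <- numeric(nrow(events))
  k <- 0L; open <- NA_real_; malformed <- 0L
  for (i in seq_len(nrow(events))) {
    if (events$state[i] == "on") {
      if (is.na(open)) open <- events$ts[i] else malformed <- malformed + 1L
    } else {
      if (is.na(open)) {
        malformed <- malformed + 1L
      } else {
        k <- k + 1L
        starts[k] <- open; ends[k] <- events$ts[i]
        open <- NA_real_
      }
    }
  }
  if (!is.na(open)) malformed <- malformed + 1L
  out <- data.frame(start_ts = starts[seq_len(k)], end_ts = ends[seq_len(k)])
  attr(out, "n_malformed") <- malformed
  out
}

#' Screen-on hours per local date
#'
#' Sums the portions of on-to-off bouts overlapping each requested local
#' date.
#'
#' @param events screen-state events (see [screen_bouts()]).
#' @param dates Date vector of days to report.
#' @param tz_offset_min participant's UTC offset in minutes.
#' @return data.frame `date`, `screen_duration_h`.
#' @export
screen_daily <- function(events, dates, tz_offset_min = 0) {
  bouts <- screen_bouts(events)
  dn <- daynum(dates)
  hrs <- numeric(length(dn))
  if (nrow(bouts)) {
    s <- local_ms(bouts$start_ts, tz_offset_min)
    e <- local_ms(bouts$end_ts, tz_offset_min)
    for (i in seq_along(dn)) {
      lo <- dn[i] * MS_PER_DAY; hi <- lo + MS_PER_DAY
      ov <- pmin(e, hi) - pmax(s, lo)
      hrs[i] <- sum(ov[ov > 0]) / MS_PER_HOUR
    }
  }
  data.frame(date = as.Date(dates), screen_duration_h = hrs)
}

#' Screen-on hours for one local date
#'
#' @inheritParams screen_daily
#' @param date one day.
#' @return hours.
#' @export
screen_duration <- function(events, date, tz_offset_min = 0) {
  screen_daily(events, as.Date(date), tz_offset_min)$screen_duration_h
}
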