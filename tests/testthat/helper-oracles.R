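# Independent oracles used to cross-check the package's implementations.
# Each is written from the definition, not from the implementation path.

# exhaustive sleep-window scan: explicit loops, no cumulative sums
oracle_window_scan <- function(nights, cfg = sleep_config()) {
  slots <- as.integer(((24 - cfg$overnight_start) + cfg$overnight_end) *
                        3600 / cfg$epoch_s)
  w <- as.integer(cfg$window_h * 3600 / cfg$epoch_s)
  step <- as.integer(cfg$step_min * 60 / cfg$epoch_s)
  cov <- table(nights$night_date)
  good <- as.numeric(names(cov))[cov >= cfg$min_coverage * slots]
  nn <- nights[nights$night_date %in% good, ]
  best <- NULL; best_mean <- Inf
  for (s in seq(0, slots - w, by = step)) {
    inwin <- nn$activity[nn$offset >= s & nn$offset < s + w]
    if (!length(inwin)) next
    m <- mean(inwin)
    if (m < best_mean - 1e-15) {
      best_mean <- m; best <- s
    }
  }
  list(start_offset_min = best * cfg$epoch_s / 60, pooled_mean = best_mean)
}

# interval sweep over well-formed alternating screen events: walk the
# timeline accumulating screen-on time per local date
oracle_screen_sweep <- function(events, dates, tz_offset_min = 0) {
  acc <- setNames(numeric(length(dates)), as.character(dates))
  dn <- as.numeric(as.Date(dates))
  on_since <- NA_real_
  for (i in seq_len(nrow(events))) {
    if (events$state[i] == "on") {
      on_since <- events$ts[i] + tz_offset_min * 60000
    } else if (!is.na(on_since)) {
      off <- events$ts[i] + tz_offset_min * 60000
      t <- on_since
      while (t < off) {
        d <- floor(t / 86400000)
        seg_end <- min(off, (d + 1) * 86400000)
        j <- match(d, dn)
        if (!is.na(j)) acc[j] <- acc[j] + (seg_end - t)
        t <- seg_end
      }
      on_since <- NA_real_
    }
  }
  as.numeric(acc) / 3600000
}

# textbook two-sample pooled t from the raw samples, two-pass
oracle_two_pass_t <- function(x, y, ci_quantile = 0.95) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  v1 <- sum((x - m1)^2) / (n1 - 1)
  v2 <- sum((y - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / df)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  t <- (m1 - m2) / se
  list(t = t, df = df, p = pt(t, df, lower.tail = FALSE),
       ci_lower = (m1 - m2) - qt(ci_quantile, df) * se,
       ci_upper = (m1 - m2) + qt(ci_quantile, df) * se)
}

# synthetic nights: true sleep interval inside the overnight span, with
# noisy low/high activity; offsets are 60-s epochs from 18:00
make_synthetic_nights <- function(n_nights, sleep_start_h, sleep_dur_h,
                                  seed, low = 0.05, low_sd = 0.015,
                                  high = 1.2, high_sd = 0.35) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_nights)) {
    offset <- 0:959
    hour_from_18 <- offset / 60
    start_off <- ((sleep_start_h - 18) %% 24) + rnorm(1, 0, 0.15)
    dur <- sleep_dur_h + rnorm(1, 0, 0.1)
    asleep <- hour_from_18 >= start_off & hour_from_18 < start_off + dur
    act <- pmax(rnorm(960, high, high_sd), 0)
    act[asleep] <- pmax(rnorm(sum(asleep), low, low_sd), 0)
    out[[i]] <- data.frame(night_date = i, offset = offset, activity = act)
  }
  do.call(rbind, out)
}

# tiny deterministic fix cloud around a center, jitter in meters
make_fix_cloud <- function(n, lat, lon, radius_m, t0, cadence_s = 60) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  r <- radius_m * (seq_len(n) %% 5) / 5
  data.frame(ts = t0 + (seq_len(n) - 1) * cadence_s * 1000,
             lat = lat + r * sin(ang) / 111320,
             lon = lon + r * cos(ang) / (111320 * cos(lat * pi / 180)),
             accuracy_m = 10)
}

small_cohort_config <- function(seed, n = 6, p_exposed = 0.5, ...) {
  pipeline_config(
    seed = seed,
    cohort = cohort_config(n_recruited = n, p_app_usage = 1,
                           p_survey_completion = 1, p_exposure_answered = 1,
                           p_exposed_or_unsure = p_exposed, ...))
}
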