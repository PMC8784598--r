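`%||%` <- function(a, b) if (is.null(a)) b else a

MS_PER_DAY <- 86400000
MS_PER_HOUR <- 3600000

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Great-circle distance in meters (haversine)
#'
#' Vectorized haversine distance on the WGS84 mean sphere (R = 6371008.8 m).
#' Used inside the significant-location assignment loop, where it is the
#' distance the clustering radius `eps_m` refers to.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance(s) in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  r <- 6371008.8
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dp <- (lat2 - lat1) * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Truncated-normal draws on [lo, hi] via inverse-CDF; exact, no rejection.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(clip(mean, lo, hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Deterministic sub-seed derivation: one RNG lane per participant and
# purpose, independent of generation order. Kept below 2^31.
sub_seed <- function(seed, index, lane = 0L) {
  as.integer((as.numeric(seed) + 1e6 * lane + index) %% .Machine$integer.max)
}

# Local-time helpers: "local" milliseconds are UTC epoch ms shifted by the
# participant's fixed UTC offset; a local date number d covers
# [d*86400000, (d+1)*86400000) local ms.
local_ms <- function(ts, tz_offset_min) ts + tz_offset_min * 60000

local_daynum <- function(ts, tz_offset_min) {
  floor(local_ms(ts, tz_offset_min) / MS_PER_DAY)
}

local_hour <- function(ts, tz_offset_min) {
  (local_ms(ts, tz_offset_min) %% MS_PER_DAY) / MS_PER_HOUR
}

daynum <- function(date) as.numeric(as.Date(date))

daynum_to_date <- function(d) as.Date(d, origin = "1970-01-01")

# utc epoch ms of local midnight of date-number d under a fixed offset
utc_ms_of_local <- function(d_num, hours, tz_offset_min) {
  d_num * MS_PER_DAY + hours * MS_PER_HOUR - tz_offset_min * 60000
}
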