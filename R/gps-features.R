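#' Significant locations from raw GPS fixes
#'
#' Single-pass centroid agglomeration: each fix (in time order) is assigned
#' to the nearest existing cluster centroid if that centroid lies within
#' `eps_m` (haversine), otherwise it opens a new cluster; centroids are the
#' running means of their assigned fixes. The result is deterministic and
#' order-stable. Cluster weights are fractions of *all* fixes, so they sum
#' to 1 when every cluster is reported; clusters lighter than `min_weight`
#' are dropped from the returned list but their mass still counts in the
#' weights.
#'
#' @param fixes data.frame with `ts`, `lat`, `lon` (time-sorted).
#' @param eps_m clustering radius in meters.
#' @param min_weight minimal weight for a cluster to be reported.
#' @return data.frame of clusters (`cluster_id`, `lat`, `lon`, `n_fixes`,
#'   `weight`, `is_home`), with the per-fix cluster assignment in
#'   `attr(, "assignment")` and the total fix count in `attr(, "n_total")`.
#'   Empty input gives an empty data.frame.
#' @export
significant_locations <- function(fixes, eps_m = 100, min_weight = 0) {
  empty <- data.frame(cluster_id = integer(0), lat = numeric(0),
                      lon = numeric(0), n_fixes = integer(0),
                      weight = numeric(0), is_home = logical(0))
  n <- nrow(fixes)
  if (is.null(n) || n == 0) {
    attr(empty, "assignment") <- integer(0)
    attr(empty, "n_total") <- 0L
    return(empty)
  }
  if (is.unsorted(fixes$ts)) stop("significant_locations: fixes must be time-sorted")
  lat <- fixes$lat; lon <- fixes$lon
  r_earth <- 6371008.8
  clat <- numeric(0); clon <- numeric(0); cnt <- integer(0)
  slat <- numeric(0); slon <- numeric(0)   # coordinate sums for exact means
  assignment <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (k > 0L) {
      # inline haversine against current centroids (hot loop)
      p1 <- lat[i] * pi / 180; p2 <- clat * pi / 180
      a <- sin((clat - lat[i]) * pi / 360)^2 +
        cos(p1) * cos(p2) * sin((clon - lon[i]) * pi / 360)^2
      d <- 2 * r_earth * asin(pmin(1, sqrt(a)))
      j <- which.min(d)
      if (d[j] <= eps_m) {
        cnt[j] <- cnt[j] + 1L
        slat[j] <- slat[j] + lat[i]; slon[j] <- slon[j] + lon[i]
        clat[j] <- slat[j] / cnt[j]; clon[j] <- slon[j] / cnt[j]
        assignment[i] <- j
        next
      }
    }
    k <- k + 1L
    clat[k] <- lat[i]; clon[k] <- lon[i]
    slat[k] <- lat[i]; slon[k] <- lon[i]
    cnt[k] <- 1L
    assignment[i] <- k
  }
  weight <- cnt / n
  keep <- weight >= min_weight
  out <- data.frame(cluster_id = seq_len(k)[keep], lat = clat[keep],
                    lon = clon[keep], n_fixes = cnt[keep],
                    weight = weight[keep], is_home = NA)
  rownames(out) <- NULL
  attr(out, "assignment") <- assignment
  attr(out, "n_total") <- n
  out
}

#' Label the home cluster
#'
#' Home is the reported cluster holding the most fixes timestamped in the
#' overnight span (default 00:00-06:00 local); ties go to the lower cluster
#' index (the cluster whose first fix came earlier). If no fix falls in the
#' overnight span, the highest-weight cluster is used and the fallback is
#' flagged in `attr(, "quality")`.
#'
#' @param clusters output of [significant_locations()].
#' @param fixes the same fixes the clusters were built from.
#' @param night_start,night_end local clock hours bounding the overnight
#'   span.
#' @param tz_offset_min participant's UTC offset in minutes.
#' @return `clusters` with exactly one `is_home = TRUE` row.
#' @export
label_home <- function(clusters, fixes, night_start = 0, night_end = 6,
                       tz_offset_min = 0) {
  if (!nrow(clusters)) stop("label_home: no clusters")
  assignment <- attr(clusters, "assignment")
  stopifnot(length(assignment) == nrow(fixes))
  hr <- local_hour(fixes$ts, tz_offset_min)
  overnight <- hr >= night_start & hr < night_end
  clusters$is_home <- FALSE
  if (!any(overnight)) {
    clusters$is_home[which.max(clusters$weight)] <- TRUE
    attr(clusters, "quality") <- "no_overnight_fixes"
    return(clusters)
  }
  tab <- tabulate(assignment[overnight], nbins = max(assignment))
  counts <- tab[clusters$cluster_id]
  clusters$is_home[which.max(counts)] <- TRUE   # first max = lower id
  clusters
}

#' Daily hours at home
#'
#' For consecutive fixes both assigned to the home cluster and separated by
#' at most `gap_max_s`, the interval between them accrues to the local
#' date(s) it overlaps. Dates with fixes but no home presence get 0; dates
#' without any fix are absent from the result (missing, not zero).
#'
#' @param fixes time-sorted fixes.
#' @param clusters home-labeled clusters from [label_home()].
#' @param gap_max_s maximal inter-fix gap in seconds.
#' @param tz_offset_min participant's UTC offset in minutes.
#' @return data.frame `date`, `home_time_h`, `n_fixes`.
#' @export
home_time <- function(fixes, clusters, gap_max_s = 600, tz_offset_min = 0) {
  if (!any(clusters$is_home %in% TRUE)) stop("home_time: home not labeled")
  home_id <- clusters$cluster_id[which(clusters$is_home)[1]]
  assignment <- attr(clusters, "assignment")
  n <- nrow(fixes)
  lms <- local_ms(fixes$ts, tz_offset_min)
  fix_day <- floor(lms / MS_PER_DAY)
  n_fixes <- table(fix_day)
  days <- as.numeric(names(n_fixes))
  acc <- setNames(numeric(length(days)), names(n_fixes))
  if (n >= 2) {
    i <- seq_len(n - 1)
    ok <- assignment[i] == home_id & assignment[i + 1] == home_id &
      (lms[i + 1] - lms[i]) <= gap_max_s * 1000
    s <- lms[i][ok]; e <- lms[i + 1][ok]
    if (length(s)) {
      d1 <- floor(s / MS_PER_DAY)
      d2 <- floor((e - 1e-9) / MS_PER_DAY)
      # part within the interval's first day
      p1 <- pmin(e, (d1 + 1) * MS_PER_DAY) - s
      add <- tapply(p1, d1, sum)
      acc[names(add)] <- acc[names(add)] + add
      cross <- d2 > d1
      if (any(cross)) {
        p2 <- e[cross] - d2[cross] * MS_PER_DAY
        add2 <- tapply(p2, d2[cross], sum)
        acc[names(add2)] <- acc[names(add2)] + add2
      }
    }
  }
  data.frame(date = daynum_to_date(days),
             home_time_h = as.numeric(acc) / MS_PER_HOUR,
             n_fixes = as.integer(n_fixes))
}
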