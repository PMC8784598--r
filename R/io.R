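#' Write per-participant sensor streams as JSON-lines
#'
#' One line per record: `{"ts": <ms>, "sensor": "gps", "lat": ..,
#' "lon": .., "accuracy_m": ..}`, `{"ts": .., "sensor": "accel",
#' "activity": ..}`, `{"ts": .., "sensor": "screen", "state": "on"}`.
#' Records are written in timestamp order across sensors.
#'
#' @param streams list with `gps`, `accel`, `screen` for one participant.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sensor_jsonl <- function(streams, path) {
  lines <- character(0)
  ts <- numeric(0)
  if (NROW(streams$gps)) {
    g <- streams$gps
    lines <- c(lines, sprintf(
      '{"ts":%.0f,"sensor":"gps","lat":%.8f,"lon":%.8f,"accuracy_m":%g}',
      g$ts, g$lat, g$lon, g$accuracy_m))
    ts <- c(ts, g$ts)
  }
  if (NROW(streams$accel)) {
    a <- streams$accel
    lines <- c(lines, sprintf('{"ts":%.0f,"sensor":"accel","activity":%.6g}',
                              a$ts, a$activity))
    ts <- c(ts, a$ts)
  }
  if (NROW(streams$screen)) {
    s <- streams$screen
    lines <- c(lines, sprintf('{"ts":%.0f,"sensor":"screen","state":"%s"}',
                              s$ts, s$state))
    ts <- c(ts, s$ts)
  }
  writeLines(lines[order(ts)], path)
  invisible(path)
}

#' Read a JSON-lines sensor file
#'
#' @param path file written by [write_sensor_jsonl()] (or any stream in the
#'   same schema).
#' @param participant_id optional id attached to every record.
#' @return list of data.frames `gps`, `accel`, `screen`, each time-sorted.
#' @export
read_sensor_jsonl <- function(path, participant_id = NULL) {
  rec <- jsonlite::stream_in(file(path), verbose = FALSE)
  pick <- function(sensor, cols) {
    if (!nrow(rec) || !any(rec$sensor == sensor)) {
      d <- as.data.frame(setNames(rep(list(numeric(0)), length(cols) + 1),
                                  c("ts", cols)))
      if (sensor == "screen") d$state <- character(0)
      return(d)
    }
    d <- rec[rec$sensor == sensor, c("ts", cols), drop = FALSE]
    d <- d[order(d$ts), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  out <- list(gps = pick("gps", c("lat", "lon", "accuracy_m")),
              accel = pick("accel", "activity"),
              screen = pick("screen", "state"))
  if (!is.null(participant_id)) {
    out <- lapply(out, function(d) {
      if (nrow(d)) d$participant_id <- participant_id
      d
    })
  }
  out
}

#' Write the roster and ground truth of a cohort run
#'
#' @param cohort a `phenocap_cohort`.
#' @param truth truth list from [generate_cohort_streams()] (optional).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, truth = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$roster, file.path(dir, "roster.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    for (nm in names(truth)) {
      write.csv(truth[[nm]], file.path(dir, paste0("truth_", nm, ".csv")),
                row.names = FALSE)
    }
  }
  invisible(dir)
}
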