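#' Run the full digital-phenotyping pipeline
#'
#' Orchestrates the four stages — simulate (cohort, sensor streams, survey
#' responses), features (daily passive features), score (survey scoring and
#' item matrices) and compare (group inference) — deterministically under
#' the configured seed, and writes the run artifacts: roster and ground
#' truth CSVs, the daily feature table, the scored surveys, the comparison
#' table (CSV and JSON report), the gender summary, and a provenance
#' manifest (config, config hash, package and R versions). A failure stops
#' with a message naming the failed stage; outputs of completed stages are
#' retained on disk.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; defaults to `config$out_dir` (required
#'   in one of the two).
#' @param participants optional participant ids for the sensor stages
#'   (defaults to the app users).
#' @param write_streams also write per-participant JSON-lines sensor files
#'   (off by default; streams can be large).
#' @return invisibly, a list with `cohort`, `streams`, `daily`, `scored`,
#'   `participant_means`, `item_means`, `feature_means`, `comparison`,
#'   `gender_summary`, `funnel`.
#' @export
run_pipeline <- function(config, out_dir = NULL, participants = NULL,
                         write_streams = FALSE) {
  stopifnot(inherits(config, "phenocap_config"))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("run_pipeline: an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate ------------------------------------------------------------
  sim <- stage("simulate", {
    cohort <- generate_cohort(config)
    streams <- generate_cohort_streams(cohort, participants)
    surveys <- generate_cohort_surveys(cohort)
    write_cohort_csv(cohort, streams$truth, out_dir)
    write.csv(surveys, file.path(out_dir, "survey_responses.csv"),
              row.names = FALSE)
    if (write_streams) {
      sdir <- file.path(out_dir, "sensors")
      dir.create(sdir, showWarnings = FALSE)
      for (pid in unique(streams$gps$participant_id)) {
        one <- lapply(streams[c("gps", "accel", "screen")],
                      function(d) d[d$participant_id == pid, , drop = FALSE])
        write_sensor_jsonl(one, file.path(sdir, paste0(pid, ".jsonl")))
      }
    }
    logmsg("simulate: funnel ", paste(cohort$funnel, collapse = " -> "))
    list(cohort = cohort, streams = streams, surveys = surveys)
  })

  # --- features ------------------------------------------------------------
  daily <- stage("features", {
    roster <- sim$cohort$roster
    have <- roster$participant_id %in% unique(sim$streams$gps$participant_id)
    d <- build_daily_features(sim$streams, roster[have, , drop = FALSE], config)
    write.csv(d, file.path(out_dir, "daily_features.csv"), row.names = FALSE)
    logmsg("features: ", nrow(d), " participant-days")
    d
  })

  # --- score ---------------------------------------------------------------
  scores <- stage("score", {
    scored <- score_administrations(sim$surveys)
    pm <- participant_mean(scored)
    im <- list(PQ16 = item_matrix(sim$surveys, "PQ16"),
               PSQI9 = item_matrix(sim$surveys, "PSQI9"))
    write.csv(scored, file.path(out_dir, "scored_surveys.csv"),
              row.names = FALSE)
    logmsg("score: ", nrow(scored), " administrations")
    list(scored = scored, participant_means = pm, item_means = im)
  })

  # --- compare -------------------------------------------------------------
  cmp <- stage("compare", {
    analysis <- analysis_roster(sim$cohort)
    groups <- split_groups(analysis)
    pm <- scores$participant_means
    pm <- pm[pm$participant_id %in% analysis$participant_id, ]
    im <- lapply(scores$item_means, function(d)
      d[d$participant_id %in% analysis$participant_id, ])
    fm <- participant_feature_means(daily)
    comparison <- compare_all(pm, im, fm, groups, config$inference)
    gender <- cohort_summary(analysis)
    write.csv(comparison, file.path(out_dir, "comparison.csv"),
              row.names = FALSE)
    write.csv(format_comparison(comparison),
              file.path(out_dir, "comparison_formatted.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(funnel = as.list(sim$cohort$funnel),
           gender = gender,
           comparison = comparison),
      file.path(out_dir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    logmsg("compare: ", nrow(comparison), " rows, ",
           sum(comparison$marker != ""), " starred")
    list(comparison = comparison, gender = gender)
  })

  manifest <- write_manifest(config, out_dir)
  invisible(list(cohort = sim$cohort, streams = sim$streams,
                 daily = daily, scored = scores$scored,
                 participant_means = scores$participant_means,
                 item_means = scores$item_means,
                 feature_means = participant_feature_means(daily),
                 comparison = cmp$comparison,
                 gender_summary = cmp$gender,
                 funnel = sim$cohort$funnel,
                 manifest = manifest))
}

write_manifest <- function(config, out_dir) {
  cfg_path <- file.path(out_dir, "config.yaml")
  serializable <- rapply(unclass(config), function(x) {
    if (inherits(x, "Date")) as.character(x) else x
  }, how = "replace")
  serializable$item_effects <- NULL
  yaml::write_yaml(serializable, cfg_path)
  manifest <- list(
    config_file = basename(cfg_path),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("phenocap")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  manifest
}
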