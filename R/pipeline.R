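# Configuration-driven, staged pipeline: load -> dedup -> cohort ->
# describe -> signals -> severity -> priority -> tto.  Each stage writes its
# CSV/JSON outputs under the run directory and records a manifest entry;
# re-running a completed stage with an unchanged configuration is a no-op.

.pipeline_stages <- c("load", "dedup", "cohort", "describe", "signals",
                      "severity", "priority", "tto")

.stage_outputs <- list(
  load = "parse_report.json",
  dedup = c("cases.csv", "dedup_report.json"),
  cohort = c("cohort_ids.csv", "target_events.csv", "unmapped_pts.csv",
             "concomitant_drugs.csv"),
  describe = "cohort_summary.json",
  signals = c("signals.csv", "soc_signal.csv", "stratified_ror.csv"),
  severity = "severity.csv",
  priority = c("priority.csv", "priority_summary.json"),
  tto = c("tto_samples.csv", "tto_by_band.csv", "tto_exclusions.json")
)

#' Read and validate a pipeline configuration
#'
#' The configuration is a single JSON file: `bundle_dir`, `pt_soc_map`,
#' optional `dme_terms`/`ime_terms`/`evidence_file` paths, `generic_names`,
#' `brand_names`, `target_soc`, `min_reports`, `age_breaks`,
#' `weight_breaks`.
#'
#' @param path JSON file path, or an equivalent named list.
#' @return validated configuration list with a `study_config` attached.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
  else path
  if (is.null(cfg$bundle_dir)) stop("config lacks 'bundle_dir'",
                                    call. = FALSE)
  if (is.null(cfg$pt_soc_map)) stop("config lacks 'pt_soc_map'",
                                    call. = FALSE)
  if (length(cfg$generic_names) + length(cfg$brand_names) == 0L) {
    stop("config must name the target drug (generic_names/brand_names)",
         call. = FALSE)
  }
  cfg$study <- study_config(
    generic_names = cfg$generic_names,
    brand_names = if (is.null(cfg$brand_names)) character(0) else
      cfg$brand_names,
    target_soc = if (is.null(cfg$target_soc)) "Gastrointestinal disorders"
    else cfg$target_soc,
    min_reports = if (is.null(cfg$min_reports)) 10 else cfg$min_reports,
    age_breaks = if (is.null(cfg$age_breaks)) c(18, 65) else cfg$age_breaks,
    weight_breaks = if (is.null(cfg$weight_breaks)) c(80, 100) else
      cfg$weight_breaks)
  cfg
}

.config_fingerprint <- function(cfg) {
  cfg$study <- NULL
  as.character(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE))
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in their fixed order, writing every
#' stage's outputs under `out_dir` and a `manifest.json` describing the run.
#' A stage whose outputs already exist under an identical configuration is
#' skipped (its manifest entry is marked `"cached"`); prerequisite results
#' are always recomputed in memory, so a partial re-run still sees
#' consistent inputs.
#'
#' @param config path to a JSON configuration or a list (see
#'   [read_pipeline_config()]).
#' @param out_dir run directory; created if needed, and the only place the
#'   pipeline writes.
#' @param stages subset of
#'   `c("load","dedup","cohort","describe","signals","severity","priority","tto")`.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = .pipeline_stages) {
  cfg <- read_pipeline_config(config)
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- .config_fingerprint(cfg)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else list(config = fp, stages = list())
  if (!identical(manifest$config, fp)) {
    manifest <- list(config = fp, stages = list())
  }
  log_line <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), ..., "\n",
        file = file.path(out_dir, "pipeline.log"), append = TRUE)
  }
  cached <- function(stage) {
    done <- isTRUE(manifest$stages[[stage]]$status %in% c("done", "cached"))
    done && all(file.exists(file.path(out_dir, .stage_outputs[[stage]])))
  }
  mark <- function(stage, status) {
    manifest$stages[[stage]] <<- list(status = status,
                                      outputs = .stage_outputs[[stage]])
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  }

  bundle <- read_faers_bundle(cfg$bundle_dir)
  if ("load" %in% stages && !cached("load")) {
    jsonlite::write_json(bundle$parse_report,
                         file.path(out_dir, "parse_report.json"),
                         auto_unbox = TRUE)
    mark("load", "done"); log_line("load: parsed bundle")
  } else if ("load" %in% stages) mark("load", "cached")

  universe <- deduplicate_cases(bundle)
  if ("dedup" %in% stages && !cached("dedup")) {
    .write_csv(universe$cases, file.path(out_dir, "cases.csv"))
    jsonlite::write_json(list(n_input_rows = universe$n_input_rows,
                              n_cases = nrow(universe$cases),
                              n_removed_duplicates =
                                universe$n_removed_duplicates,
                              n_removed_deleted = universe$n_removed_deleted),
                         file.path(out_dir, "dedup_report.json"),
                         auto_unbox = TRUE)
    mark("dedup", "done"); log_line("dedup:", nrow(universe$cases), "cases")
  } else if ("dedup" %in% stages) mark("dedup", "cached")

  study <- cfg$study
  target_ids <- match_target_cases(universe, study)
  pt_soc <- read_pt_soc_map(cfg$pt_soc_map)
  sel <- select_target_events(universe$reac, pt_soc, study$target_soc)
  events <- sel$events
  cohort_events <- events[events$primaryid %in% target_ids, , drop = FALSE]
  if ("cohort" %in% stages && !cached("cohort")) {
    .write_csv(data.frame(primaryid = target_ids),
               file.path(out_dir, "cohort_ids.csv"))
    .write_csv(cohort_events, file.path(out_dir, "target_events.csv"))
    .write_csv(sel$unmapped, file.path(out_dir, "unmapped_pts.csv"))
    .write_csv(concomitant_drugs(universe, target_ids, study),
               file.path(out_dir, "concomitant_drugs.csv"))
    mark("cohort", "done")
    log_line("cohort:", length(target_ids), "target cases,",
             nrow(cohort_events), "SOC events")
  } else if ("cohort" %in% stages) mark("cohort", "cached")

  if ("describe" %in% stages && !cached("describe")) {
    summ <- describe_cohort(universe, target_ids, study)
    jsonlite::write_json(unclass(summ),
                         file.path(out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    mark("describe", "done"); log_line("describe: summary written")
  } else if ("describe" %in% stages) mark("describe", "cached")

  screen <- screen_signals(universe, target_ids, events, study)
  if ("signals" %in% stages && !cached("signals")) {
    .write_csv(as.data.frame(screen), file.path(out_dir, "signals.csv"))
    .write_csv(soc_signal(universe, target_ids, events, study$target_soc),
               file.path(out_dir, "soc_signal.csv"))
    .write_csv(stratified_ror(universe, target_ids, events,
                              default_strata(study)),
               file.path(out_dir, "stratified_ror.csv"))
    mark("signals", "done")
    log_line("signals:", sum(screen$is_signal), "positive of", nrow(screen))
  } else if ("signals" %in% stages) mark("signals", "cached")

  labels <- classify_seriousness(universe, target_ids)
  if ("severity" %in% stages && !cached("severity")) {
    .write_csv(compare_event_severity(cohort_events, labels, target_ids),
               file.path(out_dir, "severity.csv"))
    mark("severity", "done"); log_line("severity: table written")
  } else if ("severity" %in% stages) mark("severity", "cached")

  dme <- if (!is.null(cfg$dme_terms)) read_term_list(cfg$dme_terms) else
    character(0)
  ime <- if (!is.null(cfg$ime_terms)) read_term_list(cfg$ime_terms) else
    character(0)
  evid <- if (!is.null(cfg$evidence_file)) {
    utils::read.csv(cfg$evidence_file, stringsAsFactors = FALSE)
  } else NULL
  scores <- NULL
  deaths_by_case <- labels$primaryid[grepl("death", labels$categories,
                                           fixed = TRUE)]
  prio_in <- screen[screen$is_signal, , drop = FALSE]
  if (nrow(prio_in) > 0) {
    by_pt <- .event_ids_by_pt(cohort_events)
    deaths <- vapply(.norm_name(prio_in$term), function(pt)
      length(intersect(unique(by_pt[[pt]]), deaths_by_case)), integer(1))
    ev_grade <- rep("-", nrow(prio_in))
    if (!is.null(evid)) {
      m <- match(.norm_name(prio_in$term), .norm_name(evid$pt))
      ev_grade[!is.na(m)] <- evid$evidence[m[!is.na(m)]]
    }
    scores <- score_signals(data.frame(
      pt = prio_in$term, n_reports = prio_in$a, ror025 = prio_in$ci_low,
      deaths = unname(deaths),
      dme_ime = flag_dme_ime(prio_in$term, dme, ime),
      evidence = ev_grade, stringsAsFactors = FALSE))
  }
  if ("priority" %in% stages && !cached("priority")) {
    if (is.null(scores)) {
      .write_csv(data.frame(), file.path(out_dir, "priority.csv"))
      jsonlite::write_json(list(counts = list()),
                           file.path(out_dir, "priority_summary.json"))
    } else {
      .write_csv(as.data.frame(scores), file.path(out_dir, "priority.csv"))
      jsonlite::write_json(as.list(summarize_priorities(scores)$counts),
                           file.path(out_dir, "priority_summary.json"),
                           auto_unbox = TRUE)
    }
    mark("priority", "done"); log_line("priority: scores written")
  } else if ("priority" %in% stages) mark("priority", "cached")

  if ("tto" %in% stages && !cached("tto")) {
    samples <- compute_tto(universe, target_ids, cohort_events, study)
    .write_csv(samples, file.path(out_dir, "tto_samples.csv"))
    jsonlite::write_json(as.list(attr(samples, "exclusions")),
                         file.path(out_dir, "tto_exclusions.json"),
                         auto_unbox = TRUE)
    band_tab <- if (!is.null(scores) && nrow(samples) > 0) {
      tto_by_band(samples, scores)
    } else data.frame()
    .write_csv(band_tab, file.path(out_dir, "tto_by_band.csv"))
    mark("tto", "done"); log_line("tto:", nrow(samples), "samples")
  } else if ("tto" %in% stages) mark("tto", "cached")

  invisible(manifest)
}
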