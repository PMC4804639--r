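# End-to-end orchestration: simulate -> fixations -> compare -> correlate
# -> discriminate, with plain CSV/markdown outputs and a fixture-only mode
# that reruns every computation the printed summary tables support.

default_run_config <- function() {
  list(
    battery = NULL,            # path to battery JSON; NULL = default battery
    cohort_params = NULL,      # list or path; NULL = default params
    gaze_csv = NULL,           # real-data mode: read instead of simulating
    participants_csv = NULL,
    seed = NULL,
    variant_policy = "levene",
    d_min = 0.8,
    availability_threshold = 80,
    panel = "large-effect",    # or "all-aoi1"
    out_dir = NULL
  )
}

load_run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  cfg <- utils::modifyList(default_run_config(), config)
  for (f in c("battery", "gaze_csv", "participants_csv"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      gf_stop(sprintf("config path does not exist: %s = %s", f, cfg[[f]]),
              "gf_config_error")
  cfg
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[gazeclass] ", fmt), ...))
}

write_stage_csv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(dir, name), row.names = FALSE, na = "")
  invisible(file.path(dir, name))
}

md_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) formatC(v, digits = digits,
                                                 format = "fg"))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort simulation (or CSV ingestion), fixation
#' metrics with availability exclusion, group comparisons, within-group
#' correlations, per-item ROC, panel selection, and the count-over-cutoff
#' discriminant sweep. All stage outputs are plain CSV plus a markdown
#' report; identical config and seed give byte-identical outputs.
#'
#' @param config list or JSON path; see fields of the default config:
#'   `battery`, `cohort_params`, `gaze_csv`/`participants_csv` (real-data
#'   mode), `seed` (required when simulating), `variant_policy`, `d_min`,
#'   `availability_threshold`, `panel` (`"large-effect"` or `"all-aoi1"`),
#'   `out_dir`.
#' @param quiet suppress stage logging.
#' @return A `gf_run_report` list: config echo, package version, per-stage
#'   row counts, the result tables, and accumulated warnings.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- load_run_config(config)
  battery <- if (is.null(cfg$battery)) default_battery()
             else load_battery(cfg$battery)
  warnings <- character(0)
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)

  if (!is.null(cfg$gaze_csv)) {
    log_stage(quiet, "reading gaze data from %s", cfg$gaze_csv)
    gaze <- read_gaze_csv(cfg$gaze_csv)
    participants <- read_participants_csv(cfg$participants_csv)
  } else {
    if (is.null(cfg$seed))
      gf_stop("a seed is required when the pipeline simulates its cohort",
              "gf_config_error")
    params <- if (is.null(cfg$cohort_params)) default_cohort_params()
              else if (inherits(cfg$cohort_params, "gf_cohort_params"))
                cfg$cohort_params
              else if (is.character(cfg$cohort_params))
                utils::modifyList(default_cohort_params(),
                                  jsonlite::fromJSON(cfg$cohort_params,
                                                     simplifyVector = TRUE))
              else utils::modifyList(default_cohort_params(), cfg$cohort_params)
    log_stage(quiet, "simulating cohort (n_asd=%d, n_td=%d, seed=%s)",
              params$n_asd, params$n_td, format(cfg$seed))
    cohort <- generate_cohort(params, seed = cfg$seed, battery = battery)
    gaze <- cohort$gaze
    participants <- cohort$participants
    if (!is.null(out)) write_cohort_csv(cohort, out)
  }
  log_stage(quiet, "participants: %d (%d ASD, %d TD)", nrow(participants),
            sum(participants$group == "ASD"), sum(participants$group == "TD"))

  fixation <- compute_fixation_table(gaze, battery,
                                     threshold = cfg$availability_threshold)
  log_stage(quiet, "fixation records: %d included, %d excluded (< %g%%)",
            nrow(fixation$included), nrow(fixation$excluded),
            cfg$availability_threshold)
  if (!is.null(out)) {
    write_fixation_csv(fixation, file.path(out, "fixation.csv"),
                       file.path(out, "excluded.csv"))
  }

  comparisons <- compare_groups(fixation, participants, battery,
                                variant_policy = cfg$variant_policy)
  write_stage_csv(comparisons, out, "comparisons.csv")
  correlations <- within_group_correlations(fixation, participants)
  write_stage_csv(correlations, out, "correlations.csv")
  roc <- roc_analysis(fixation, participants, battery)
  write_stage_csv(roc, out, "roc.csv")

  panel <- if (identical(cfg$panel, "all-aoi1"))
    select_panel(comparisons, d_min = -Inf, aoi1_only = TRUE)
  else select_panel(comparisons, d_min = cfg$d_min, aoi1_only = TRUE)
  log_stage(quiet, "panel (%s): %s", cfg$panel, paste(panel, collapse = ", "))

  rules <- lapply(panel, function(it) {
    r <- roc[roc$item == it, ]
    structure(list(item = it, direction = r$direction, cutoff = r$cutoff,
                   cutoff_report = r$cutoff_report,
                   sens_at_cutoff = r$sens_at_cutoff,
                   spec_at_cutoff = r$spec_at_cutoff,
                   youden_j = r$sens_at_cutoff + r$spec_at_cutoff - 1),
              class = "gf_cutoff_rule")
  })
  disc <- discriminant_sweep(fixation, participants, rules)
  write_stage_csv(disc$breakdown, out, "breakdown.csv")
  write_stage_csv(disc$metrics, out, "discriminant.csv")
  if (any(is.infinite(disc$metrics$plr)))
    warnings <- c(warnings, "PLR is infinite at some count threshold (specificity = 1)")
  if (any(disc$breakdown$n_asd + disc$breakdown$n_td == 0))
    warnings <- c(warnings, "some item combinations contain no participants")

  report <- structure(list(
    config = cfg, version = as.character(utils::packageVersion("gazeclass")),
    counts = list(participants = nrow(participants),
                  included = nrow(fixation$included),
                  excluded = nrow(fixation$excluded)),
    fixation = fixation, comparisons = comparisons,
    correlations = correlations, roc = roc, panel = panel,
    discriminant = disc, warnings = warnings
  ), class = "gf_run_report")
  if (!is.null(out)) write_report_md(report, file.path(out, "report.md"))
  report
}

write_report_md <- function(report, path) {
  disc <- report$discriminant
  lines <- c(
    "# gazeclass run report", "",
    sprintf("gazeclass version %s; seed %s.", report$version,
            format(report$config$seed %||% "none (real data)")),
    sprintf("Participants: %d; included %d, excluded %d (availability < %g%%).",
            report$counts$participants, report$counts$included,
            report$counts$excluded, report$config$availability_threshold), "",
    "## Group comparisons", "",
    md_table(report$comparisons[c("item", "mean_asd", "sd_asd", "mean_td",
                                  "sd_td", "t", "p", "variant", "d",
                                  "alpha", "significant")]), "",
    "## Within-group correlations (significant rows)", "",
    md_table(report$correlations[report$correlations$significant,
                                 c("item", "covariate", "group", "n", "r", "p")]),
    "",
    "## ROC per item", "",
    md_table(report$roc[c("item", "direction", "auc", "ci_low", "ci_high",
                          "cutoff_report")]), "",
    sprintf("## Discriminant panel: %s", paste(report$panel, collapse = ", ")),
    "",
    md_table(disc$metrics[c("k", "sensitivity_pct", "specificity_pct",
                            "plr_report", "nlr_report")]), "")
  if (length(report$warnings))
    lines <- c(lines, "## Warnings", "", paste0("- ", report$warnings), "")
  writeLines(lines, path)
  invisible(path)
}

#' Rerun every computation the printed summary tables support
#'
#' No simulation: recomputes t, p and Cohen's d from the printed group
#' means/SDs, selects the large-effect AoI-1 panel from the recomputed d
#' values, and reconstructs the count-threshold discriminant metrics from
#' the printed panel breakdown counts.
#'
#' @param out_dir optional output directory for CSVs and report.
#' @param d_min panel effect-size threshold.
#' @return list with `comparisons`, `panel`, `rules` (printed cutoffs),
#'   `metrics`, `fixtures`.
#' @export
fixture_mode <- function(out_dir = NULL, d_min = 0.8) {
  fx <- load_fixtures()
  comparisons <- compare_from_summary(fx$table2, n_asd = fx$n_asd,
                                      n_td = fx$n_td, variant = "auto")
  panel <- select_panel(comparisons, d_min = d_min, aoi1_only = TRUE)
  rules <- cutoff_rules_from_table(fx$table4, panel)
  metrics <- discriminant_from_counts(breakdown_met_counts(fx$table5))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_stage_csv(comparisons, out_dir, "comparisons.csv")
    write_stage_csv(metrics, out_dir, "discriminant.csv")
  }
  list(comparisons = comparisons, panel = panel, rules = rules,
       metrics = metrics, fixtures = fx)
}

#' @export
print.gf_run_report <- function(x, ...) {
  cat(sprintf("<gf_run_report> v%s: %d participants (%d included), panel: %s\n",
              x$version, x$counts$participants, x$counts$included,
              paste(x$panel, collapse = ", ")))
  print(x$discriminant)
  invisible(x)
}
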